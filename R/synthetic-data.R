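#' Simulation configuration for the synthetic-data generators
#'
#' Bundles the knobs shared by the coverage and fluorescence simulators.
#' The defaults emulate the conditions of the wet experiments the pipeline
#' was designed around: a deep 5'-end-capture sequencing run (per-position
#' background read starts plus strongly amplified starts at cleavage sites),
#' and triplicate fluorometric traces sampled every 80 s.
#'
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   output.
#' @param read_length Mapped read length in nt (>= 1).
#' @param depth Expected background read-start intensity basis (>= 1); the
#'   per-position background start rate is `depth * background_rate` and the
#'   start count at a planted site is `depth * efficiency * amplification`.
#' @param noise_sd Gaussian noise s.d. for fluorescence values, in percent
#'   units (>= 0).
#' @param replicates Number of fluorescence replicates (>= 1).
#' @param background_rate Background read starts per position, as a fraction
#'   of `depth`.
#' @param amplification Amplification factor applied to site read starts
#'   (barcode-ligated fragment ends are preferentially amplified and
#'   sequenced).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, read_length = 150L, depth = 1000L,
                       noise_sd = 2, replicates = 3L,
                       background_rate = 0.01, amplification = 100) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  if (read_length < 1) stop("read_length must be >= 1")
  if (depth < 1) stop("depth must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (amplification <= 0) stop("amplification must be > 0")
  structure(
    list(seed = seed, read_length = as.integer(read_length),
         depth = depth, noise_sd = noise_sd,
         replicates = as.integer(replicates),
         background_rate = background_rate, amplification = amplification),
    class = "sim_config"
  )
}

#' Generate a random RNA sequence
#'
#' @param length Sequence length (>= 1).
#' @param composition Numeric vector of 4 probabilities for A, C, G, U
#'   (in that order, or named); must sum to 1 within 1e-9.
#' @param seed Integer seed.
#' @return A single RNA string over {A, C, G, U}.
#' @examples
#' gen_random_rna(10, c(1, 0, 0, 0), seed = 1) # "AAAAAAAAAA"
#' @export
gen_random_rna <- function(length, composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                           seed = 1L) {
  if (length < 1) stop("length must be >= 1")
  composition <- check_composition(composition)
  set.seed(as.integer(seed))
  paste(sample(c("A", "C", "G", "U"), length, replace = TRUE, prob = composition),
        collapse = "")
}

# Validate a 4-base composition vector; returns it named A/C/G/U in order.
check_composition <- function(composition) {
  if (length(composition) != 4L) stop("composition must have 4 elements (A, C, G, U)")
  if (!is.null(names(composition))) {
    if (!setequal(names(composition), c("A", "C", "G", "U")))
      stop("composition names must be A, C, G, U")
    composition <- composition[c("A", "C", "G", "U")]
  } else {
    names(composition) <- c("A", "C", "G", "U")
  }
  s <- sum(composition)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("composition must sum to 1 (got %.12g)", s))
  if (any(composition < 0)) stop("composition probabilities must be >= 0")
  composition
}

#' Write a motif into a sequence at given positions
#'
#' Overwrites the sequence with `motif` at each 0-based position. Planted
#' windows must not overlap (overlaps would make the ground truth ambiguous).
#'
#' @param sequence RNA string.
#' @param motif RNA string to plant.
#' @param positions Integer vector of 0-based start positions.
#' @return The modified sequence (same length).
#' @examples
#' plant_motifs("GGGGGGGG", "AACU", 2) # "GGAACUGG"
#' @export
plant_motifs <- function(sequence, motif, positions) {
  L <- nchar(sequence)
  m <- nchar(motif)
  positions <- as.integer(positions)
  if (any(positions < 0) || any(positions + m > L))
    stop("motif window out of range for position(s) ",
         paste(positions[positions < 0 | positions + m > L], collapse = ", "))
  if (length(positions) > 1L) {
    p <- sort(positions)
    if (any(diff(p) < m)) stop("planted motif windows overlap")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  mchars <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (pos in positions) chars[(pos + 1):(pos + m)] <- mchars
  paste(chars, collapse = "")
}

#' Planted cleavage sites
#'
#' A site's `position` is the 0-based index of the first nucleotide of the
#' downstream fragment, i.e. the second A of an A|ACU-type cut (the enzyme
#' cuts between the two adenines, so coverage steps up at the second A).
#'
#' @param position Integer vector of 0-based positions (0 < position < L).
#' @param efficiency Fraction of molecules cut at each site, in (0, 1].
#' @return A data.frame with columns `position` and `efficiency`.
#' @export
planted_sites <- function(position, efficiency = 0.5) {
  position <- as.integer(position)
  efficiency <- rep_len(efficiency, length(position))
  if (any(efficiency <= 0 | efficiency > 1)) stop("efficiency must be in (0, 1]")
  if (any(position < 1)) stop("position must be >= 1 (position 0 has no upstream)")
  data.frame(position = position, efficiency = efficiency)[order(position), ,
                                                           drop = FALSE]
}

#' Simulate a 5'-end-capture coverage profile with planted cleavage sites
#'
#' Models only read 5'-start positions plus a fixed read length, which is all
#' the relative-coverage-increase statistic depends on. For each planted site
#' a Poisson(depth * efficiency * amplification) count of reads starts exactly
#' at the site position (the 5' end of the cleavage-derived downstream
#' fragment, tagged by barcode ligation); background reads start at every
#' position at rate depth * background_rate. Coverage at i counts reads whose
#' interval [start, min(start + read_length, L)) contains i.
#'
#' @param sequence RNA string of the reference substrate.
#' @param sites A data.frame as returned by [planted_sites()]; may have zero
#'   rows.
#' @param config A [sim_config()].
#' @param reference_id Name for the resulting profile.
#' @return A [coverage_profile()] whose `starts` attribute holds the
#'   per-position read-start counts (for coverage-conservation checks).
#' @export
simulate_cleavage_coverage <- function(sequence, sites, config,
                                       reference_id = "ref") {
  stopifnot(inherits(config, "sim_config"))
  L <- nchar(sequence)
  if (nrow(sites) > 0) {
    if (any(sites$position >= L)) stop("site position beyond sequence end")
    if (is.unsorted(sites$position)) sites <- sites[order(sites$position), ]
  }
  set.seed(config$seed)
  starts <- stats::rpois(L, config$depth * config$background_rate)
  if (nrow(sites) > 0) {
    idx <- sites$position + 1L
    starts[idx] <- starts[idx] +
      stats::rpois(nrow(sites),
                   config$depth * sites$efficiency * config$amplification)
  }
  # coverage[i] = number of starts in (i - read_length, i]
  cs <- cumsum(starts)
  lag <- pmax(seq_len(L) - config$read_length, 0L)
  coverage <- cs - c(0, cs)[lag + 1L]
  coverage_profile(reference_id, sequence, coverage, starts = starts)
}

#' Simulate fluorometric cleavage time courses
#'
#' Draws replicate traces from the integrated first-order rate equation
#' F(t) = Fmax * (1 - exp(-k t)) with additive homoscedastic Gaussian noise.
#'
#' @param f_max Presumed maximum fluorescence, percent (>= 0).
#' @param k Observed rate constant, per minute (>= 0).
#' @param times Non-negative, strictly increasing times in minutes.
#' @param noise_sd Gaussian noise s.d., percent units (0 gives the exact curve).
#' @param replicates Number of replicate traces.
#' @param seed Integer seed.
#' @param label Series label.
#' @return A `fluorescence_series`: list with `label`, `times`, and `values`
#'   (a replicates x times matrix).
#' @export
simulate_fluorescence <- function(f_max, k, times, noise_sd = 0,
                                  replicates = 1L, seed = 1L,
                                  label = "series") {
  if (f_max < 0 || k < 0) stop("f_max and k must be >= 0")
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  mu <- f_max * (1 - exp(-k * times))
  values <- matrix(rep(mu, each = replicates), nrow = replicates)
  if (noise_sd > 0)
    values <- values + matrix(stats::rnorm(replicates * length(times), 0, noise_sd),
                              nrow = replicates)
  structure(list(label = label, times = times, values = values),
            class = "fluorescence_series")
}

#' Generate a synthetic CDS set with known motif ground truth
#'
#' Generates `n_genes` coding sequences with lengths drawn (uniformly) from
#' multiples of 3 in `length_range` and i.i.d. bases from `composition`. A
#' `forced_zero_fraction` subset is scrubbed of every motif occurrence by
#' substituting the third base of each occurrence (G, or C when the base is
#' already G; neither substitution can create an A or complete a new motif)
#' and re-scanning until no occurrence remains, so those genes have K = 0 by
#' construction. The true motif count of every gene is returned alongside.
#'
#' @param n_genes Number of genes (0 allowed).
#' @param length_range Length range in nt; both ends multiples of 3, min >= 6.
#' @param composition Base probabilities (A, C, G, U).
#' @param forced_zero_fraction Fraction of genes scrubbed to K = 0.
#' @param motifs Character vector of recognition motifs.
#' @param seed Integer seed.
#' @return A data.frame with columns `locus_tag`, `product`, `sequence`,
#'   `K_true` (motif count of the returned sequence) and `forced_zero`.
#' @export
gen_cds_set <- function(n_genes, length_range = c(300L, 3000L),
                        composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                        forced_zero_fraction = 0,
                        motifs = mazf_nd1_motifs(), seed = 1L) {
  if (n_genes == 0)
    return(data.frame(locus_tag = character(), product = character(),
                      sequence = character(), K_true = integer(),
                      forced_zero = logical()))
  composition <- check_composition(composition)
  if (length_range[1] < 6) stop("minimum gene length must be >= 6")
  if (any(length_range %% 3 != 0)) stop("length_range must be multiples of 3")
  if (forced_zero_fraction < 0 || forced_zero_fraction > 1)
    stop("forced_zero_fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  codon_counts <- seq(length_range[1] %/% 3L, length_range[2] %/% 3L)
  lens <- 3L * codon_counts[sample.int(length(codon_counts), n_genes,
                                       replace = TRUE)]
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE, prob = composition),
          collapse = ""), character(1))
  n_zero <- round(forced_zero_fraction * n_genes)
  zero_idx <- if (n_zero > 0) sort(sample.int(n_genes, n_zero)) else integer()
  for (i in zero_idx) seqs[i] <- scrub_motifs(seqs[i], motifs, locus = i)
  forced <- seq_len(n_genes) %in% zero_idx
  data.frame(
    locus_tag = sprintf("SYN_%05d", seq_len(n_genes)),
    product = ifelse(forced, "synthetic protein (motif-scrubbed)",
                     "synthetic protein"),
    sequence = seqs,
    K_true = vapply(seqs, count_motifs, integer(1), motifs = motifs,
                    USE.NAMES = FALSE),
    forced_zero = forced
  )
}

# Remove all motif occurrences by single-base substitution of the third base
# of each occurrence (-> G, or -> C if already G), re-scanning until clean.
scrub_motifs <- function(sequence, motifs, locus = NA, max_iter = 100L) {
  m <- nchar(motifs[1])
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (iter in seq_len(max_iter)) {
    hits <- motif_match_starts(paste(chars, collapse = ""), motifs)
    if (length(hits) == 0) return(paste(chars, collapse = ""))
    third <- hits + 2L  # hits are 0-based starts; third base is offset +2
    chars[third + 1L] <- ifelse(chars[third + 1L] == "G", "C", "G")
  }
  stop("could not scrub motifs from gene ", locus,
       " within ", max_iter, " passes")
}
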