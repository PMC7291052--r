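#' Per-position coverage over one reference sequence
#'
#' @param reference_id Reference name.
#' @param sequence RNA string (T is converted to U).
#' @param coverage Non-negative integer vector, one value per position
#'   (0-based positions externally; element i of the vector is position i-1).
#' @param starts Optional per-position read-start counts (kept for
#'   coverage-conservation checks on simulated profiles).
#' @return A list of class `coverage_profile`.
#' @export
coverage_profile <- function(reference_id, sequence, coverage, starts = NULL) {
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  if (nchar(sequence) != length(coverage))
    stop("coverage length (", length(coverage),
         ") does not match sequence length (", nchar(sequence), ")")
  if (length(coverage) == 0) stop("empty profile")
  if (any(coverage < 0)) stop("coverage values must be >= 0")
  structure(list(reference_id = reference_id, sequence = sequence,
                 coverage = as.numeric(coverage), starts = starts),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile <", x$reference_id, ">: ", length(x$coverage),
      " nt, coverage ", min(x$coverage), "-", max(x$coverage), "\n", sep = "")
  invisible(x)
}

#' Relative coverage increase
#'
#' The cleavage-calling statistic: coverage at a position divided by the
#' coverage at the immediately former position. A step up marks a fragment
#' 5' end created by cleavage (and tagged by barcode ligation). Position 0
#' has no former position and positions whose former coverage is zero are
#' undefined; both are returned as NA and excluded from ranking.
#'
#' @param profile A [coverage_profile()].
#' @return Numeric vector of the same length as the profile (NA where
#'   undefined).
#' @export
relative_coverage_increase <- function(profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  cov <- profile$coverage
  prev <- c(NA_real_, cov[-length(cov)])
  rci <- cov / prev
  rci[!is.na(prev) & prev == 0] <- NA_real_
  rci[1] <- NA_real_
  rci
}

#' Call candidate cleavage sites from coverage profiles
#'
#' Candidate positions must have defined relative coverage increase and
#' coverage of at least `min_coverage` at both the position and its former
#' position (both enter the statistic). Candidates are ranked by rci across
#' all supplied profiles (a single pooled ranking) and the top `top_n` are
#' returned; ties are broken by reference id then position. Flanking
#' sequence from `up` nt upstream to `down` nt downstream is attached; calls
#' whose flank is truncated by a reference end are flagged.
#'
#' @param profiles A [coverage_profile()] or list of them.
#' @param min_coverage Minimum coverage for the position and its former
#'   position (default 5000).
#' @param top_n Number of top-ranked positions to keep (default 50).
#' @param up,down Flank extent in nt (default 5 each side).
#' @return A data.frame with columns `reference_id`, `position` (0-based),
#'   `coverage`, `former_coverage`, `rci`, `flank`, `truncated`, sorted by
#'   descending rci.
#' @export
call_sites <- function(profiles, min_coverage = 5000, top_n = 50,
                       up = 5L, down = 5L) {
  if (inherits(profiles, "coverage_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop("no profiles supplied")
  if (min_coverage < 0) stop("min_coverage must be >= 0")
  if (top_n < 1) stop("top_n must be >= 1")
  per <- lapply(profiles, function(p) {
    rci <- relative_coverage_increase(p)
    cov <- p$coverage
    prev <- c(NA_real_, cov[-length(cov)])
    keep <- which(!is.na(rci) & cov >= min_coverage & prev >= min_coverage)
    if (length(keep) == 0) return(NULL)
    fl <- vapply(keep - 1L, function(pos)
      extract_flank(p$sequence, pos, up = up, down = down), character(1))
    data.frame(reference_id = p$reference_id, position = keep - 1L,
               coverage = cov[keep], former_coverage = prev[keep],
               rci = rci[keep],
               flank = as.character(fl),
               truncated = vapply(keep - 1L, function(pos)
                 pos - up < 0 || pos + down > nchar(p$sequence) - 1L,
                 logical(1)))
  })
  calls <- do.call(rbind, per)
  if (is.null(calls))
    return(data.frame(reference_id = character(), position = integer(),
                      coverage = numeric(), former_coverage = numeric(),
                      rci = numeric(), flank = character(),
                      truncated = logical()))
  ord <- order(-calls$rci, calls$reference_id, calls$position)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  utils::head(calls, top_n)
}

#' Extract the flanking sequence around a called position
#'
#' Returns the substring from `up` nt upstream to `down` nt downstream of
#' the 0-based `position`, inclusive (11 nt with the defaults when both
#' fit). If the window falls off either reference end the available part is
#' returned with attribute `truncated = TRUE`; truncated flanks are excluded
#' from position-frequency matrices rather than padded, since padding would
#' bias column frequencies.
#'
#' @param sequence Reference sequence.
#' @param position 0-based position (offset 0 of the flank).
#' @param up,down Number of nt upstream/downstream.
#' @return Character scalar with attribute `truncated`.
#' @export
extract_flank <- function(sequence, position, up = 5L, down = 5L) {
  L <- nchar(sequence)
  if (position < 0 || position >= L) stop("position out of range")
  from <- max(position - up, 0L)
  to <- min(position + down, L - 1L)
  structure(substr(sequence, from + 1L, to + 1L),
            truncated = (position - up < 0) || (position + down > L - 1L))
}

#' Build a position-frequency matrix from aligned flanks
#'
#' Counts nucleotides per offset over flanks aligned on the called position
#' (offset 0), and computes per-column frequencies and information content
#' as 2 - Shannon entropy in bits (no small-sample correction). All flanks
#' must have the same length; with the default +/-5 nt flanks the offsets
#' run -5..+5.
#'
#' @param flanks Character vector of equal-length flanks (offset 0 at the
#'   centre position, i.e. element `up + 1`).
#' @param up Number of upstream offsets in the flanks (default 5).
#' @return A list of class `pfm` with `offsets`, `counts` (4 x width,
#'   rows A/C/G/U), `frequencies`, `information_content` (bits, per offset),
#'   `n_sequences`, and the contributing `flanks`.
#' @export
build_pfm <- function(flanks, up = 5L) {
  flanks <- as.character(flanks)
  if (length(flanks) == 0) stop("no flanks supplied")
  w <- unique(nchar(flanks))
  if (length(w) != 1) stop("all flanks must have the same length")
  offsets <- seq_len(w) - up - 1L
  mat <- do.call(rbind, strsplit(flanks, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j)
    c(A = sum(mat[, j] == "A"), C = sum(mat[, j] == "C"),
      G = sum(mat[, j] == "G"), U = sum(mat[, j] == "U")),
    numeric(4))
  colnames(counts) <- offsets
  freq <- sweep(counts, 2, colSums(counts), "/")
  ic <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(list(offsets = offsets, counts = counts, frequencies = freq,
                 information_content = ic, n_sequences = length(flanks),
                 flanks = flanks),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position-frequency matrix over", x$n_sequences, "flanks\n")
  print(rbind(x$counts, IC_bits = round(x$information_content, 2)))
  invisible(x)
}

#' Per-offset consensus of a PFM
#'
#' @param pfm A [build_pfm()] result.
#' @return Character vector of the plurality base at each offset.
#' @export
pfm_consensus <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  stats::setNames(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)],
                  pfm$offsets)
}

#' Tally candidate recognition motifs across flanks
#'
#' Enumerates the distinct 4-mers observed at the motif-bearing offsets of
#' each flank, with support counts sorted descending. The anchor window
#' defaults to offsets -1..+2: the called position (offset 0) is the first
#' nucleotide of the downstream fragment, i.e. the second A of an A|ACU-type
#' cut, so the recognition tetrad spans one position upstream of the call to
#' two downstream and the scissile bond lies between offsets -1 and 0.
#'
#' @param pfm A [build_pfm()] result (its stored flanks are used).
#' @param anchor_offsets Integer offsets of the motif window (default -1:2).
#' @return A data.frame with columns `motif` and `count`, sorted by
#'   decreasing count (ties alphabetically).
#' @export
consensus_motifs <- function(pfm, anchor_offsets = -1:2) {
  stopifnot(inherits(pfm, "pfm"))
  idx <- match(anchor_offsets, pfm$offsets)
  if (anyNA(idx)) stop("anchor_offsets outside the PFM offsets")
  if (any(diff(idx) != 1)) stop("anchor_offsets must be contiguous")
  words <- substr(pfm$flanks, min(idx), max(idx))
  tab <- sort(table(words), decreasing = TRUE)
  data.frame(motif = names(tab), count = as.integer(tab))
}
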