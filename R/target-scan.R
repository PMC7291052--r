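#' The MazF-nd1 recognition motifs
#'
#' The three tetrads the enzyme cleaves (between the two adenines):
#' AACU, AACG, AAUU.
#'
#' @return Character vector of the three motifs.
#' @export
mazf_nd1_motifs <- function() c("AACU", "AACG", "AAUU")

# 0-based start positions (overlaps allowed) where any motif matches.
motif_match_starts <- function(sequence, motifs) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  L <- nchar(s)
  m <- nchar(motifs[1])
  if (any(nchar(motifs) != m)) stop("motifs must all have the same length")
  if (L < m) return(integer())
  win <- substring(s, seq_len(L - m + 1L), m:L)
  which(win %in% motifs) - 1L
}

#' Count recognition-motif occurrences in a sequence
#'
#' K is the number of start positions at which any motif of the set matches;
#' occurrences may overlap one another. T is mapped to U before matching and
#' windows containing non-ACGU symbols never match.
#'
#' @param sequence Nucleotide string (DNA or RNA alphabet).
#' @param motifs Character vector of equal-length motifs.
#' @return Integer count K.
#' @examples
#' count_motifs("AAUUAACG") # 2
#' @export
count_motifs <- function(sequence, motifs = mazf_nd1_motifs()) {
  if (nchar(sequence) < nchar(motifs[1])) {
    warning("sequence shorter than motif length; K = 0")
    return(0L)
  }
  length(motif_match_starts(sequence, motifs))
}

#' Per-window motif probability from base composition
#'
#' The probability that a random window drawn from the given base
#' composition spells one of the motifs: the sum over motifs of the product
#' of their base frequencies. For the default motif set this reduces to the
#' closed form A^2 * C * (U + G) + A^2 * U^2.
#'
#' @param composition Fractions of A, C, G, U (sum to 1 within 1e-9).
#' @param motifs Character vector of motifs.
#' @return Probability p in [0, 1].
#' @examples
#' motif_probability(c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) # 3 * 0.25^4
#' @export
motif_probability <- function(composition, motifs = mazf_nd1_motifs()) {
  composition <- check_composition(composition)
  sum(vapply(strsplit(chartr("T", "U", toupper(motifs)), "", fixed = TRUE),
             function(b) prod(composition[b]), numeric(1)))
}

#' Base composition of a sequence
#'
#' Fractions of A, C, G, U (T counted as U). Non-ACGU symbols are excluded
#' from the denominator with a warning reporting how many were skipped.
#'
#' @param sequence Nucleotide string.
#' @return Named numeric vector (A, C, G, U) summing to 1.
#' @export
base_composition <- function(sequence) {
  chars <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "", fixed = TRUE)[[1]]
  n_bad <- sum(!chars %in% c("A", "C", "G", "U"))
  if (n_bad > 0)
    warning(n_bad, " non-ACGU symbol(s) excluded from composition")
  chars <- chars[chars %in% c("A", "C", "G", "U")]
  if (length(chars) == 0) stop("no ACGU bases in sequence")
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), U = sum(chars == "U"))
  counts / sum(counts)
}

#' Expected motif count in a CDS
#'
#' E = p * (L - 3): the number of 4-nt windows is treated as L - 3,
#' matching the statistic as originally defined for tetrad motifs.
#'
#' @param p Per-window motif probability.
#' @param L CDS length in bp (>= 3).
#' @return Expected count E.
#' @export
expected_count <- function(p, L) {
  if (any(L < 3)) stop("L must be >= 3")
  p * (L - 3)
}

#' Upper-tail binomial probability of the observed motif count
#'
#' P = sum_{i = K}^{n} C(n, i) p^i (1 - p)^(n - i) with n = L - 3 windows:
#' the probability of observing at least K motif occurrences if windows were
#' independent draws with probability p. Computed through the binomial
#' survival function (log-space internally), inclusive of K. K = 0 gives
#' P = 1. Small P flags genes with many more occurrences than expected
#' (MazF-sensitive); the window count n = L - 3 is kept for fidelity to the
#' original tetrad statistic (set `n_windows = L - m + 1` for other motif
#' lengths).
#'
#' @param K Observed motif count (0 <= K <= n).
#' @param L CDS length in bp.
#' @param p Per-window motif probability.
#' @param n_windows Number of windows treated as trials (default L - 3).
#' @return Tail probability P in [0, 1].
#' @export
binomial_tail <- function(K, L, p, n_windows = L - 3) {
  n <- n_windows
  if (any(K < 0) || any(K > n)) stop("K must be in [0, n_windows]")
  if (any(p < 0) || any(p > 1)) stop("p must be in [0, 1]")
  stats::pbinom(K - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Score a CDS set for MazF sensitivity
#'
#' For each gene: base composition from the gene's own sequence, per-window
#' motif probability p, observed count K, expected count E = p (L - 3), and
#' the upper-tail binomial probability P. Genes are returned sorted by
#' ascending P (ties by locus tag). Empty or non-ACGU-only sequences are
#' skipped with a warning.
#'
#' @param genes A data.frame with columns `locus_tag`, `sequence`, and
#'   optionally `product`.
#' @param motifs Character vector of motifs.
#' @return A data.frame with columns `locus_tag`, `product`, `L`, `K`, `p`,
#'   `E`, `P`.
#' @export
score_genes <- function(genes, motifs = mazf_nd1_motifs()) {
  if (nrow(genes) == 0) stop("no genes supplied")
  if (is.null(genes$product)) genes$product <- ""
  ok <- nzchar(genes$sequence) &
    grepl("[ACGTUacgtu]", genes$sequence)
  if (any(!ok))
    warning(sum(!ok), " gene(s) skipped (empty or no ACGU bases): ",
            paste(utils::head(genes$locus_tag[!ok], 5), collapse = ", "))
  genes <- genes[ok, , drop = FALSE]
  L <- nchar(genes$sequence)
  K <- vapply(genes$sequence, count_motifs, integer(1), motifs = motifs,
              USE.NAMES = FALSE)
  p <- vapply(genes$sequence, function(s)
    motif_probability(base_composition(s), motifs), numeric(1),
    USE.NAMES = FALSE)
  scores <- data.frame(locus_tag = genes$locus_tag, product = genes$product,
                       L = L, K = K, p = p, E = p * (L - 3),
                       P = binomial_tail(K, L, p))
  scores <- scores[order(scores$P, scores$locus_tag), , drop = FALSE]
  rownames(scores) <- NULL
  scores
}

#' Top MazF-sensitive genes
#'
#' The genes with the smallest binomial tail probabilities P (observed motif
#' count most in excess of expectation).
#'
#' @param scores A [score_genes()] result.
#' @param top_n Number of genes to return (default 25).
#' @return The `top_n` rows with smallest P (ascending, ties by locus tag).
#' @export
sensitive_genes <- function(scores, top_n = 25) {
  scores <- scores[order(scores$P, scores$locus_tag), , drop = FALSE]
  rownames(scores) <- NULL
  utils::head(scores, top_n)
}

#' MazF-tolerant genes
#'
#' Exactly the genes lacking any recognition-motif occurrence (K = 0);
#' their transcripts cannot be cleaved by the enzyme.
#'
#' @param scores A [score_genes()] result.
#' @return The rows with K = 0.
#' @export
tolerant_genes <- function(scores) {
  out <- scores[scores$K == 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
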