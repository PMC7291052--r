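# Packaged reference tables for MazF-nd1: the fluorometric probe panel, the
# reported kinetic characterization of each probe, and the reported
# sensitive/tolerant gene tables for the Nitrospira strain ND1 genome. These
# are inputs to the analysis (generating parameters for simulations and
# worked examples for the binomial statistic), not outputs of this package.

nd1_table <- function(name) {
  path <- system.file("extdata", name, package = "mazfkit", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}

#' Fluorometric probe panel for MazF-nd1
#'
#' The 17 dual-labelled DNA/RNA chimeric oligonucleotides used to assay
#' cleavage of each candidate tetrad (lowercase = DNA, uppercase = RNA;
#' a FRET dye pair flanks each probe so fluorescence rises on cleavage),
#' plus the all-DNA and motif-free RNA negative-control probes.
#'
#' @return A data.frame with columns `name`, `sequence`.
#' @export
nd1_probe_panel <- function() nd1_table("nd1_probe_panel.tsv")

#' Reported kinetic characterization of the MazF-nd1 probe panel
#'
#' Per candidate tetrad: its occurrence count in the five substrate RNAs of
#' the sequencing assay, and the reported initial reaction velocity `v0`
#' (percent/min), `f_max` (percent) and rate constant `k` (per min) from
#' fitting the integrated first-order rate equation.
#'
#' @return A data.frame with columns `sequence`,
#'   `occurrence_in_substrates`, `v0`, `f_max`, `k`.
#' @export
nd1_reported_kinetics <- function() nd1_table("nd1_reported_kinetics.tsv")

#' Reported top-25 MazF-nd1-sensitive genes
#'
#' The 25 Nitrospira strain ND1 coding sequences with the smallest binomial
#' tail probabilities P, with their length `L` (bp), observed motif count
#' `K` and expected count `E`. Used as worked examples: p can be
#' reconstructed per row as E / (L - 3).
#'
#' @return A data.frame with columns `rank`, `locus_tag`, `product`, `L`,
#'   `K`, `E`, `P`.
#' @export
nd1_reported_sensitive_genes <- function() nd1_table("nd1_sensitive_genes.tsv")

#' Reported annotated MazF-nd1-tolerant genes
#'
#' The 18 annotated Nitrospira strain ND1 coding sequences lacking any
#' recognition-motif occurrence (K = 0).
#'
#' @return A data.frame with columns `locus_tag`, `product`, `L`.
#' @export
nd1_reported_tolerant_genes <- function() nd1_table("nd1_tolerant_genes.tsv")
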