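#' Read a FASTA file
#'
#' Headers are split at the first whitespace into an id and a description
#' (used as the product annotation for CDS sets). Sequences are uppercased;
#' line wrapping is ignored. Duplicate ids are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `desc`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(data.frame(id = character(), desc = character(),
                      sequence = character()))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id))
    stop("duplicate FASTA id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  data.frame(id = id, desc = desc,
             sequence = toupper(as.character(set)), row.names = NULL)
}

#' Write sequences to a FASTA file
#'
#' @param df A data.frame with columns `id`, `sequence` and optionally
#'   `desc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path) {
  set <- Biostrings::BStringSet(df$sequence)
  desc <- if (!is.null(df$desc)) ifelse(nzchar(df$desc),
                                        paste(df$id, df$desc), df$id) else df$id
  names(set) <- desc
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write coverage profiles as TSV
#'
#' Three tab-separated columns with a header: `reference`, `position`
#' (0-based), `coverage`.
#'
#' @param profiles A [coverage_profile()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(profiles, path) {
  if (inherits(profiles, "coverage_profile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(reference = p$reference_id,
               position = seq_along(p$coverage) - 1L,
               coverage = p$coverage)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read coverage profiles from TSV, joining reference sequences
#'
#' Expects the 3-column format of [write_coverage_tsv()]. Positions missing
#' from the table are filled with zero coverage (with a warning); positions
#' at or beyond the reference length, or references absent from `references`,
#' are errors.
#'
#' @param path Path to the coverage TSV.
#' @param references A data.frame as returned by [read_fasta()].
#' @return A list of [coverage_profile()] objects, one per reference present
#'   in the table.
#' @export
read_coverage_tsv <- function(path, references) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("reference", "position", "coverage")
  if (!all(need %in% names(tab)))
    stop("coverage TSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$reference), function(d) {
    rid <- d$reference[1]
    i <- match(rid, references$id)
    if (is.na(i)) stop("unknown reference id in coverage TSV: ", rid)
    L <- nchar(references$sequence[i])
    if (any(d$position < 0) || any(d$position >= L))
      stop("position out of range for reference ", rid)
    cov <- numeric(L)
    cov[d$position + 1L] <- d$coverage
    if (nrow(d) < L)
      warning(L - nrow(d), " position(s) missing for reference ", rid,
              "; filled with 0")
    coverage_profile(rid, references$sequence[i], cov)
  })
}

#' Write fluorescence series as long-format TSV
#'
#' Columns: `time_min`, `replicate`, `value`, `series_label`.
#'
#' @param series_list A `fluorescence_series` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fluorescence_tsv <- function(series_list, path) {
  if (inherits(series_list, "fluorescence_series")) series_list <- list(series_list)
  tab <- do.call(rbind, lapply(series_list, function(s) {
    nrep <- nrow(s$values)
    data.frame(time_min = rep(s$times, each = nrep),
               replicate = rep(seq_len(nrep), times = length(s$times)),
               value = as.vector(s$values),
               series_label = s$label)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fluorescence series from long-format TSV
#'
#' @param path Path to a TSV written by [write_fluorescence_tsv()].
#' @return A named list of `fluorescence_series`.
#' @export
read_fluorescence_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("time_min", "replicate", "value", "series_label")
  if (!all(need %in% names(tab)))
    stop("fluorescence TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$series_label), function(d) {
    times <- sort(unique(d$time_min))
    reps <- sort(unique(d$replicate))
    values <- matrix(NA_real_, nrow = length(reps), ncol = length(times))
    values[cbind(match(d$replicate, reps), match(d$time_min, times))] <- d$value
    if (anyNA(values))
      stop("replicates of series ", d$series_label[1],
           " do not share the time grid")
    structure(list(label = d$series_label[1], times = times, values = values),
              class = "fluorescence_series")
  })
  out
}
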