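#' Default run configuration
#'
#' Parameters of a full pipeline run. The defaults reproduce the settings
#' of the original characterization: coverage filter 5000, top 50 cleavage
#' calls, +/-5 nt flanks, fivefold velocity separation, motif set
#' AACU/AACG/AAUU, top 25 sensitive genes, fluorescence sampled every 80 s
#' (4/3 min) for 2 h in triplicate.
#'
#' @param seed Master seed; each stage derives its own sub-seed from it.
#' @param n_references Number of synthetic substrate RNAs.
#' @param reference_length Length of each substrate (nt).
#' @param sites_per_reference Planted cleavage sites per substrate.
#' @param min_coverage,top_n,up,down Cleavage-calling parameters.
#' @param fold_threshold Velocity fold separation for primary motifs.
#' @param motifs Recognition motif set.
#' @param top_sensitive Number of top sensitive genes to report.
#' @param n_genes Synthetic CDS count.
#' @param forced_zero_fraction Fraction of CDS scrubbed to K = 0.
#' @param times Fluorescence time grid, minutes.
#' @param noise_sd Fluorescence noise s.d. (percent).
#' @param replicates Fluorescence replicates.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_references = 5L, reference_length = 1000L,
                       sites_per_reference = 4L, min_coverage = 5000,
                       top_n = 50L, up = 5L, down = 5L, fold_threshold = 5,
                       motifs = mazf_nd1_motifs(), top_sensitive = 25L,
                       n_genes = 1000L, forced_zero_fraction = 0.1,
                       times = seq(0, 120, by = 4 / 3), noise_sd = 2,
                       replicates = 3L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stage tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes the three stages end to end with known ground truth: (1)
#' simulate substrate RNAs with planted cleavage sites, call sites and build
#' the flank PFM and candidate-motif tally; (2) simulate the fluorometric
#' probe panel from the packaged kinetic parameters, normalize, fit and rank
#' motifs; (3) generate a synthetic CDS set, score it with the binomial
#' statistic and extract sensitive and tolerant genes. All stage tables are
#' written as TSV under `out_dir` together with a JSON manifest (parameters,
#' seeds, input checksums, package version).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## stage 1: cleavage mapping on simulated coverage
  scfg <- sim_config(seed = derive_seed(config$seed, "coverage"),
                     depth = 35000, read_length = 150L)
  refs <- list()
  truth <- list()
  for (i in seq_len(config$n_references)) {
    rid <- sprintf("SYNRNA-%d", i)
    rseed <- derive_seed(config$seed, paste0("ref", i))
    seq0 <- gen_random_rna(config$reference_length, seed = rseed)
    set.seed(derive_seed(config$seed, paste0("sites", i)))
    pos <- sample(seq(50L, config$reference_length - 50L,
                      by = 12L), config$sites_per_reference)
    pos <- sort(pos)
    seq1 <- plant_motifs(seq0, "AACU", pos - 1L)  # cut site = second A
    rcfg <- scfg
    rcfg$seed <- derive_seed(config$seed, paste0("cov", i))
    prof <- simulate_cleavage_coverage(
      seq1, planted_sites(pos, efficiency = 0.005), rcfg, reference_id = rid)
    refs[[rid]] <- prof
    truth[[rid]] <- data.frame(reference = rid, position = pos)
  }
  calls <- call_sites(refs, min_coverage = config$min_coverage,
                      top_n = config$top_n, up = config$up, down = config$down)
  pfm <- build_pfm(calls$flank[!calls$truncated], up = config$up)
  motifs_tally <- consensus_motifs(pfm)

  fasta_path <- file.path(out_dir, "substrates.fasta")
  write_fasta(data.frame(id = names(refs),
                         sequence = vapply(refs, `[[`, "", "sequence")),
              fasta_path)
  cov_path <- file.path(out_dir, "coverage.tsv")
  write_coverage_tsv(refs, cov_path)
  utils::write.table(do.call(rbind, truth), file.path(out_dir, "planted_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls, file.path(out_dir, "cleavage_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(offset = pfm$offsets, t(pfm$counts),
               IC_bits = pfm$information_content, check.names = FALSE),
    file.path(out_dir, "pfm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(motifs_tally, file.path(out_dir, "candidate_motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 2: kinetics of the probe panel (simulated from reported parameters)
  kin <- nd1_reported_kinetics()
  pos_level <- 1000; neg_level <- 100  # raw fluorescence units
  series <- lapply(seq_len(nrow(kin)), function(i) {
    s <- simulate_fluorescence(
      kin$f_max[i], kin$k[i], config$times, noise_sd = config$noise_sd,
      replicates = config$replicates,
      seed = derive_seed(config$seed, paste0("fluor", kin$sequence[i])),
      label = paste0("DR-14-", kin$sequence[i]))
    s$values <- neg_level + s$values / 100 * (pos_level - neg_level)
    s
  })
  controls <- list(
    structure(list(label = "RNase-positive", times = config$times,
                   values = matrix(pos_level, config$replicates,
                                   length(config$times))),
              class = "fluorescence_series"),
    structure(list(label = "no-enzyme", times = config$times,
                   values = matrix(neg_level, config$replicates,
                                   length(config$times))),
              class = "fluorescence_series"))
  fluor_path <- file.path(out_dir, "fluorescence.tsv")
  write_fluorescence_tsv(c(series, controls), fluor_path)
  fits <- do.call(rbind, lapply(series, function(s) {
    norm <- normalize_percent(s, positive_mean = pos_level,
                              negative_mean = neg_level)
    fit <- fit_exponential(norm$times, norm$percent)
    data.frame(label = s$label, motif = sub("^DR-14-", "", s$label),
               f_max = fit$f_max, k = fit$k, v0 = fit$v0, rss = fit$rss,
               n_points = fit$n_points, converged = fit$converged)
  }))
  ranking <- rank_motifs(fits$motif, fits$v0,
                         fold_threshold = config$fold_threshold)
  utils::write.table(fits, file.path(out_dir, "kinetic_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    rbind(cbind(ranking$primary, class = "primary"),
          cbind(ranking$suboptimal, class = "suboptimal")),
    file.path(out_dir, "motif_ranking.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: genome scan on a synthetic CDS set
  cds <- gen_cds_set(config$n_genes,
                     forced_zero_fraction = config$forced_zero_fraction,
                     motifs = config$motifs,
                     seed = derive_seed(config$seed, "cds"))
  cds_path <- file.path(out_dir, "cds.fasta")
  if (nrow(cds) > 0)
    write_fasta(data.frame(id = cds$locus_tag, desc = cds$product,
                           sequence = cds$sequence), cds_path)
  scores <- score_genes(cds, motifs = config$motifs)
  utils::write.table(scores, file.path(out_dir, "gene_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sensitive_genes(scores, config$top_sensitive),
                     file.path(out_dir, "sensitive_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tolerant_genes(scores),
                     file.path(out_dir, "tolerant_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## manifest
  params <- unclass(config)
  params$motifs <- paste(params$motifs, collapse = ",")
  params$times <- sprintf("seq(0, %g, by = %g)", max(config$times),
                          config$times[2] - config$times[1])
  inputs <- c(fasta_path, cov_path, fluor_path,
              if (file.exists(cds_path)) cds_path)
  manifest <- list(
    package = "mazfkit",
    version = as.character(utils::packageVersion("mazfkit")),
    seed = config$seed,
    parameters = params,
    input_checksums = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(profiles = refs, truth = do.call(rbind, truth),
                 calls = calls, pfm = pfm, motifs = motifs_tally,
                 fits = fits, ranking = ranking, cds = cds, scores = scores,
                 manifest = manifest))
}
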