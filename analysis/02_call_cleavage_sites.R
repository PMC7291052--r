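#!/usr/bin/env Rscript
# Stage 1: call cleavage sites from the simulated coverage profiles with the
# relative-coverage-increase statistic (coverage filter 5000, global top 50),
# build the flank position-frequency matrix and tally candidate tetrads.

suppressPackageStartupMessages(library(mazfkit))

ind <- "results/synthetic"
out <- "results/cleavage_map"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

refs <- read_fasta(file.path(ind, "substrates.fasta"))
profiles <- read_coverage_tsv(file.path(ind, "coverage.tsv"), refs)
truth <- read.delim(file.path(ind, "planted_sites.tsv"))

calls <- call_sites(profiles, min_coverage = 5000, top_n = 50)
write.table(calls, file.path(out, "cleavage_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

recall <- mean(paste(truth$reference, truth$position) %in%
                 paste(calls$reference_id, calls$position))
message(nrow(calls), " calls; recall of planted sites among them: ",
        sprintf("%.2f", recall))

pfm <- build_pfm(calls$flank[!calls$truncated])
write.table(data.frame(offset = pfm$offsets, t(pfm$counts),
                       IC_bits = round(pfm$information_content, 3),
                       check.names = FALSE),
            file.path(out, "pfm.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("consensus at offsets -1..+2: ",
        paste(pfm_consensus(pfm)[c("-1", "0", "1", "2")], collapse = ""),
        " (IC ", paste(round(pfm$information_content[c("-1", "0", "1", "2")], 2),
                       collapse = "/"), " bits)")

tally <- consensus_motifs(pfm)
write.table(tally, file.path(out, "candidate_motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("top candidate tetrads: ",
        paste(sprintf("%s (%d)", head(tally$motif, 3), head(tally$count, 3)),
              collapse = ", "))
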