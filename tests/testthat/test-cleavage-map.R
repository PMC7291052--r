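profile_from <- function(coverage, sequence = NULL, id = "r") {
  if (is.null(sequence)) sequence <- strrep("G", length(coverage))
  coverage_profile(id, sequence, coverage)
}

test_that("relative coverage increase is the ratio to the former position", {
  expect_equal(relative_coverage_increase(profile_from(c(100, 100, 100))),
               c(NA, 1, 1))
  expect_equal(relative_coverage_increase(profile_from(c(5000, 20000)))[2], 4)
  expect_true(is.na(relative_coverage_increase(profile_from(c(0, 50)))[2]))
  expect_error(coverage_profile("r", "", numeric(0)), "empty")
})

test_that("rci telescopes to a coverage ratio when no zeros intervene", {
  set.seed(1)
  cov <- sample(1000:2000, 50)
  rci <- relative_coverage_increase(profile_from(cov))
  for (a in c(1, 10, 25)) {
    b <- 50
    expect_equal(prod(rci[(a + 1):b]), cov[b] / cov[a])
  }
})

test_that("call_sites filters on both positions and ranks by rci", {
  expect_identical(nrow(call_sites(profile_from(c(100, 400, 4000)))), 0L)

  calls <- call_sites(profile_from(c(6000, 6000, 24000, 24000)))
  expect_identical(nrow(calls), 3L)
  expect_identical(calls$position[1], 2L)  # 0-based index of the jump
  expect_equal(calls$rci[1], 4)
  expect_equal(calls$former_coverage[1], 6000)

  # both numerator and denominator must pass the coverage filter
  calls2 <- call_sites(profile_from(c(4000, 24000, 24000)))
  expect_false(1L %in% calls2$position)

  # fewer candidates than top_n returns all; top_n truncates
  expect_identical(nrow(call_sites(profile_from(rep(8000, 10)), top_n = 50)), 9L)
  expect_identical(nrow(call_sites(profile_from(rep(8000, 10)), top_n = 4)), 4L)
})

test_that("call_sites is invariant under uniform coverage scaling", {
  set.seed(2)
  cov <- sample(6000:9000, 100)
  a <- call_sites(profile_from(cov), top_n = 20)
  b <- call_sites(profile_from(cov * 3), top_n = 20)
  expect_identical(a$position, b$position)
  expect_equal(a$rci, b$rci)
})

test_that("pooled ranking across references uses a single global top-N", {
  p1 <- profile_from(c(6000, 12000, 12000), id = "a")   # rci 2 at pos 1
  p2 <- profile_from(c(6000, 30000, 30000), id = "b")   # rci 5 at pos 1
  calls <- call_sites(list(p1, p2), top_n = 2)
  expect_identical(calls$reference_id[1], "b")
  expect_identical(calls$reference_id[2], "a")
  # ties broken by reference id then position
  p3 <- profile_from(c(6000, 12000, 12000), id = "c")
  tied <- call_sites(list(p3, p1), top_n = 10)
  same <- tied[tied$rci == 2, ]
  expect_identical(same$reference_id, c("a", "c"))
})

test_that("extract_flank returns the inclusive window and flags truncation", {
  s <- "GGGGGAACUGGGGG"
  # direct-indexing oracle: 0-based position 6, up/down 5 -> chars 2..12
  expect_identical(as.character(extract_flank(s, 6)), substr(s, 2, 12))
  expect_identical(nchar(extract_flank(s, 6)), 11L)
  expect_false(attr(extract_flank(s, 6), "truncated"))
  expect_true(attr(extract_flank(s, 2), "truncated"))
  expect_identical(as.character(extract_flank(s, 2)), substr(s, 1, 8))
  expect_identical(as.character(extract_flank(s, 3, up = 0, down = 0)), "G")
  expect_error(extract_flank(s, 20), "out of range")
})

test_that("build_pfm counts, frequencies and information content are exact", {
  pure <- build_pfm(rep(flank_with_motif("AACU"), 10))
  expect_true(all(abs(pure$information_content - 2) < 1e-12))
  expect_true(all(colSums(pure$counts) == 10))
  expect_identical(pure$offsets, -5:5)

  mixed <- build_pfm(c(rep(flank_with_motif("AACU"), 5),
                       rep(flank_with_motif("AAUU"), 5)))
  # motif occupies offsets -1..+2: pure A at -1 and 0, pure U at +2
  expect_equal(mixed$frequencies["A", "-1"], 1)
  expect_equal(mixed$frequencies["A", "0"], 1)
  expect_equal(mixed$frequencies["U", "2"], 1)
  expect_equal(mixed$information_content[["1"]], 1)  # C/U split at +1
  expect_identical(unname(pfm_consensus(mixed)[c("-1", "0", "2")]),
                   c("A", "A", "U"))

  uniform <- build_pfm(c("A", "C", "G", "U"), up = 0)
  expect_equal(uniform$information_content[["0"]], 0)

  expect_error(build_pfm(character()), "no flanks")
  expect_error(build_pfm(c("AAA", "AAAA")), "same length")
})

test_that("consensus_motifs tallies anchor-window words by support", {
  pfm <- build_pfm(c(rep(flank_with_motif("AACU"), 15),
                     rep(flank_with_motif("AAUU"), 9)))
  tally <- consensus_motifs(pfm)
  expect_identical(tally$motif[1:2], c("AACU", "AAUU"))
  expect_identical(tally$count[1:2], c(15L, 9L))

  one <- consensus_motifs(build_pfm(rep(flank_with_motif("AACU"), 7)))
  expect_identical(nrow(one), 1L)
  expect_identical(one$count, 7L)
  expect_error(consensus_motifs(build_pfm("GGGGGAACUGG"), anchor_offsets = 6:9),
               "outside")
})

test_that("planted cleavage sites are recovered among the top calls", {
  cfg <- sim_config(seed = 101, read_length = 150, depth = 35000,
                    background_rate = 0.01, amplification = 100)
  profiles <- list()
  truth <- character()
  for (i in 1:5) {
    rid <- paste0("r", i)
    seq0 <- gen_random_rna(1000, seed = 200 + i)
    pos <- seq(100L, 900L, length.out = 4)
    pos <- as.integer(round(pos))
    seq1 <- plant_motifs(seq0, "AACU", pos - 1L)
    rcfg <- cfg
    rcfg$seed <- 300 + i
    profiles[[rid]] <- simulate_cleavage_coverage(
      seq1, planted_sites(pos, efficiency = 0.005), rcfg, reference_id = rid)
    truth <- c(truth, paste(rid, pos))
  }
  calls <- call_sites(profiles, top_n = 50)
  recall <- mean(truth %in% paste(calls$reference_id, calls$position))
  expect_gte(recall, 0.9)
  # the planted-site flanks read AACU at the motif window
  hit <- calls[paste(calls$reference_id, calls$position) %in% truth, ]
  expect_true(all(substr(hit$flank, 5, 8) == "AACU"))
})
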