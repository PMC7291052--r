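test_that("gen_random_rna respects composition, length and seed", {
  expect_identical(gen_random_rna(10, c(1, 0, 0, 0), seed = 3), "AAAAAAAAAA")
  expect_error(gen_random_rna(0), "length")
  expect_error(gen_random_rna(10, c(0.5, 0.5, 0.5, 0.5)), "1\\.5|sum")

  s <- gen_random_rna(1e4, seed = 11)
  a_frac <- lengths(regmatches(s, gregexpr("A", s))) / 1e4
  expect_lt(abs(a_frac - 0.25), 0.02)

  expect_identical(gen_random_rna(500, seed = 5), gen_random_rna(500, seed = 5))
  expect_false(gen_random_rna(500, seed = 5) == gen_random_rna(500, seed = 6))
})

test_that("plant_motifs substitutes in place and rejects bad windows", {
  expect_identical(plant_motifs("GGGGGGGG", "AACU", 2), "GGAACUGG")
  expect_identical(plant_motifs("GGGG", "AACU", 0), "AACU")
  expect_error(plant_motifs("GGGGG", "AACU", 2), "out of range")
  expect_error(plant_motifs("GGGGGGGGGG", "AACU", c(2, 4)), "overlap")
  planted <- plant_motifs(strrep("G", 20), "AACU", c(0, 8, 16))
  expect_identical(nchar(planted), 20L)
  expect_identical(count_motifs(planted, "AACU"), 3L)
})

test_that("simulated coverage matches the read model exactly in degenerate cases", {
  cfg0 <- sim_config(seed = 1, read_length = 3, depth = 10, background_rate = 0)
  prof0 <- simulate_cleavage_coverage(strrep("G", 30), planted_sites(integer(0)),
                                      cfg0)
  expect_true(all(prof0$coverage == 0))

  # one fully efficient site, no background: coverage exactly on [p, p+3)
  p0 <- 10L
  prof1 <- simulate_cleavage_coverage(strrep("G", 30), planted_sites(p0, 1),
                                      cfg0)
  expect_true(all(prof1$coverage[(p0 + 1):(p0 + 3)] > 0))
  expect_true(all(prof1$coverage[-((p0 + 1):(p0 + 3))] == 0))

  # truncation at the sequence end
  prof2 <- simulate_cleavage_coverage(strrep("G", 12), planted_sites(11L, 1),
                                      cfg0)
  expect_true(prof2$coverage[12] > 0)
  expect_identical(sum(prof2$coverage > 0), 1L)
})

test_that("planted sites produce a large relative coverage increase", {
  cfg <- sim_config(seed = 42, read_length = 50, depth = 1000,
                    background_rate = 0.01, amplification = 100)
  seqs <- gen_random_rna(500, seed = 42)
  prof <- simulate_cleavage_coverage(seqs, planted_sites(250L, 0.5), cfg)
  rci <- relative_coverage_increase(prof)
  expect_gt(rci[251], 10)  # 0-based position 250
  # recompute from the retained read-start list
  expect_equal(rci[251], sum(prof$starts[(250 - 49 + 1):(250 + 1)]) /
                 sum(prof$starts[(250 - 49):250]))
})

test_that("coverage is conserved against the read-start list", {
  cfg <- sim_config(seed = 9, read_length = 20, depth = 100,
                    background_rate = 0.05)
  prof <- simulate_cleavage_coverage(gen_random_rna(200, seed = 9),
                                     planted_sites(c(50L, 120L), 0.3), cfg)
  expect_equal(prof$coverage,
               naive_coverage_from_starts(prof$starts, cfg$read_length))
  # total coverage = sum over reads of covered length
  L <- length(prof$starts)
  covered <- pmin(cfg$read_length, L - seq_len(L) + 1L)
  expect_equal(sum(prof$coverage), sum(prof$starts * covered))
})

test_that("simulate_fluorescence follows the rate equation exactly at zero noise", {
  s0 <- simulate_fluorescence(80, 0.05, c(0, 1, 2), noise_sd = 0, seed = 1)
  expect_equal(s0$values[1, 1], 0)
  s_inf <- simulate_fluorescence(80, 0.05, c(0, 1000), noise_sd = 0, seed = 1)
  expect_equal(s_inf$values[1, 2], 80, tolerance = 1e-10)
  # direct evaluation with the reported AACU parameters at t = 20 min
  s20 <- simulate_fluorescence(85.67, 7.50e-2, c(0, 20), noise_sd = 0, seed = 1)
  expect_equal(s20$values[1, 2], 85.67 * (1 - exp(-1.5)), tolerance = 1e-12)
  expect_equal(round(s20$values[1, 2], 2), 66.55)
  expect_error(simulate_fluorescence(80, 0.05, c(-1, 0)), "non-negative")
})

test_that("fluorescence replicates and seeds behave deterministically", {
  a <- simulate_fluorescence(80, 0.05, 0:10, noise_sd = 2, replicates = 3, seed = 4)
  b <- simulate_fluorescence(80, 0.05, 0:10, noise_sd = 2, replicates = 3, seed = 4)
  expect_identical(a, b)
  expect_identical(dim(a$values), c(3L, 11L))
  expect_false(identical(a$values[1, ], a$values[2, ]))
})

test_that("gen_cds_set honours forced-zero construction and motif expectation", {
  all_zero <- gen_cds_set(20, forced_zero_fraction = 1, seed = 2)
  expect_true(all(all_zero$K_true == 0))
  expect_true(all(vapply(all_zero$sequence, count_motifs, integer(1)) == 0))
  expect_true(all(nchar(all_zero$sequence) %% 3 == 0))

  expect_identical(nrow(gen_cds_set(0)), 0L)

  # mean K under uniform composition ~ p * (L - 3), p = 3/4^4
  cds <- gen_cds_set(1000, length_range = c(999, 999), seed = 8)
  expect_identical(unique(nchar(cds$sequence)), 999L)
  expected <- 996 * 3 * 0.25^4
  expect_lt(abs(mean(cds$K_true) / expected - 1), 0.10)
  # ground-truth K column agrees with direct counting
  idx <- c(1, 500, 1000)
  expect_identical(cds$K_true[idx],
                   vapply(cds$sequence[idx], naive_count_motifs, 0L,
                          motifs = mazf_nd1_motifs(), USE.NAMES = FALSE))
})

test_that("generators are reproducible for identical configs and seeds", {
  cfg <- sim_config(seed = 77, read_length = 30, depth = 500)
  p1 <- simulate_cleavage_coverage(gen_random_rna(300, seed = 77),
                                   planted_sites(150L, 0.4), cfg)
  p2 <- simulate_cleavage_coverage(gen_random_rna(300, seed = 77),
                                   planted_sites(150L, 0.4), cfg)
  expect_identical(p1, p2)
  expect_identical(gen_cds_set(5, seed = 3), gen_cds_set(5, seed = 3))
})
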