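# aCGH arm: normalisation, smoothing, CBS against an exhaustive oracle,
# state thresholds and level merging.

test_that("median normalisation and duplicate averaging", {
  pr <- data.frame(chrom = "chr1", position = c(1:5 * 100, 300),
                   probe_id = c(paste0("p", 1:5), "p3"),
                   log2_ratio = c(1, 1, 0.2, 1, 1, 0.4))
  out <- normalise_probes(pr)
  expect_equal(nrow(out), 5)
  med <- median(c(1, 1, 0.3, 1, 1))
  expect_equal(out$log2_ratio[out$probe_id == "p3"], 0.3 - med)
  # constant profile -> all zero
  prc <- data.frame(chrom = "chr1", position = 1:7 * 10,
                    probe_id = paste0("q", 1:7), log2_ratio = 0.8)
  expect_true(all(normalise_probes(prc)$log2_ratio == 0))
  # 101 probes with known median
  set.seed(2)
  v <- c(sort(runif(50, -1, 0.34)), 0.35, sort(runif(50, 0.36, 2)))
  pr101 <- data.frame(chrom = "chr1", position = seq_along(v) * 10,
                      probe_id = paste0("r", seq_along(v)), log2_ratio = v)
  expect_equal(median(normalise_probes(pr101)$log2_ratio), 0)
})

test_that("outlier smoothing: identity, isolated spike, simulation rates", {
  smooth_prof <- data.frame(chrom = "chr1", position = 1:50 * 10,
                            probe_id = paste0("p", 1:50),
                            log2_ratio = sin(1:50 / 8) * 0.1)
  expect_equal(smooth_outliers(smooth_prof), smooth_prof)

  spike <- data.frame(chrom = "chr1", position = 1:21 * 10,
                      probe_id = paste0("p", 1:21),
                      log2_ratio = c(rep(0, 10), 5, rep(0, 10)))
  sm <- smooth_outliers(spike)
  expect_lt(sm$log2_ratio[11], 5)
  expect_equal(sm$log2_ratio[-11], spike$log2_ratio[-11])

  sim <- simulate_acgh(cnv_sim_config(
    chrom_lengths = c(chr1 = 5e7), probe_spacing = 1e4,
    planted_segments = NULL, noise_sd = 0.2,
    outlier_rate = 0.01, outlier_magnitude = 2, seed = 3))
  sm <- smooth_outliers(sim$probes)
  is_out <- sim$probes$probe_id %in% sim$truth$outlier_probes
  attenuated <- abs(sm$log2_ratio[is_out]) < abs(sim$probes$log2_ratio[is_out])
  expect_gte(mean(attenuated), 0.9)
  altered_clean <- sm$log2_ratio[!is_out] != sim$probes$log2_ratio[!is_out]
  expect_lt(mean(altered_clean), 0.01)
})

test_that("CBS max statistic agrees with the exhaustive all-pairs oracle", {
  set.seed(7)
  for (trial in 1:15) {
    n <- sample(8:50, 1)
    x <- rnorm(n) + rep(c(0, sample(c(0, 1, 3), 1)), c(n %/% 2, n - n %/% 2))
    got <- tyroflow:::.cbs_max_stat(x, 2L)
    want <- oracle_cbs_stat(x, 2)
    expect_equal(got$stat, want$stat, tolerance = 1e-10)
    # an arc and its complement carry the same statistic (circular
    # symmetry), so compare the induced interior breakpoint set
    cuts <- function(ij) setdiff(unlist(ij), c(0, n))
    expect_setequal(cuts(got[c("i", "j")]), cuts(want[c("i", "j")]))
  }
})

test_that("flat zero-noise genome yields exactly one segment per chromosome", {
  sim <- simulate_acgh(cnv_sim_config(
    chrom_lengths = c(chr1 = 2e6, chr2 = 2e6), probe_spacing = 1e4,
    planted_segments = NULL, noise_sd = 0, outlier_rate = 0, seed = 1))
  seg <- suppressMessages(cbs_segment(sim$probes, n_permutations = 200,
                                      seed = 2))
  expect_equal(nrow(seg), 2)
  expect_true(all(seg$seg_mean == 0))
})

test_that("zero-noise step at probe 500 of 1000 is found exactly", {
  x <- c(rep(0, 500), rep(log2(20), 500))
  pr <- data.frame(chrom = "chr1", position = 1:1000 * 1000,
                   probe_id = paste0("p", 1:1000), log2_ratio = x)
  seg <- cbs_segment(pr, n_permutations = 200, seed = 3)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_probes, c(500L, 500L))
  expect_equal(seg$seg_mean, c(0, log2(20)), tolerance = 1e-12)
  expect_equal(seg$end[1], 500 * 1000)
})

test_that("segmentation is deterministic and conserves the probe mean", {
  sim <- simulate_acgh(cnv_sim_config(
    chrom_lengths = c(chr1 = 3e6), probe_spacing = 1e4,
    planted_segments = data.frame(chrom = "chr1", start = 1e6 + 1,
                                  end = 1.5e6, fold_change = 8),
    noise_sd = 0.2, outlier_rate = 0, seed = 11))
  seg1 <- cbs_segment(sim$probes, n_permutations = 300, seed = 5)
  seg2 <- cbs_segment(sim$probes, n_permutations = 300, seed = 5)
  expect_identical(seg1, seg2)
  wmean <- sum(seg1$seg_mean * seg1$n_probes) / sum(seg1$n_probes)
  expect_equal(wmean, mean(sim$probes$log2_ratio), tolerance = 1e-9)
})

test_that("breakpoints of a planted amplification recover within +/- 2 probes", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_acgh(cnv_sim_config(
      chrom_lengths = c(chr1 = 5e6), probe_spacing = 25000,
      planted_segments = data.frame(chrom = "chr1", start = 2500001,
                                    end = 3000000, fold_change = 20),
      noise_sd = 0.2, outlier_rate = 0, seed = 600 + s))
    seg <- cbs_segment(sim$probes, n_permutations = 300, seed = 700 + s)
    amp <- seg[which.max(seg$seg_mean), ]
    first <- match(amp$start, sim$probes$position)
    last <- match(amp$end, sim$probes$position)
    tr <- sim$truth$segments
    abs(first - tr$probe_first) <= 2 && abs(last - tr$probe_last) <= 2
  }, NA)
  expect_true(all(hits))
})

test_that("state thresholds follow the -0.5 / 0.5 / 1.5 plateau rules exactly", {
  seg <- data.frame(sample = "t", chrom = "chr1", start = 1, end = 10,
                    n_probes = 5,
                    seg_mean = c(-0.6, -0.5, 0, 0.5, 0.50001, 1.0, 1.5,
                                 1.50001, log2(20)))
  cs <- classify_segments(seg)
  expect_identical(cs$state,
                   c("deletion", "neutral", "neutral", "neutral",
                     "amplification", "amplification", "amplification",
                     "high_amplification", "high_amplification"))
  expect_equal(cs$fold_change[9], 20, tolerance = 1e-12)
})

test_that("level merging: single level, hand-computed two-level case, recovery", {
  seg <- data.frame(sample = "t", chrom = "c", start = 1, end = 2,
                    n_probes = c(10, 10, 10),
                    seg_mean = c(0.0, 0.02, 4.3))
  ml <- merge_levels(classify_segments(seg), merge_delta = 0.1)
  expect_equal(sort(unique(ml$level)), c(1, 2))
  expect_equal(attr(ml, "plateaus"), c(0.01, 4.3), tolerance = 1e-12)
  expect_equal(ml$level, c(1, 1, 2))

  near0 <- data.frame(sample = "t", chrom = "c", start = 1, end = 2,
                      n_probes = 5, seg_mean = c(-0.05, 0.02, 0.08))
  expect_equal(unique(merge_levels(classify_segments(near0), 0.2)$level), 1)

  # 3 planted copy states recovered as 3 levels at low noise
  lv <- vapply(1:5, function(s) {
    sim <- simulate_acgh(cnv_sim_config(
      chrom_lengths = c(chr1 = 4e6), probe_spacing = 1e4,
      planted_segments = data.frame(chrom = "chr1",
                                    start = c(1e6 + 1, 3e6 + 1),
                                    end = c(1.5e6, 3.5e6),
                                    fold_change = c(4, 20)),
      noise_sd = 0.1, outlier_rate = 0, seed = 800 + s))
    seg <- cbs_segment(sim$probes, n_permutations = 300, seed = 900 + s)
    max(merge_levels(classify_segments(seg))$level)
  }, 0)
  expect_true(all(lv == 3))
})

test_that("a short chromosome yields a single logged segment", {
  pr <- data.frame(chrom = "chr9", position = 1:3 * 100,
                   probe_id = paste0("p", 1:3), log2_ratio = c(0, 5, 0))
  expect_message(seg <- cbs_segment(pr, min_width = 2, seed = 1),
                 "short_chromosome")
  expect_equal(nrow(seg), 1)
})
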