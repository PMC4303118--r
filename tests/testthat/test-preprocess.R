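# Filtering, spike-in normalisation, site collapse, presence filtering and
# conditional imputation.

test_that("localization filter is inclusive at the threshold and counts", {
  rec <- make_evidence("s1", sprintf("P%d", 1:20), 1:20, 100,
                       loc_prob = c(rep(0.9, 14), rep(0.5, 4), 0.75, 0.7499))
  rec$is_contaminant[1:2] <- TRUE
  out <- suppressMessages(filter_evidence(rec))
  # 20 rows, 2 contaminants out, then 4 at 0.5 and 1 at 0.7499 out; 0.75 kept
  expect_equal(nrow(out), 13)
  expect_true("P19" %in% out$protein_id)    # loc_prob == 0.75 retained
  expect_false("P20" %in% out$protein_id)   # 0.7499 removed
  expect_false(any(out$is_contaminant))
})

test_that("spike-in factors: identity, hand-computed 2x case, idempotence", {
  # two samples, three standards; sample B uniformly 2x sample A
  base <- c(A1 = 5e6, A2 = 5e5, A3 = 1e7)
  rec <- rbind(
    make_evidence("sA", names(base), 1, unname(base), spikein = TRUE),
    make_evidence("sB", names(base), 1, unname(base) * 2, spikein = TRUE),
    make_evidence(c("sA", "sB"), "P1", 10, c(100, 100)))
  fac <- compute_spikein_factors(rec)
  # dividing by the factors must equalise spike-ins across samples
  norm_a <- base / fac$factors[["sA"]]
  norm_b <- base * 2 / fac$factors[["sB"]]
  expect_equal(norm_a, norm_b, tolerance = 1e-12)
  expect_equal(fac$factors[["sB"]] / fac$factors[["sA"]], 2,
               tolerance = 1e-12)

  # identical spike-ins across samples -> all factors 1
  rec_eq <- rbind(
    make_evidence("sA", names(base), 1, unname(base), spikein = TRUE),
    make_evidence("sB", names(base), 1, unname(base), spikein = TRUE))
  expect_equal(unname(compute_spikein_factors(rec_eq)$factors), c(1, 1),
               tolerance = 1e-12)

  # idempotence: factors of an already-normalised table are all 1
  rec_norm <- rec
  sp <- rec_norm$is_spikein
  rec_norm$raw_intensity <- rec_norm$raw_intensity /
    fac$factors[rec_norm$sample_id]
  fac2 <- compute_spikein_factors(rec_norm)
  expect_equal(unname(fac2$factors), c(1, 1), tolerance = 1e-9)

  # hard errors
  expect_error(compute_spikein_factors(
    make_evidence("sA", "P1", 10, 100)), "without spike-in")
})

test_that("factors recover planted per-sample scale factors (Spearman >= 0.95)", {
  sim <- simulate_phospho(phospho_sim_config(seed = 7))
  ev <- suppressMessages(filter_evidence(sim$evidence))
  fac <- compute_spikein_factors(ev, sim$spikeins)
  rho <- cor(fac$factors,
             sim$truth$sample_scale_factors[names(fac$factors)],
             method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("collapse_to_sites sums then logs, tracks missing cells", {
  classes <- c(s1 = "a", s2 = "a", s3 = "b")
  rec <- rbind(
    make_evidence("s1", "P1", 10, 1000),            # single row -> 3.0
    make_evidence("s2", "P1", 10, c(400, 600)),     # sum -> 3.0
    make_evidence("s1", sprintf("P%d", 2:5), 10, 10),
    make_evidence("s2", sprintf("P%d", 2:4), 10, 10),
    make_evidence("s3", sprintf("P%d", 1:4), 10, 10))
  mat <- collapse_to_sites(rec, NULL, classes)
  expect_equal(mat$values["P1_Y10", "s1"], 3.0)
  expect_equal(mat$values["P1_Y10", "s2"], 3.0)
  expect_equal(dim(mat), c(5L, 3L))
  expect_equal(sum(!mat$observed), 2)   # P5 in s2, P5 in s3
  # max aggregation alternative
  mat_max <- collapse_to_sites(rec, NULL, classes, aggregate = "max")
  expect_equal(mat_max$values["P1_Y10", "s2"], log10(600))
})

test_that("presence_threshold reproduces the at-least-75% rule", {
  expect_identical(presence_threshold(8, 0.75), 6L)
  expect_identical(presence_threshold(5, 0.75), 4L)
  expect_identical(presence_threshold(1, 0.75), 1L)
  expect_identical(presence_threshold(8, 1), 8L)
})

test_that("reproducible_sites matches brute force and is monotone", {
  set.seed(21)
  m <- make_885_matrix(80)
  holes <- matrix(runif(length(m$values)) < 0.35, nrow(m$values))
  m$values[holes] <- NA
  m <- py_matrix(m$values, m$classes)

  # spec worked examples
  counts <- t(sapply(seq_len(80), function(i)
    tapply(m$observed[i, ], m$classes, sum)))
  for (fr in c(0.5, 0.75, 0.9)) {
    got <- suppressMessages(reproducible_sites(m, fr))
    want <- m$sites[
      counts[, "p53"] >= ceiling(fr * 8) |
        counts[, "PyMT"] >= ceiling(fr * 8) |
        counts[, "Her2"] >= ceiling(fr * 5)]
    expect_setequal(got, want)
  }
  # monotone: raising fraction never grows the set
  s50 <- suppressMessages(reproducible_sites(m, 0.5))
  s75 <- suppressMessages(reproducible_sites(m, 0.75))
  s90 <- suppressMessages(reproducible_sites(m, 0.9))
  expect_true(all(s75 %in% s50))
  expect_true(all(s90 %in% s75))
})

test_that("a site seen in 6/8 of one class only is retained, 5/8+5/8+3/5 is not", {
  vals <- matrix(NA_real_, 2, 21,
                 dimnames = list(c("PA_Y1", "PB_Y1"), paste0("s", 1:21)))
  classes <- setNames(rep(c("p53", "PyMT", "Her2"), c(8, 8, 5)),
                      colnames(vals))
  vals[1, 1:6] <- 5                          # 6/8 p53 only
  vals[2, c(1:5, 9:13, 17:19)] <- 5          # 5/8, 5/8, 3/5
  m <- py_matrix(vals, classes)
  expect_identical(suppressMessages(reproducible_sites(m)), "PA_Y1")
})

test_that("imputation routes by the strict >50% rule, tags provenance", {
  set.seed(31)
  n <- 21
  vals <- matrix(rnorm(8 * n, 6), 8, n,
                 dimnames = list(sprintf("P%d_Y1", 1:8), paste0("s", 1:n)))
  classes <- setNames(rep(c("a", "b", "c"), c(8, 8, 5)), colnames(vals))
  vals[1, 1:10] <- NA   # observed in 11  -> knn (11/21 > 0.5)
  vals[2, 1:11] <- NA   # observed in 10  -> fallback (10/21 <= 0.5)
  m <- py_matrix(vals, classes)
  for (fb in c("row_min", "col_mean")) {
    mi <- suppressMessages(impute(m, k = 3, fallback = fb))
    expect_true(all(mi$provenance[1, 1:10] == "knn"))
    expect_true(all(mi$provenance[2, 1:11] == fb))
    expect_true(all(mi$provenance[3:8, ] == "measured"))
    # observed cells never altered
    expect_equal(mi$values[m$observed], m$values[m$observed])
    expect_false(any(is.na(mi$values)))
    if (fb == "row_min")
      expect_equal(unique(mi$values[2, 1:11]), min(vals[2, ], na.rm = TRUE))
    if (fb == "col_mean")
      expect_equal(mi$values[2, 1], mean(vals[m$observed[, 1], 1]))
  }
  # complete site stays untouched
  m0 <- make_885_matrix(4)
  mi0 <- impute(m0)
  expect_identical(mi0$values, m0$values)
  expect_true(all(mi0$provenance == "measured"))
  # zero-observation site cannot fall back with row_min
  vals[2, ] <- NA
  expect_error(impute(py_matrix(vals, classes), fallback = "row_min"),
               "zero observations")
})

test_that("k-NN exactly recovers held-out cells on rank-1 (replicated-row) data", {
  set.seed(41)
  n_samp <- 21
  v <- sort(runif(n_samp, 5, 8))
  coef <- rep(c(1, 1.5, 2, 3), each = 20)       # rows proportional: c_i * v
  vals <- outer(coef, v)
  dimnames(vals) <- list(sprintf("P%03d_Y1", seq_along(coef)),
                         paste0("s", 1:n_samp))
  classes <- setNames(rep(c("a", "b", "c"), c(8, 8, 5)), colnames(vals))
  truth <- vals
  holes <- matrix(runif(length(vals)) < 0.10, nrow(vals))
  vals[holes] <- NA
  mi <- suppressMessages(impute(py_matrix(vals, classes), k = 10,
                                fallback = "row_min"))
  knn_cells <- mi$provenance == "knn"
  expect_gt(sum(knn_cells), 0)
  expect_equal(mi$values[knn_cells], truth[knn_cells], tolerance = 1e-6)
})

test_that("impute respects the routing invariant on simulated data", {
  sim <- simulate_phospho(phospho_sim_config(n_sites = 120, seed = 17))
  ev <- suppressMessages(filter_evidence(sim$evidence))
  fac <- compute_spikein_factors(ev, sim$spikeins)
  mat <- collapse_to_sites(ev, fac, sim$truth$classes)
  mi <- suppressMessages(impute(mat))
  n_obs <- rowSums(mat$observed)
  for (i in seq_len(nrow(mat$values))) {
    imp <- mi$provenance[i, !mat$observed[i, ]]
    if (!length(imp)) next
    if (n_obs[i] > ncol(mat$values) / 2) {
      expect_true(all(imp %in% c("knn", "col_mean")))
    } else {
      expect_true(all(imp == "row_min"))
    }
  }
})
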