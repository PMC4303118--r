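# Two-step random forest. Forests here are kept small (150-500 trees):
# the contracts under test (separability, determinism, monotonicity,
# OOB calibration) are insensitive to tree count at these sizes.

# Perfectly separable 3-class data: disjoint marker families with large
# offsets, plus uninformative background sites.
make_separable <- function(n_noise = 30, marker_per_class = 3, seed = 1) {
  set.seed(seed)
  classes <- setNames(rep(c("p53", "PyMT", "Her2"), c(8, 8, 5)),
                      paste0("s", 1:21))
  n_mark <- marker_per_class * 3
  vals <- matrix(rnorm((n_noise + n_mark) * 21, 6, 0.3), n_noise + n_mark, 21)
  rownames(vals) <- c(sprintf("MARK%d_Y%d", seq_len(n_mark), 100),
                      sprintf("NOISE%d_Y%d", seq_len(n_noise), 100))
  colnames(vals) <- names(classes)
  markers <- split(rownames(vals)[seq_len(n_mark)],
                   rep(c("p53", "PyMT", "Her2"), each = marker_per_class))
  for (cl in names(markers))
    vals[markers[[cl]], classes == cl] <-
      vals[markers[[cl]], classes == cl] + 4   # huge, noiseless separation
  list(mat = make_pym(vals, classes), markers = markers)
}

test_that("separable data: step-2 OOB = 0 and all marker families selected", {
  sep <- make_separable(seed = 3)
  model <- suppressMessages(train_two_step(sep$mat, n_trees = 300, seed = 5))
  expect_equal(model$step2_oob_error, 0)
  for (cl in names(sep$markers))
    expect_gt(length(intersect(model$selected_sites, sep$markers[[cl]])), 0)
  expect_true(all(apply(model$importances[model$selected_sites, , drop = FALSE],
                        1, max) > model$threshold))
})

test_that("training is deterministic under a fixed seed and sample order", {
  sep <- make_separable(seed = 7)
  m1 <- suppressMessages(train_two_step(sep$mat, n_trees = 150, seed = 9))
  m2 <- suppressMessages(train_two_step(sep$mat, n_trees = 150, seed = 9))
  expect_identical(m1$selected_sites, m2$selected_sites)
  expect_identical(m1$importances, m2$importances)
  expect_identical(m1$step2_oob_error, m2$step2_oob_error)
  # permuting sample order leaves the model unchanged
  perm <- sample(ncol(sep$mat$values))
  mat_p <- py_matrix(sep$mat$values[, perm], sep$mat$classes[perm])
  m3 <- suppressMessages(train_two_step(mat_p, n_trees = 150, seed = 9))
  expect_identical(m1$selected_sites, m3$selected_sites)
})

test_that("raising the threshold never enlarges the selection", {
  sep <- make_separable(seed = 11)
  m_lo <- suppressMessages(train_two_step(sep$mat, threshold = 0.5,
                                          n_trees = 150, seed = 13))
  m_hi <- suppressMessages(train_two_step(sep$mat, threshold = 2.5,
                                          n_trees = 150, seed = 13))
  expect_true(all(m_hi$selected_sites %in% m_lo$selected_sites))
  expect_error(suppressMessages(train_two_step(sep$mat, threshold = 101,
                                               n_trees = 50, seed = 1)),
               "threshold")
})

test_that("pure-noise OOB error shows no skill beyond the majority baseline", {
  # Analytic floor: on label-independent features no classifier beats the
  # majority-class predictor, so OOB error cannot sit meaningfully below
  # 1 - 8/21. At n = 21 the OOB estimate is additionally pessimistic (each
  # held-out sample's own neighbourhood is depleted in its class), so the
  # observed error lies at or above the baseline rather than at it; the same
  # upward bias is exhibited by the reference implementations at this n.
  baseline <- 1 - 8 / 21   # always predict a largest class
  errs <- vapply(1:12, function(s) {
    m <- make_885_matrix(50, sd = 1, seed = 100 + s)
    set.seed(s)
    rf <- random_forest(t(m$values), m$classes, n_trees = 150,
                        importance = FALSE)
    rf$oob_error
  }, 0)
  expect_gte(mean(errs), baseline - 0.1)
  expect_lte(mean(errs), 0.9)   # still in the chance regime, not degenerate
})

test_that("prediction: resubstitution bound, single-sample, holdout consistency", {
  sep <- make_separable(seed = 17)
  model <- suppressMessages(train_two_step(sep$mat, n_trees = 200, seed = 19))
  pr <- predict(model, sep$mat)
  acc <- mean(pr$labels == sep$mat$classes[names(pr$labels)])
  expect_gte(acc, 1 - model$step2_oob_error)
  expect_equal(unname(rowSums(pr$votes)), rep(1, ncol(sep$mat$values)))
  # single training sample keeps its own label on separable data
  one <- sep$mat$values[, 3, drop = FALSE]
  expect_equal(unname(predict(model, one)$labels),
               unname(sep$mat$classes[3]))
  # missing selected sites are reported
  short <- sep$mat$values[-match(model$selected_sites[1],
                                 rownames(sep$mat$values)), ]
  expect_error(predict(model, short), "lacks selected site")

  # held-out data from the same generator, new seeds
  accs <- vapply(1:6, function(s) {
    hold <- make_separable(seed = 300 + s)
    pr <- predict(model, hold$mat)
    mean(pr$labels == hold$mat$classes[names(pr$labels)])
  }, 0)
  expect_lt(abs(mean(accs) - (1 - model$step2_oob_error)), 0.1)
})

test_that("selected sites beat random site subsets of equal size (OOB)", {
  sep <- make_separable(n_noise = 60, seed = 23)
  model <- suppressMessages(train_two_step(sep$mat, n_trees = 150, seed = 25))
  k <- length(model$selected_sites)
  set.seed(27)
  rand_oob <- replicate(8, {
    sub <- sample(rownames(sep$mat$values), k)
    rf <- random_forest(t(sep$mat$values[sub, , drop = FALSE]),
                        sep$mat$classes, n_trees = 150, importance = FALSE)
    rf$oob_error
  })
  expect_lte(model$step2_oob_error, mean(rand_oob))
})

test_that("signature recovery at the paper-scale design across seeds", {
  frac_planted <- vapply(1:3, function(s) {
    sim <- simulate_phospho(phospho_sim_config(n_sites = 120,
                                               seed = 400 + s))
    ev <- suppressMessages(filter_evidence(sim$evidence))
    fac <- compute_spikein_factors(ev, sim$spikeins)
    mat <- collapse_to_sites(ev, fac, sim$truth$classes)
    mi <- suppressMessages(impute(subset_sites(
      mat, suppressMessages(reproducible_sites(mat)))))
    model <- suppressMessages(train_two_step(mi, n_trees = 300,
                                             seed = 500 + s))
    mean(model$selected_sites %in% unlist(sim$truth$specific_sites))
  }, 0)
  expect_gte(mean(frac_planted), 0.8)
})

test_that("model serialises to JSON with its reproducibility parameters", {
  sep <- make_separable(seed = 29)
  model <- suppressMessages(train_two_step(sep$mat, n_trees = 100, seed = 31))
  f <- tempfile(fileext = ".json")
  write_signature(model, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$selected_sites, model$selected_sites)
  expect_equal(back$seed, model$seed)
  expect_equal(back$step2_oob_error, model$step2_oob_error)
})
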