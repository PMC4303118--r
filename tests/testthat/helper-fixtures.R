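# Fixture builders and independent oracles shared across test files.
# All fixtures are constructed in code; nothing is read from disk except
# files the tests themselves write to tempdir().

# -- evidence rows ----------------------------------------------------------
make_evidence <- function(sample_id, protein_id, position, intensity,
                          gene_symbol = protein_id, residue = "Y",
                          loc_prob = 1, spikein = FALSE,
                          contaminant = FALSE, reverse = FALSE) {
  n <- max(lengths(list(sample_id, protein_id, position, intensity)))
  data.frame(sample_id = rep_len(sample_id, n),
             protein_id = rep_len(protein_id, n),
             gene_symbol = rep_len(gene_symbol, n),
             residue = rep_len(residue, n),
             position = as.integer(rep_len(position, n)),
             localization_prob = rep_len(loc_prob, n),
             raw_intensity = rep_len(intensity, n),
             is_spikein = rep_len(spikein, n),
             is_contaminant = rep_len(contaminant, n),
             is_reverse = rep_len(reverse, n),
             stringsAsFactors = FALSE)
}

# -- py_matrix from a plain matrix ------------------------------------------
make_pym <- function(values, classes, observed = !is.na(values)) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%05d_Y%d", seq_len(nrow(values)), 100)
  if (is.null(colnames(values)))
    colnames(values) <- names(classes) %||%
      paste0("s", seq_len(ncol(values)))
  if (is.null(names(classes))) names(classes) <- colnames(values)
  py_matrix(values, classes = classes, observed = observed)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# A complete random matrix with the study's 8/8/5 class layout.
make_885_matrix <- function(n_sites, sd = 0.25, baseline = 7, seed = 1) {
  set.seed(seed)
  classes <- setNames(rep(c("p53", "PyMT", "Her2"), c(8, 8, 5)),
                      paste0("s", 1:21))
  vals <- matrix(rnorm(n_sites * 21, baseline, sd), n_sites, 21,
                 dimnames = list(sprintf("P%05d_Y100", seq_len(n_sites)),
                                 names(classes)))
  make_pym(vals, classes)
}

# -- independent oracles ----------------------------------------------------

# Ordinary pooled-variance t for contrast a - b under the one-way model,
# coded independently of fit_moderated_contrasts.
oracle_pooled_t <- function(x, classes, a, b) {
  cls <- unique(classes)
  resid <- x
  for (cl in cls) {
    cols <- classes == cl
    resid[, cols] <- x[, cols] - rowMeans(x[, cols, drop = FALSE])
  }
  s2 <- rowSums(resid^2) / (ncol(x) - length(cls))
  na <- sum(classes == a); nb <- sum(classes == b)
  diff <- rowMeans(x[, classes == a, drop = FALSE]) -
    rowMeans(x[, classes == b, drop = FALSE])
  diff / sqrt(s2 * (1 / na + 1 / nb))
}

# Exhaustive hypergeometric upper-tail p by enumerating every n-subset of an
# N-element universe whose first K elements are "in the set".
oracle_hyper_enum <- function(N, K, n, k) {
  subs <- combn(N, n)
  hits <- colSums(subs <= K)
  mean(hits >= k)
}

# Adjusted Rand index between two label vectors.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Brute-force 3-set Venn region counts by per-element membership enumeration.
oracle_venn <- function(sets) {
  items <- unique(unlist(sets))
  nm <- names(sets)
  counts <- setNames(integer(7), c(
    nm, paste(nm[1], nm[2], sep = "&"), paste(nm[1], nm[3], sep = "&"),
    paste(nm[2], nm[3], sep = "&"), paste(nm, collapse = "&")))
  for (it in items) {
    inset <- vapply(sets, function(s) it %in% s, NA)
    key <- paste(nm[inset], collapse = "&")
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Brute-force maximal circular two-segment t over all arcs, mirroring the
# definition but written independently of the C++ code.
oracle_cbs_stat <- function(x, min_width = 2) {
  n <- length(x)
  best <- -Inf; bi <- NA; bj <- NA
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    k <- j - i
    if (k < min_width || n - k < min_width) next
    arc <- sum(x[(i + 1):j])
    rest <- sum(x) - arc
    t <- abs(arc / k - rest / (n - k)) / sqrt(1 / k + 1 / (n - k))
    if (t > best) { best <- t; bi <- i; bj <- j }
  }
  list(stat = best, i = bi, j = bj)
}
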