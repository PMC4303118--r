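## From evidence records to the filtered, spike-in-normalised, imputed
## site x sample log10 matrix that all downstream statistics consume.

#' Site-by-sample log10 intensity matrix
#'
#' Lightweight container for a pY-site quantitation matrix: `values` holds
#' log10 intensities (NA where missing), `observed` marks measured cells, and
#' `provenance` tags every cell as `measured`, `knn`, `row_min` or `col_mean`
#' once imputation has run. `classes` maps each sample to its tumour class.
#'
#' @param values numeric matrix, sites in rows (rownames = site keys),
#'   samples in columns (colnames = sample ids)
#' @param classes named character vector, one class label per sample
#' @param observed logical matrix, defaults to `!is.na(values)`
#' @param provenance character matrix of per-cell tags
#' @return object of class `py_matrix`
#' @export
py_matrix <- function(values, classes,
                      observed = !is.na(values),
                      provenance = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  classes <- classes[colnames(values)]
  if (any(is.na(classes)))
    tf_stop("class labels must cover all samples", "tyroflow_config_error")
  if (is.null(provenance)) {
    provenance <- matrix(ifelse(observed, "measured", NA_character_),
                         nrow = nrow(values), dimnames = dimnames(values))
  }
  structure(list(values = values, observed = observed,
                 provenance = provenance,
                 sites = rownames(values), samples = colnames(values),
                 classes = classes),
            class = "py_matrix")
}

#' @export
print.py_matrix <- function(x, ...) {
  cat(sprintf("py_matrix: %d pY sites x %d samples (%d classes: %s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$classes)),
              paste(sort(unique(x$classes)), collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(!x$observed),
              100 * mean(!x$observed)))
  invisible(x)
}

#' @export
dim.py_matrix <- function(x) dim(x$values)

#' Filter evidence records on quality flags and localization probability
#'
#' Removes contaminant and reversed-match rows, then rows below the minimum
#' localization probability (threshold inclusive: a row at exactly
#' `min_loc_prob` is retained). Spike-in standard rows are exempt from the
#' localization filter (synthetic standards carry no localisation ambiguity)
#' but not from the flag filters. Removal counts are logged.
#'
#' @param records evidence data.frame from [read_evidence()]
#' @param min_loc_prob minimum localization probability, default 0.75
#' @return filtered records
#' @export
filter_evidence <- function(records, min_loc_prob = 0.75) {
  n0 <- nrow(records)
  flagged <- records$is_contaminant | records$is_reverse
  records <- records[!flagged, , drop = FALSE]
  low <- !records$is_spikein & (is.na(records$localization_prob) |
                                  records$localization_prob < min_loc_prob)
  records <- records[!low, , drop = FALSE]
  tf_log("preprocess", "filter_evidence", input = n0,
         removed_flagged = sum(flagged), removed_loc = sum(low),
         retained = nrow(records))
  if (!nrow(records)) warning("no evidence rows survive filtering")
  rownames(records) <- NULL
  records
}

#' Per-sample normalisation factors from spike-in standards
#'
#' Each sample receives a multiplicative factor: the geometric mean over
#' standards of (observed intensity in this sample / across-sample geometric
#' mean reference of that standard). Dividing a sample's raw intensities by
#' its factor equalises spike-in intensities across samples. The geometric
#' mean makes the factor robust to one aberrant standard.
#'
#' @param records evidence records (spike-in rows are identified by
#'   `is_spikein`; the `protein_id` of those rows names the standard)
#' @param spikein_amounts optional data.frame from [read_spikeins()]; used
#'   only to restrict to declared standards
#' @return list with `factors` (named per sample), and `standards`, a
#'   data.frame of per-sample per-standard observed intensities
#' @export
compute_spikein_factors <- function(records, spikein_amounts = NULL) {
  sp <- records[records$is_spikein, , drop = FALSE]
  if (!is.null(spikein_amounts))
    sp <- sp[sp$protein_id %in% spikein_amounts$standard, , drop = FALSE]
  samples <- unique(records$sample_id)
  missing_sp <- setdiff(samples, unique(sp$sample_id))
  if (length(missing_sp))
    tf_stop(paste0("sample(s) without spike-in observations: ",
                   paste(missing_sp, collapse = ", ")),
            "tyroflow_normalisation_error")
  if (any(sp$raw_intensity <= 0, na.rm = TRUE) || any(is.na(sp$raw_intensity)))
    tf_stop("zero/absent spike-in intensity", "tyroflow_normalisation_error")
  ag <- aggregate(raw_intensity ~ sample_id + protein_id, data = sp, FUN = sum)
  ref <- tapply(log(ag$raw_intensity), ag$protein_id, mean)  # log of geo-mean
  lratio <- log(ag$raw_intensity) - ref[ag$protein_id]
  fac <- exp(tapply(lratio, ag$sample_id, mean))
  fac <- setNames(as.numeric(fac), names(fac))   # strip 1-d array dim
  list(factors = fac[samples],
       standards = ag[order(ag$sample_id, ag$protein_id), ])
}

#' Collapse normalised evidence to a site x sample log10 matrix
#'
#' All non-spike-in evidence rows mapping to one (site, sample) are combined
#' (sum by default, MaxQuant's convention for features of one peptide; `max`
#' selectable) after division by the per-sample normalisation factor; the
#' combined intensity is log10-transformed. Cells with no rows are missing.
#'
#' @param records filtered evidence records
#' @param factors per-sample factors from [compute_spikein_factors()], or a
#'   named numeric vector; `NULL` for no normalisation
#' @param classes named character vector mapping sample id to class label
#' @param aggregate one of `"sum"`, `"max"`
#' @return a [py_matrix()]
#' @export
collapse_to_sites <- function(records, factors, classes,
                              aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  if (is.list(factors)) factors <- factors$factors
  rec <- records[!records$is_spikein, , drop = FALSE]
  samples <- names(classes)
  if (is.null(samples)) tf_stop("classes must be named by sample id",
                                "tyroflow_config_error")
  keys <- site_key(rec$protein_id, rec$residue, rec$position)
  sites <- sort(unique(keys))
  norm <- rec$raw_intensity
  if (!is.null(factors)) {
    miss <- setdiff(unique(rec$sample_id), names(factors))
    if (length(miss)) tf_stop(paste0("no normalisation factor for sample(s): ",
                                     paste(miss, collapse = ", ")),
                              "tyroflow_normalisation_error")
    norm <- norm / factors[rec$sample_id]
  }
  vals <- matrix(NA_real_, length(sites), length(samples),
                 dimnames = list(sites, samples))
  fun <- if (aggregate == "sum") sum else max
  agg <- tapply(norm, list(factor(keys, sites),
                           factor(rec$sample_id, samples)), fun)
  filled <- !is.na(agg)
  vals[filled] <- log10(agg[filled])
  py_matrix(vals, classes = classes)
}

#' Minimum sample count for the presence filter
#'
#' "Detected in at least `fraction` of the class's samples" means at least
#' `ceiling(fraction * n_samples)` samples: 6 of 8, 4 of 5 at the default 75%.
#'
#' @param n_samples samples in the class
#' @param fraction required fraction, default 0.75
#' @return integer threshold
#' @export
presence_threshold <- function(n_samples, fraction = 0.75) {
  stopifnot(n_samples >= 1, fraction > 0, fraction <= 1)
  as.integer(ceiling(fraction * n_samples))
}

#' Reproducibly detected pY sites
#'
#' A site is kept if it was observed in at least
#' `presence_threshold(n_c, fraction)` samples of at least one class `c`.
#'
#' @param mat a [py_matrix()]
#' @param fraction per-class presence fraction, default 0.75
#' @return character vector of retained site keys
#' @export
reproducible_sites <- function(mat, fraction = 0.75) {
  stopifnot(inherits(mat, "py_matrix"))
  keep <- rep(FALSE, length(mat$sites))
  for (cl in unique(mat$classes)) {
    cols <- which(mat$classes == cl)
    thr <- presence_threshold(length(cols), fraction)
    keep <- keep | rowSums(mat$observed[, cols, drop = FALSE]) >= thr
  }
  tf_log("preprocess", "reproducible_sites", input = length(mat$sites),
         retained = sum(keep), fraction = fraction)
  mat$sites[keep]
}

#' Subset a py_matrix to given sites
#' @param mat a [py_matrix()]
#' @param sites site keys to keep (order preserved)
#' @return a [py_matrix()]
#' @export
subset_sites <- function(mat, sites) {
  stopifnot(all(sites %in% mat$sites))
  py_matrix(mat$values[sites, , drop = FALSE], classes = mat$classes,
            observed = mat$observed[sites, , drop = FALSE],
            provenance = mat$provenance[sites, , drop = FALSE])
}

#' Conditional imputation of missing intensities
#'
#' Sites observed in strictly more than 50% of all samples have their gaps
#' filled by k-nearest-neighbour imputation over sites (neighbours are the
#' `k` sites, observed in the target sample, with smallest Euclidean distance
#' on mutually observed samples; the imputed value is their unweighted mean in
#' the target sample). All other sites fall back to either the site's minimum
#' observed value across samples (`row_min`) or the sample's mean over
#' observed values (`col_mean`). Observed cells are never altered; cell
#' provenance records the rule used.
#'
#' @param mat a [py_matrix()] on log10 scale
#' @param k neighbour count, default 10
#' @param fallback `"row_min"` or `"col_mean"`
#' @return a complete [py_matrix()] (no NA), provenance tags set
#' @export
impute <- function(mat, k = 10, fallback = c("row_min", "col_mean")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(mat, "py_matrix"), k >= 1)
  vals <- mat$values; obs <- mat$observed; prov <- mat$provenance
  n_samp <- ncol(vals)
  n_obs <- rowSums(obs)
  if (fallback == "row_min" && any(n_obs == 0))
    tf_stop(paste0("site(s) with zero observations cannot use row_min: ",
                   paste(rownames(vals)[n_obs == 0], collapse = ", ")),
            "tyroflow_impute_error")
  knn_route <- n_obs > n_samp / 2          # strictly more than 50%
  col_means <- vapply(seq_len(n_samp), function(j)
    mean(vals[obs[, j], j]), 0)
  warned <- FALSE
  for (i in which(rowSums(!obs) > 0)) {
    miss_j <- which(!obs[i, ])
    if (knn_route[i]) {
      for (j in miss_j) {
        cand <- which(obs[, j] & seq_len(nrow(vals)) != i)
        if (!length(cand)) { vals[i, j] <- col_means[j]
                             prov[i, j] <- "col_mean"; next }
        d <- vapply(seq_along(cand), function(ci) {
          sh <- which(obs[i, ] & obs[cand[ci], ])
          if (!length(sh)) return(Inf)
          sqrt(sum((vals[i, sh] - vals[cand[ci], sh])^2))
        }, 0)
        ok <- is.finite(d)
        cand <- cand[ok]; d <- d[ok]
        if (!length(cand)) { vals[i, j] <- col_means[j]
                             prov[i, j] <- "col_mean"; next }
        if (length(cand) < k && !warned) {
          warning(sprintf("fewer than k=%d eligible neighbours; using all",
                          k)); warned <- TRUE
        }
        nb <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
        vals[i, j] <- mean(vals[nb, j])
        prov[i, j] <- "knn"
      }
    } else {
      fill <- if (fallback == "row_min") {
        rep(min(vals[i, obs[i, ]]), length(miss_j))
      } else col_means[miss_j]
      vals[i, miss_j] <- fill
      prov[i, miss_j] <- fallback
    }
  }
  out <- py_matrix(vals, classes = mat$classes, observed = obs,
                   provenance = prov)
  tf_log("preprocess", "impute", cells_imputed = sum(!obs),
         knn_sites = sum(knn_route & rowSums(!obs) > 0), fallback = fallback)
  out
}
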