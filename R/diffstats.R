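## Empirical-Bayes moderated pairwise contrasts between tumour classes,
## Storey-type tail-area q-values, and class-specific pY-site calling.
##
## Model: one-way layout with a mean per class. Per site g the residual
## variance s_g^2 has df = N - n_classes degrees of freedom. An inverse-chi^2
## prior (d0, s0^2) is estimated across sites by method of moments on
## log s_g^2 (Smyth-style), giving the posterior variance
##   s_tilde^2 = (d0 s0^2 + df s^2) / (d0 + df)
## and a moderated t on d0 + df degrees of freedom for each pairwise contrast.

#' Invert the trigamma function (Newton iteration)
#' @noRd
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (iter in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
      if (x <= 0) x <- 1e-8
    }
    x
  }, 0)
}

#' Estimate the variance prior (d0, s0^2) by method of moments
#'
#' Operates on log sample variances: with df residual degrees of freedom,
#' `e = log(s^2) - digamma(df/2) + log(df/2)` has mean `log(s0^2) +
#' digamma(d0/2) - log(d0/2)` and excess variance `trigamma(d0/2)` beyond the
#' sampling term `trigamma(df/2)`. Homogeneous variances give `d0 = Inf`.
#' Zero variances are floored at 1e-12 before logging.
#'
#' @param s2 per-site residual variances
#' @param df residual degrees of freedom (scalar)
#' @return list with `d0` and `s0_sq`
#' @export
estimate_variance_prior <- function(s2, df) {
  stopifnot(df > 0)
  s2 <- pmax(s2, 1e-5 * stats::median(s2), 1e-12)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  ev <- if (n > 1) sum((e - ebar)^2) / (n - 1) else 0
  excess <- ev - trigamma(df / 2)
  if (n < 2 || excess <= 0)
    return(list(d0 = Inf, s0_sq = mean(s2)))
  d0 <- 2 * trigamma_inverse(excess)
  s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0)
}

#' Moderated pairwise contrasts between classes
#'
#' Fits the one-way class-means model per pY site, shrinks residual variances
#' toward an empirical prior, and reports a moderated t, raw p and (after
#' [estimate_qvalues()]) q for every unordered class pair, plus a moderated
#' omnibus F across classes.
#'
#' @param mat complete (imputed) [py_matrix()]; every class needs >= 2 samples
#' @param prior_df_override force the prior degrees of freedom; `0` gives the
#'   ordinary pooled-variance t (no moderation), `Inf` full shrinkage to the
#'   prior variance; `NULL` (default) estimates d0 from the data
#' @return a `contrast_table`: data.frame with one row per site; columns
#'   `mean_<class>` per class, and `diff_/t_/p_/q_<A>.vs.<B>` per pair,
#'   `F`, `p_F`, `q_F`; attributes `prior` (d0, s0_sq), `classes`, `pairs`
#' @export
fit_moderated_contrasts <- function(mat, prior_df_override = NULL) {
  stopifnot(inherits(mat, "py_matrix"))
  if (any(!is.finite(mat$values)))
    tf_stop("matrix must be complete (run impute() first)",
            "tyroflow_stats_error")
  cls <- sort(unique(mat$classes))
  n_c <- vapply(cls, function(cl) sum(mat$classes == cl), 0L)
  if (any(n_c < 2))
    tf_stop(paste0("class(es) with < 2 samples: ",
                   paste(cls[n_c < 2], collapse = ", ")),
            "tyroflow_stats_error")
  x <- mat$values
  N <- ncol(x)
  df <- N - length(cls)
  means <- sapply(cls, function(cl)
    rowMeans(x[, mat$classes == cl, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(x), cls))
  rss <- rowSums((x - means[, mat$classes, drop = FALSE])^2)
  s2 <- rss / df

  prior <- estimate_variance_prior(s2, df)
  if (!is.null(prior_df_override)) {
    d0 <- prior_df_override
    prior <- list(d0 = d0, s0_sq = prior$s0_sq)
  }
  d0 <- prior$d0
  if (is.infinite(d0)) {
    s2_post <- rep(prior$s0_sq, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- df
  } else {
    s2_post <- (d0 * prior$s0_sq + df * s2) / (d0 + df)
    df_total <- d0 + df
  }

  out <- data.frame(site = rownames(x), stringsAsFactors = FALSE)
  for (cl in cls) out[[paste0("mean_", cl)]] <- means[, cl]
  pairs <- combn(cls, 2)
  pair_names <- apply(pairs, 2, paste, collapse = ".vs.")
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- means[, a] - means[, b]
    se <- sqrt(s2_post * (1 / n_c[a] + 1 / n_c[b]))
    tt <- ifelse(se > 0, diff / se, 0)
    p <- 2 * pt(-abs(tt), df_total)
    p[diff == 0] <- 1
    out[[paste0("diff_", pair_names[j])]] <- diff
    out[[paste0("t_", pair_names[j])]] <- tt
    out[[paste0("p_", pair_names[j])]] <- p
    out[[paste0("q_", pair_names[j])]] <- estimate_qvalues(p)
  }
  grand <- rowMeans(x)
  ms_between <- rowSums(sweep((means - grand)^2, 2, n_c[cls], `*`)) /
    (length(cls) - 1)
  Fstat <- ifelse(s2_post > 0, ms_between / s2_post, 0)
  p_F <- pf(Fstat, length(cls) - 1, df_total, lower.tail = FALSE)
  p_F[ms_between == 0] <- 1
  out$F <- Fstat
  out$p_F <- p_F
  out$q_F <- estimate_qvalues(p_F)
  attr(out, "prior") <- prior
  attr(out, "classes") <- cls
  attr(out, "pairs") <- pair_names
  attr(out, "df") <- df
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Storey-type tail-area q-values
#'
#' Two-component model: the null proportion eta0 is estimated by Storey's
#' lambda-grid smoothing (lambda = 0.05, 0.10, ..., 0.95, cubic smoothing
#' spline evaluated at the largest lambda; inputs with fewer than 100 p-values
#' use the conservative eta0 = 1), then `q(p) = eta0 * p * m / rank(p)`,
#' enforced monotone by a running minimum from the largest p down, capped
#' at 1.
#'
#' @param p vector of p-values in `[0,1]`
#' @param eta0 optionally force the null proportion (e.g. 1)
#' @return q-values, same length/order as `p`
#' @export
estimate_qvalues <- function(p, eta0 = NULL) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    tf_stop("p-values outside [0,1]", "tyroflow_stats_error")
  m <- length(p)
  if (is.null(eta0)) {
    if (m < 100) {
      eta0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      eta0 <- predict(fit, x = max(lambda))$y
      eta0 <- min(max(eta0, 1 / m), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(eta0 * m * p[o] / (m:1)))[ro]
  q
}

#' Call class-specific pY sites
#'
#' A site is called specific to class `C` when both pairwise contrasts of `C`
#' against the other classes are significant (`q < q_threshold`, strict) and
#' the class mean of `C` exceeds both other class means (increased spectral
#' intensity). The per-class call sets are disjoint by construction. An
#' optional omnibus pre-filter additionally requires the moderated F to pass
#' `q_F < omnibus_q`.
#'
#' @param contrasts a `contrast_table` from [fit_moderated_contrasts()]
#' @param q_threshold significance threshold on the contrast q-values,
#'   default 0.05
#' @param omnibus_q if non-`NULL`, sites must first pass the moderated
#'   omnibus F at this q
#' @return named list of character vectors (site keys) per class; also
#'   attached to the table as a `call` column via attribute `calls`
#' @export
call_class_specific <- function(contrasts, q_threshold = 0.05,
                                omnibus_q = NULL) {
  cls <- attr(contrasts, "classes")
  pairs <- attr(contrasts, "pairs")
  pass_omni <- if (is.null(omnibus_q)) rep(TRUE, nrow(contrasts))
  else contrasts$q_F < omnibus_q
  calls <- setNames(vector("list", length(cls)), cls)
  call_col <- rep("none", nrow(contrasts))
  for (cl in cls) {
    others <- setdiff(cls, cl)
    ok <- pass_omni
    for (ot in others) {
      pn <- if (paste(cl, ot, sep = ".vs.") %in% pairs)
        paste(cl, ot, sep = ".vs.") else paste(ot, cl, sep = ".vs.")
      ok <- ok & contrasts[[paste0("q_", pn)]] < q_threshold &
        contrasts[[paste0("mean_", cl)]] > contrasts[[paste0("mean_", ot)]]
    }
    calls[[cl]] <- contrasts$site[ok]
    call_col[ok] <- paste0(cl, "-specific")
  }
  attr(calls, "call_column") <- call_col
  calls
}
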