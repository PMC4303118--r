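## Two-step random-forest tumour-type signature: a first forest over all
## reproducible pY sites yields per-class permutation importances; sites with
## importance above the threshold (default > 1.2 percentage points, strict)
## for at least one class seed a second forest, whose OOB error is the
## signature's headline generalisation estimate.

#' Train the two-step random-forest signature
#'
#' Step 1 trains a forest on all sites of the (complete) matrix and computes
#' per-class permutation importance in percentage points of class-wise OOB
#' accuracy. Step 2 retains sites whose importance exceeds `threshold` for at
#' least one class (strict inequality) and trains a second forest on them
#' only. Samples are internally ordered by id so the result is invariant to
#' input sample order; a fixed seed gives identical output.
#'
#' @param mat complete [py_matrix()] (typically restricted to reproducible
#'   sites); >= 2 classes with >= 2 samples each
#' @param threshold importance cut in percentage points, default 1.2
#' @param n_trees trees per forest, default 2000
#' @param seed integer seed
#' @param importance_scale select sites on `"raw"` percentage-point
#'   importance (default) or `"scaled"` z-scores; both are reported
#' @return object of class `signature_model`: `step1_oob_error`,
#'   `step2_oob_error`, `importances` (sites x classes, percentage points),
#'   `importances_scaled`, `selected_sites` (ordered by decreasing maximum
#'   importance), `threshold`, `seed`, `n_trees`, `forest` (step-2
#'   `tf_forest`), `classes`
#' @export
train_two_step <- function(mat, threshold = 1.2, n_trees = 2000, seed = 1L,
                           importance_scale = c("raw", "scaled")) {
  importance_scale <- match.arg(importance_scale)
  stopifnot(inherits(mat, "py_matrix"))
  if (any(!is.finite(mat$values)))
    tf_stop("matrix must be complete (run impute() first)",
            "tyroflow_signature_error")
  ord <- order(mat$samples)
  X <- t(mat$values)[ord, , drop = FALSE]
  y <- factor(mat$classes[ord])
  if (nlevels(y) < 2 || any(table(y) < 2))
    tf_stop("need >= 2 classes with >= 2 samples each",
            "tyroflow_signature_error")
  set.seed(seed)
  rf1 <- random_forest(X, y, n_trees = n_trees)
  imp <- rf1$importance[, levels(y), drop = FALSE]
  imp_scaled <- rf1$importance_scaled[, levels(y), drop = FALSE]
  sel_matrix <- if (importance_scale == "raw") imp else imp_scaled
  hit <- apply(sel_matrix, 1, max) > threshold
  if (!any(hit))
    tf_stop(sprintf(paste0("no site has importance > %g for any class; ",
                           "consider lowering the threshold"), threshold),
            "tyroflow_signature_error")
  sel <- rownames(imp)[hit]
  sel <- sel[order(-apply(sel_matrix[sel, , drop = FALSE], 1, max), sel)]
  rf2 <- random_forest(X[, sel, drop = FALSE], y, n_trees = n_trees)
  tf_log("signature", "train_two_step", sites_in = ncol(X),
         selected = length(sel), oob1 = rf1$oob_error, oob2 = rf2$oob_error)
  structure(list(step1_oob_error = rf1$oob_error,
                 step2_oob_error = rf2$oob_error,
                 importances = imp, importances_scaled = imp_scaled,
                 selected_sites = sel, threshold = threshold,
                 seed = as.integer(seed), n_trees = n_trees,
                 forest = rf2, classes = levels(y)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf(paste0("signature_model: %d selected pY sites ",
                     "(importance > %g)\n"), length(x$selected_sites),
              x$threshold))
  cat(sprintf("  step-1 OOB error %.4f, step-2 OOB error %.4f\n",
              x$step1_oob_error, x$step2_oob_error))
  invisible(x)
}

#' Predict tumour classes from a signature model
#'
#' @param object a `signature_model`
#' @param mat [py_matrix()] (or numeric matrix, samples in columns) containing
#'   all selected sites; an error lists any absent sites
#' @param ... unused
#' @return list with `labels` and per-class `votes` (fractions summing to 1)
#' @export
predict.signature_model <- function(object, mat, ...) {
  vals <- if (inherits(mat, "py_matrix")) mat$values else mat
  miss <- setdiff(object$selected_sites, rownames(vals))
  if (length(miss))
    tf_stop(paste0("input matrix lacks selected site(s): ",
                   paste(miss, collapse = ", ")), "tyroflow_predict_error")
  X <- t(vals[object$selected_sites, , drop = FALSE])
  predict(object$forest, X)
}

#' Serialise a signature model to JSON
#'
#' Writes sites, importances, threshold, seed and forest parameters (the tree
#' ensemble itself is re-derivable by retraining with the recorded seed).
#' @param model a `signature_model`
#' @param path output JSON path
#' @export
write_signature <- function(model, path) {
  jsonlite::write_json(list(
    selected_sites = model$selected_sites,
    threshold = model$threshold, seed = model$seed,
    n_trees = model$n_trees, classes = model$classes,
    step1_oob_error = model$step1_oob_error,
    step2_oob_error = model$step2_oob_error,
    importances = as.data.frame(model$importances)), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
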