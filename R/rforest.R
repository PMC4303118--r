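## A compact random forest for classification: CART trees (Gini), bootstrap
## bagging, out-of-bag error, and permutation importance per class (mean
## decrease in class-wise OOB accuracy). Deliberately small-n oriented: the
## matrices here are tens of samples by a few hundred pY sites, so plain R
## with vectorised split search is fast enough and fully auditable.

grow_tree <- function(X, y, K, mtry, min_node = 1L) {
  n <- nrow(X); p <- ncol(X)
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0); pred <- integer(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_
    right[length(right) + 1L] <<- NA_integer_
    pred[length(pred) + 1L] <<- NA_integer_
    length(feature)
  }
  majority <- function(yy) {
    tab <- tabulate(yy, K)
    which.max(tab)                      # ties -> smallest class index
  }
  build <- function(idx) {
    node <- new_node()
    yy <- y[idx]
    if (length(idx) <= min_node || length(unique(yy)) == 1L) {
      pred[node] <<- majority(yy)
      return(node)
    }
    feats <- sort(sample.int(p, min(mtry, p)))
    best <- list(score = -Inf, f = NA_integer_, thr = NA_real_)
    tot <- tabulate(yy, K)
    nn <- length(idx)
    for (f in feats) {
      v <- X[idx, f]
      o <- order(v)
      vs <- v[o]; ys <- yy[o]
      cuts <- which(vs[-nn] < vs[-1])   # splits between distinct values
      if (!length(cuts)) next
      cum <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(nn))
      lsz <- cuts; rsz <- nn - cuts
      lsc <- rowSums(cum[cuts, , drop = FALSE]^2) / lsz
      rsc <- rowSums((matrix(tot, length(cuts), K, byrow = TRUE) -
                        cum[cuts, , drop = FALSE])^2) / rsz
      sc <- lsc + rsc
      bi <- which.max(sc)
      if (sc[bi] > best$score + 1e-12) {
        best <- list(score = sc[bi], f = f,
                     thr = (vs[cuts[bi]] + vs[cuts[bi] + 1L]) / 2)
      }
    }
    if (is.na(best$f)) {
      pred[node] <<- majority(yy)
      return(node)
    }
    go_left <- X[idx, best$f] <= best$thr
    feature[node] <<- best$f
    threshold[node] <<- best$thr
    l <- build(idx[go_left])
    r <- build(idx[!go_left])
    feature_node <- node
    left[feature_node] <<- l
    right[feature_node] <<- r
    node
  }
  root <- build(seq_len(n))
  list(feature = feature, threshold = threshold, left = left,
       right = right, pred = pred, root = root,
       used = sort(unique(feature[!is.na(feature)])))
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  for (i in seq_len(n)) {
    node <- tree$root
    while (is.na(tree$pred[node])) {
      node <- if (X[i, tree$feature[node]] <= tree$threshold[node])
        tree$left[node] else tree$right[node]
    }
    out[i] <- tree$pred[node]
  }
  out
}

#' Train a random forest classifier
#'
#' Bagged CART trees with Gini split search (`mtry` features per node,
#' sampled without replacement), out-of-bag error, and permutation importance
#' expressed as mean decrease in OOB accuracy per class, in percentage points
#' (only features used by a tree are permuted; unused features contribute a
#' zero decrease for that tree). Fully deterministic under `set.seed()`.
#'
#' @param X numeric matrix, samples in rows, features in columns (colnames
#'   required for importance naming)
#' @param y factor (or coercible) of class labels, length `nrow(X)`
#' @param n_trees number of trees, default 2000
#' @param mtry features tried per node, default `floor(sqrt(ncol(X)))`
#' @param importance compute permutation importance (default `TRUE`)
#' @return object of class `tf_forest`: trees, `oob_error`, `oob_votes`,
#'   `importance` (features x classes + `overall`, percentage points),
#'   `importance_scaled` (z-scores), `classes`
#' @export
random_forest <- function(X, y, n_trees = 2000,
                          mtry = max(1L, floor(sqrt(ncol(X)))),
                          importance = TRUE) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- factor(y)
  K <- nlevels(y)
  yi <- as.integer(y)
  n <- nrow(X); p <- ncol(X)
  votes <- matrix(0L, n, K)
  imp_sum <- matrix(0, p, K + 1)
  imp_sq <- matrix(0, p, K + 1)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), boot)
    tree <- grow_tree(X[boot, , drop = FALSE], yi[boot], K, mtry)
    trees[[b]] <- tree
    if (!length(oob)) next
    pred0 <- predict_tree(tree, X[oob, , drop = FALSE])
    votes[cbind(oob, pred0)] <- votes[cbind(oob, pred0)] + 1L
    if (importance && length(tree$used)) {
      acc0 <- c(vapply(seq_len(K), function(k) {
        sel <- yi[oob] == k
        if (!any(sel)) NA_real_ else mean(pred0[sel] == k)
      }, 0), mean(pred0 == yi[oob]))
      Xo <- X[oob, , drop = FALSE]
      for (f in tree$used) {
        Xp <- Xo
        Xp[, f] <- Xp[sample.int(length(oob)), f]
        predp <- predict_tree(tree, Xp)
        accp <- c(vapply(seq_len(K), function(k) {
          sel <- yi[oob] == k
          if (!any(sel)) NA_real_ else mean(predp[sel] == k)
        }, 0), mean(predp == yi[oob]))
        dec <- acc0 - accp
        dec[is.na(dec)] <- 0
        imp_sum[f, ] <- imp_sum[f, ] + dec
        imp_sq[f, ] <- imp_sq[f, ] + dec^2
      }
    }
  }
  covered <- rowSums(votes) > 0
  oob_pred <- apply(votes, 1, which.max)
  oob_error <- mean(oob_pred[covered] != yi[covered])
  imp_mean <- imp_sum / n_trees
  imp_sd <- sqrt(pmax(imp_sq / n_trees - imp_mean^2, 0)) / sqrt(n_trees)
  imp_scaled <- ifelse(imp_sd > 0, imp_mean / imp_sd, 0)
  cn <- c(levels(y), "overall")
  dimnames(imp_mean) <- dimnames(imp_scaled) <-
    list(colnames(X), cn)
  structure(list(trees = trees, classes = levels(y), n_trees = n_trees,
                 mtry = mtry, features = colnames(X),
                 oob_error = oob_error, oob_votes = votes,
                 importance = 100 * imp_mean,
                 importance_scaled = imp_scaled),
            class = "tf_forest")
}

#' Predict classes with a trained forest
#' @param object a `tf_forest`
#' @param X matrix with the forest's feature columns
#' @param ... unused
#' @return list with `labels` (character) and `votes` (fractions summing to 1
#'   per sample)
#' @export
predict.tf_forest <- function(object, X, ...) {
  miss <- setdiff(object$features, colnames(X))
  if (length(miss))
    tf_stop(paste0("input lacks feature(s): ", paste(miss, collapse = ", ")),
            "tyroflow_predict_error")
  X <- X[, object$features, drop = FALSE]
  K <- length(object$classes)
  votes <- matrix(0, nrow(X), K)
  for (tree in object$trees) {
    pr <- predict_tree(tree, X)
    votes[cbind(seq_len(nrow(X)), pr)] <- votes[cbind(seq_len(nrow(X)), pr)] + 1
  }
  frac <- votes / rowSums(votes)
  colnames(frac) <- object$classes
  labels <- object$classes[apply(votes, 1, which.max)]
  list(labels = setNames(labels, rownames(X)), votes = frac)
}
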