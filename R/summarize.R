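## Cross-cutting descriptive outputs: hierarchical clustering with the
## study's settings (row-standardised, Euclidean, complete linkage),
## three-set overlap counts, kinase-class intensity aggregation and
## within-class fold-change screens.

#' Hierarchical clustering of sites and samples
#'
#' Rows are z-scored (mean 0, SD 1; zero-SD rows left at 0) when
#' `standardise_rows`, then sites and samples are clustered with Euclidean
#' distance and complete linkage. `stats::hclust` ordering is deterministic.
#'
#' @param mat complete [py_matrix()] or numeric matrix (sites x samples)
#' @param standardise_rows z-score rows first, default `TRUE`
#' @return list with `row_order`, `col_order`, `row_hclust`, `col_hclust`,
#'   `standardised` (the matrix used)
#' @export
hcluster <- function(mat, standardise_rows = TRUE) {
  x <- if (inherits(mat, "py_matrix")) mat$values else mat
  if (nrow(x) < 2 || ncol(x) < 2)
    tf_stop("need at least 2 sites and 2 samples to cluster",
            "tyroflow_summarize_error")
  if (any(!is.finite(x)))
    tf_stop("matrix must be complete", "tyroflow_summarize_error")
  if (standardise_rows) {
    mu <- rowMeans(x)
    sdev <- apply(x, 1, sd)
    x <- (x - mu) / ifelse(sdev > 0, sdev, 1)
    x[sdev == 0, ] <- 0
  }
  rh <- hclust(dist(x), method = "complete")
  ch <- hclust(dist(t(x)), method = "complete")
  list(row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch, standardised = x)
}

#' Top-k most variable sites (within-class subgrouping helper)
#'
#' Ranks sites by variance (default), MAD or range across the given samples
#' and returns the top `k` site keys.
#'
#' @param mat a [py_matrix()]
#' @param k number of sites, default 150
#' @param samples optional sample subset (e.g. one tumour class)
#' @param method `"variance"`, `"mad"` or `"range"`
#' @return character vector of site keys
#' @export
top_variable_sites <- function(mat, k = 150, samples = NULL,
                               method = c("variance", "mad", "range")) {
  method <- match.arg(method)
  x <- mat$values
  if (!is.null(samples)) x <- x[, samples, drop = FALSE]
  score <- switch(method,
                  variance = apply(x, 1, var),
                  mad = apply(x, 1, mad),
                  range = apply(x, 1, function(v) diff(range(v))))
  names(sort(score, decreasing = TRUE))[seq_len(min(k, nrow(x)))]
}

#' Three-set overlap (Venn) counts
#'
#' Exact counts of the seven disjoint regions of three sets, plus per-set
#' totals. Region names use the set names joined by `&`.
#'
#' @param sets named list of exactly three character vectors
#' @return list with `regions` (named integer vector, 7 disjoint regions),
#'   `totals` (per set) and `union_size`
#' @export
overlap_counts <- function(sets) {
  stopifnot(length(sets) == 3, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  all_items <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_items %in% s,
                 logical(length(all_items)))
  if (length(all_items) == 1) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, nm))
  key <- apply(memb, 1, function(r) paste(nm[r], collapse = "&"))
  combos <- c(nm, paste(nm[1], nm[2], sep = "&"),
              paste(nm[1], nm[3], sep = "&"),
              paste(nm[2], nm[3], sep = "&"),
              paste(nm, collapse = "&"))
  regions <- setNames(integer(length(combos)), combos)
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  list(regions = regions,
       totals = vapply(sets, length, 0L),
       union_size = length(all_items))
}

#' Summed pY intensity per protein and kinase class
#'
#' Sums linear-scale intensities (`10^log10`) over all sites and samples per
#' protein (gene symbol), then per kinase class. Unannotated proteins are
#' grouped as `"other"` and logged.
#'
#' @param mat complete [py_matrix()]
#' @param kinase_classes named character vector: gene symbol -> class label
#'   (e.g. `RTK`, `nonRTK-TK`, `S/T`, `dual`)
#' @return list of data.frames `per_protein` (gene, class, total_intensity;
#'   ranked) and `per_class`
#' @export
kinase_intensity_summary <- function(mat, kinase_classes) {
  genes <- parse_site_key(mat$sites)$protein_id  # annotation keyed likewise
  lin <- rowSums(10^mat$values)
  per_gene <- tapply(lin, genes, sum)
  cls <- kinase_classes[names(per_gene)]
  unann <- names(per_gene)[is.na(cls)]
  if (length(unann))
    tf_log("summarize", "unannotated_proteins_grouped_other",
           n = length(unann))
  cls[is.na(cls)] <- "other"
  per_protein <- data.frame(gene = names(per_gene),
                            class = unname(cls),
                            total_intensity = as.numeric(per_gene),
                            stringsAsFactors = FALSE)
  per_protein <- per_protein[order(-per_protein$total_intensity,
                                   per_protein$gene), ]
  rownames(per_protein) <- NULL
  pc <- tapply(per_protein$total_intensity, per_protein$class, sum)
  per_class <- data.frame(class = names(pc), total_intensity = as.numeric(pc),
                          stringsAsFactors = FALSE)
  per_class <- per_class[order(-per_class$total_intensity), ]
  rownames(per_class) <- NULL
  list(per_protein = per_protein, per_class = per_class)
}

#' Fold-change screen between two sample groups
#'
#' Retains sites whose mean log10 intensity in group A exceeds group B by
#' more than `log10(min_fold)` (strict). Optionally rolls sites up to
#' proteins by the maximum site fold change.
#'
#' @param mat complete [py_matrix()]
#' @param group_a,group_b disjoint character vectors of sample ids
#' @param min_fold linear fold-change threshold, default 10
#' @param rollup also return a protein-level table, default `TRUE`
#' @return list with `sites` (data.frame site, mean_a, mean_b, log10_fold)
#'   and, if `rollup`, `proteins`
#' @export
fold_change_screen <- function(mat, group_a, group_b, min_fold = 10,
                               rollup = TRUE) {
  if (!length(group_a) || !length(group_b))
    tf_stop("both groups must be non-empty", "tyroflow_summarize_error")
  if (length(intersect(group_a, group_b)))
    tf_stop("groups must be disjoint", "tyroflow_summarize_error")
  stopifnot(all(c(group_a, group_b) %in% mat$samples))
  ma <- rowMeans(mat$values[, group_a, drop = FALSE])
  mb <- rowMeans(mat$values[, group_b, drop = FALSE])
  lf <- ma - mb
  keep <- lf > log10(min_fold)
  sites <- data.frame(site = mat$sites[keep], mean_a = ma[keep],
                      mean_b = mb[keep], log10_fold = lf[keep],
                      stringsAsFactors = FALSE)
  sites <- sites[order(-sites$log10_fold), ]
  rownames(sites) <- NULL
  out <- list(sites = sites)
  if (rollup) {
    prot <- parse_site_key(sites$site)$protein_id
    if (nrow(sites)) {
      best <- tapply(sites$log10_fold, prot, max)
      out$proteins <- data.frame(protein = names(best),
                                 max_log10_fold = as.numeric(best),
                                 stringsAsFactors = FALSE)
      out$proteins <- out$proteins[order(-out$proteins$max_log10_fold), ]
      rownames(out$proteins) <- NULL
    } else {
      out$proteins <- data.frame(protein = character(0),
                                 max_log10_fold = numeric(0))
    }
  }
  out
}
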