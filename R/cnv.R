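## aCGH copy-number arm: median normalisation with duplicate-probe
## averaging, outlier smoothing, permutation-based circular binary
## segmentation, plateau-threshold state calling (deletion < -0.5, neutral,
## amplification, high amplification > 1.5) and genome-wide level merging.

#' Median-normalise an aCGH probe table
#'
#' Duplicate probe ids (within a chromosome) are first collapsed to their
#' mean log2 ratio; the global median log2 ratio is then subtracted.
#'
#' @param probes data.frame from [read_probes()]
#' @return normalised probe data.frame, sorted by (chrom, position)
#' @export
normalise_probes <- function(probes) {
  ag <- aggregate(log2_ratio ~ chrom + position + probe_id, data = probes,
                  FUN = mean)
  ag <- ag[order(ag$chrom, ag$position), ]
  ag$log2_ratio <- ag$log2_ratio - median(ag$log2_ratio)
  rownames(ag) <- NULL
  ag[c("chrom", "position", "probe_id", "log2_ratio")]
}

#' Smooth isolated outlier probes
#'
#' A probe is treated as an outlier when it deviates by more than `trim_sd`
#' robust SDs from the median of its local window and from each existing
#' neighbour; such probes are shrunk to the window median plus/minus
#' `trim_sd` robust SDs. The robust SD is `1.4826 * MAD` computed per
#' chromosome (a window-local MAD over a handful of probes is too unstable
#' to set a trimming scale). All other probes are untouched.
#'
#' @param probes normalised probe data.frame
#' @param trim_sd deviation threshold in robust SDs, default 3
#' @param window window size in probes (centred), default 5
#' @return probe data.frame with smoothed log2 ratios
#' @export
smooth_outliers <- function(probes, trim_sd = 3, window = 5) {
  h <- floor(window / 2)
  out <- probes
  for (ch in unique(probes$chrom)) {
    sel <- which(probes$chrom == ch)
    x <- probes$log2_ratio[sel]
    n <- length(x)
    y <- x
    rsd <- mad(x, constant = 1.4826)
    for (i in seq_len(n)) {
      win <- x[max(1, i - h):min(n, i + h)]
      med <- median(win)
      dev <- x[i] - med
      if (abs(dev) <= trim_sd * rsd) next
      nb <- c(if (i > 1) x[i - 1], if (i < n) x[i + 1])
      if (all(abs(x[i] - nb) > trim_sd * rsd))
        y[i] <- med + sign(dev) * trim_sd * rsd
    }
    out$log2_ratio[sel] <- y
  }
  out
}

segment_indices <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  if (n < 2 * min_width || var(x) < 1e-18) return(c(0L, n))
  ms <- .cbs_max_stat(x, min_width)
  p <- .cbs_perm_pvalue(x, ms$stat, n_perm, alpha, min_width)
  if (p >= alpha) return(c(0L, n))
  i <- ms$i; j <- ms$j
  cuts <- sort(unique(c(0L, i, j, n)))
  bounds <- c(0L)
  for (s in seq_len(length(cuts) - 1)) {
    lo <- cuts[s]; hi <- cuts[s + 1]
    sub <- segment_indices(x[(lo + 1):hi], alpha, n_perm, min_width)
    bounds <- c(bounds, lo + sub[-1])
  }
  unique(bounds)
}

#' Circular binary segmentation of an aCGH profile
#'
#' Recursive binary splitting per chromosome: at each level the maximal
#' circular two-segment t-statistic is located (arc length bounded by
#' `min_width`), its significance assessed by permuting probe values within
#' the current segment, and the split accepted iff the permutation p-value is
#' below `alpha`; recursion continues until no split is accepted. Segment
#' means are probe averages; intervals are 1-based inclusive bp. Chromosomes
#' with fewer than `2 * min_width` probes yield a single segment (logged).
#'
#' @param probes smoothed, normalised probe data.frame
#' @param alpha per-split significance level, default 0.01
#' @param n_permutations permutations per split test, default 1000
#' @param min_width minimal segment width in probes, default 2
#' @param seed integer seed for the permutation RNG
#' @param sample sample id recorded in the output, default `"sample"`
#' @return data.frame `sample, chrom, start, end, n_probes, seg_mean` plus
#'   attributes `parameters`
#' @export
cbs_segment <- function(probes, alpha = 0.01, n_permutations = 1000,
                        min_width = 2, seed = 1L, sample = "sample") {
  set.seed(seed)
  res <- list()
  for (ch in unique(probes$chrom)) {
    d <- probes[probes$chrom == ch, ]
    d <- d[order(d$position), ]
    x <- d$log2_ratio
    if (length(x) < 2 * min_width)
      tf_log("cnv", "short_chromosome_single_segment", chrom = ch,
             probes = length(x))
    bounds <- segment_indices(x, alpha, n_permutations, min_width)
    for (s in seq_len(length(bounds) - 1)) {
      lo <- bounds[s] + 1L; hi <- bounds[s + 1]
      res[[length(res) + 1L]] <- data.frame(
        sample = sample, chrom = ch,
        start = d$position[lo], end = d$position[hi],
        n_probes = hi - lo + 1L, seg_mean = mean(x[lo:hi]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "parameters") <- list(alpha = alpha,
                                  n_permutations = n_permutations,
                                  min_width = min_width, seed = seed)
  out
}

#' Assign copy-number states to segments
#'
#' Plateau thresholds on the segment mean log2 ratio: `deletion` below -0.5;
#' `neutral` in `[-0.5, 0.5]`; `amplification` in `(0.5, 1.5]`;
#' `high_amplification` above 1.5. The reported fold change is
#' `2^seg_mean` relative to the diploid reference.
#'
#' @param segments data.frame from [cbs_segment()]
#' @return segments with `state` and `fold_change` columns
#' @export
classify_segments <- function(segments) {
  m <- segments$seg_mean
  segments$state <- ifelse(m < -0.5, "deletion",
                    ifelse(m <= 0.5, "neutral",
                    ifelse(m <= 1.5, "amplification", "high_amplification")))
  segments$fold_change <- 2^m
  segments
}

#' Merge segment means into genome-wide copy-number levels
#'
#' Iterative nearest-pair merging of segment means (each level's mean is the
#' probe-count-weighted mean of its members) while the closest pair of level
#' means differs by less than `merge_delta`. Each segment receives a `level`
#' id (1 = lowest mean) and the pooled `level_mean`; the sorted unique level
#' means (the plateaus of the ordered segment-mean plot) are attached as
#' attribute `plateaus`. The merge rule operationalises a visual plateau
#' criterion and is recorded as such in run metadata.
#'
#' @param segments classified segment data.frame (one tumour)
#' @param merge_delta merge tolerance in log2 units, default 0.2
#' @return segments with `level`, `level_mean`; attribute `plateaus`
#' @export
merge_levels <- function(segments, merge_delta = 0.2) {
  n <- nrow(segments)
  grp <- seq_len(n)
  w <- segments$n_probes
  m <- segments$seg_mean
  repeat {
    ids <- sort(unique(grp))
    if (length(ids) < 2) break
    gm <- vapply(ids, function(g)
      sum(m[grp == g] * w[grp == g]) / sum(w[grp == g]), 0)
    o <- order(gm)
    gaps <- diff(gm[o])
    k <- which.min(gaps)
    if (gaps[k] >= merge_delta) break
    grp[grp == ids[o[k + 1]]] <- ids[o[k]]
  }
  ids <- sort(unique(grp))
  gm <- vapply(ids, function(g)
    sum(m[grp == g] * w[grp == g]) / sum(w[grp == g]), 0)
  o <- order(gm)
  level_of <- setNames(order(o), ids)   # rank of each group by mean
  segments$level <- as.integer(level_of[as.character(grp)])
  segments$level_mean <- gm[o][segments$level]
  attr(segments, "plateaus") <- unname(sort(gm))
  segments
}

#' Export amplified regions as BED
#'
#' Writes segments in states `amplification`/`high_amplification` as 0-based
#' half-open BED intervals.
#' @param segments classified segments
#' @param path output BED path
#' @export
write_amplified_bed <- function(segments, path) {
  amp <- segments[segments$state %in% c("amplification",
                                        "high_amplification"), ]
  bed <- data.frame(chrom = amp$chrom, start = amp$start - 1L,
                    end = amp$end, name = amp$state,
                    score = round(amp$seg_mean, 4))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
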