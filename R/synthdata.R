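## Synthetic-data generators. These state the world the test-suite lives in:
## a 3-class tumour design (8 p53 + 8 PyMT + 5 Her2 samples), log10-normal pY
## site intensities with intensity-dependent (logistic) missingness, three
## spike-in standards per sample at 5 pmol / 0.5 pmol / 10 pmol, planted
## 10-fold class-specific sites, and aCGH probe series with planted focal
## amplifications. Ground truth is returned alongside so recovery is testable.

#' Configuration for the phosphoproteomics generator
#'
#' Defaults mirror the study design the pipeline targets: classes p53/PyMT/
#' Her2 with 8/8/5 samples, 10 planted class-specific sites per class with a
#' +1.0 log10 (10-fold) effect, log10 baseline intensities N(7, 0.8) with
#' within-class measurement noise SD 0.25, logistic detection probability in
#' log10 intensity (midpoint 5.5, steepness 1.5), three spike-in standards at
#' 5, 0.5 and 10 pmol, localization probabilities Beta(8, 1) (about 10% of
#' rows below the 0.75 filter), and log-normal per-sample technical scale
#' factors (sdlog 0.3) for the spike-in normalisation to correct.
#'
#' @param n_per_class named integer vector: samples per class
#' @param n_sites number of pY sites
#' @param n_specific_per_class planted class-specific sites per class
#' @param effect_log10 planted effect on log10 scale (1.0 = 10-fold)
#' @param baseline_mean,baseline_sd site baseline log10 intensity distribution
#' @param noise_sd within-class measurement noise SD (log10)
#' @param missing_steepness,missing_midpoint logistic detection-probability
#'   parameters versus log10 intensity; `missing_midpoint = -Inf` disables
#'   missingness entirely
#' @param spikein_amounts named numeric vector, pmol per standard peptide
#' @param spikein_noise_sd log10 noise SD on spike-in intensities
#' @param localization_alpha_beta length-2 Beta parameters for localization
#'   probabilities
#' @param scale_sdlog sdlog of the log-normal per-sample scale factors
#' @param sites_per_protein average pY sites per protein (site-to-protein map)
#' @param seed integer RNG seed
#' @return a `phospho_sim_config` list, validated
#' @export
phospho_sim_config <- function(n_per_class = c(p53 = 8, PyMT = 8, Her2 = 5),
                               n_sites = 400,
                               n_specific_per_class = 10,
                               effect_log10 = 1.0,
                               baseline_mean = 7, baseline_sd = 0.8,
                               noise_sd = 0.25,
                               missing_steepness = 1.5,
                               missing_midpoint = 5.5,
                               spikein_amounts = c(MK14_STD = 5,
                                                   EFTU_STD = 0.5,
                                                   EGFR_STD = 10),
                               spikein_noise_sd = 0.02,
                               localization_alpha_beta = c(8, 1),
                               scale_sdlog = 0.3,
                               sites_per_protein = 1.5,
                               seed = 1L) {
  cfg <- list(n_per_class = n_per_class, n_sites = as.integer(n_sites),
              n_specific_per_class = as.integer(n_specific_per_class),
              effect_log10 = effect_log10, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, noise_sd = noise_sd,
              missing_steepness = missing_steepness,
              missing_midpoint = missing_midpoint,
              spikein_amounts = spikein_amounts,
              spikein_noise_sd = spikein_noise_sd,
              localization_alpha_beta = localization_alpha_beta,
              scale_sdlog = scale_sdlog,
              sites_per_protein = sites_per_protein,
              seed = as.integer(seed))
  bad <- function(field, msg)
    tf_stop(sprintf("invalid config field '%s': %s", field, msg),
            "tyroflow_config_error")
  if (length(cfg$n_per_class) < 2 || any(cfg$n_per_class < 1) ||
      is.null(names(cfg$n_per_class)))
    bad("n_per_class", "need >=2 named classes with positive counts")
  if (cfg$n_sites < 1) bad("n_sites", "must be positive")
  if (cfg$n_specific_per_class < 0) bad("n_specific_per_class", "negative")
  if (cfg$n_specific_per_class * length(cfg$n_per_class) > cfg$n_sites)
    bad("n_specific_per_class", "sum over classes exceeds n_sites")
  if (cfg$baseline_sd < 0) bad("baseline_sd", "negative")
  if (cfg$noise_sd < 0) bad("noise_sd", "negative")
  if (cfg$missing_steepness < 0)
    bad("missing_steepness", "must be >= 0 (detection monotone in intensity)")
  if (any(cfg$spikein_amounts <= 0) || is.null(names(cfg$spikein_amounts)))
    bad("spikein_amounts", "need named positive amounts")
  if (length(cfg$localization_alpha_beta) != 2 ||
      any(cfg$localization_alpha_beta <= 0))
    bad("localization_alpha_beta", "need two positive Beta parameters")
  class(cfg) <- "phospho_sim_config"
  cfg
}

#' Simulate a phosphotyrosine profiling experiment
#'
#' Produces an evidence table (one row per detected site-sample observation
#' plus spike-in rows in every sample), the spike-in declaration table, and a
#' ground-truth object. Raw intensities are `10^(true log10 value) * sample
#' scale factor`; an observation is emitted with probability
#' `plogis(steepness * (true log10 - midpoint))`, so detection is monotone
#' non-decreasing in abundance. Planted class-specific sites have their class
#' mean shifted by `+effect_log10`. Identical seeds give identical tables.
#'
#' @param config a [phospho_sim_config()]
#' @return list with `evidence` (data.frame as from [read_evidence()]),
#'   `spikeins` (data.frame `standard`, `amount_pmol`) and `truth` (list:
#'   `specific_sites` per class, `true_log10_matrix`, `sample_scale_factors`,
#'   `classes`)
#' @export
simulate_phospho <- function(config = phospho_sim_config()) {
  stopifnot(inherits(config, "phospho_sim_config"))
  set.seed(config$seed)
  cls <- rep(names(config$n_per_class), config$n_per_class)
  samples <- paste0(cls, "_", unlist(lapply(config$n_per_class, seq_len)))
  classes <- setNames(cls, samples)
  ns <- config$n_sites

  n_prot <- max(1L, ceiling(ns / config$sites_per_protein))
  prot <- sprintf("P%05d", ((seq_len(ns) - 1L) %% n_prot) + 1L)
  gene <- sprintf("GENE%d", ((seq_len(ns) - 1L) %% n_prot) + 1L)
  pos <- 100L + 10L * (seq_len(ns) - 1L) %/% n_prot
  sites <- site_key(prot, "Y", pos)

  baseline <- rnorm(ns, config$baseline_mean, config$baseline_sd)
  true_mat <- matrix(baseline, ns, length(samples),
                     dimnames = list(sites, samples))
  specific <- list()
  pool <- seq_len(ns)
  for (cl in names(config$n_per_class)) {
    idx <- pool[seq_len(config$n_specific_per_class)]
    pool <- setdiff(pool, idx)
    specific[[cl]] <- sites[idx]
    true_mat[idx, classes == cl] <- true_mat[idx, classes == cl] +
      config$effect_log10
  }
  true_mat <- true_mat + matrix(rnorm(length(true_mat), 0, config$noise_sd),
                                ns, length(samples))
  scale_fac <- setNames(exp(rnorm(length(samples), 0, config$scale_sdlog)),
                        samples)

  ## midpoint of -Inf disables missingness outright
  p_det <- if (is.infinite(config$missing_midpoint) &&
               config$missing_midpoint < 0) {
    matrix(1, ns, length(samples))
  } else {
    plogis(config$missing_steepness * (true_mat - config$missing_midpoint))
  }
  detected <- matrix(runif(length(true_mat)) < p_det, ns, length(samples))

  loc <- rbeta(ns, config$localization_alpha_beta[1],
               config$localization_alpha_beta[2])

  idx <- which(detected, arr.ind = TRUE)
  ev <- data.frame(
    sample_id = samples[idx[, 2]],
    protein_id = prot[idx[, 1]], gene_symbol = gene[idx[, 1]],
    residue = "Y", position = pos[idx[, 1]],
    localization_prob = loc[idx[, 1]],
    raw_intensity = 10^true_mat[idx] * scale_fac[samples[idx[, 2]]],
    is_spikein = FALSE, is_contaminant = FALSE, is_reverse = FALSE,
    stringsAsFactors = FALSE)

  ## spike-ins: present in every sample, intensity ~ amount * scale * noise
  counts_per_pmol <- 1e6
  sp <- expand.grid(standard = names(config$spikein_amounts),
                    sample_id = samples, stringsAsFactors = FALSE)
  sp_int <- config$spikein_amounts[sp$standard] * counts_per_pmol *
    scale_fac[sp$sample_id] *
    10^rnorm(nrow(sp), 0, config$spikein_noise_sd)
  sp_ev <- data.frame(
    sample_id = sp$sample_id, protein_id = sp$standard,
    gene_symbol = sp$standard, residue = "Y", position = 1L,
    localization_prob = 1, raw_intensity = as.numeric(sp_int),
    is_spikein = TRUE, is_contaminant = FALSE, is_reverse = FALSE,
    stringsAsFactors = FALSE)
  ev <- rbind(ev, sp_ev)
  ev <- ev[order(ev$sample_id, ev$protein_id, ev$position), ]
  rownames(ev) <- NULL

  list(evidence = ev,
       spikeins = data.frame(standard = names(config$spikein_amounts),
                             amount_pmol = as.numeric(config$spikein_amounts),
                             stringsAsFactors = FALSE),
       truth = list(specific_sites = specific, true_log10_matrix = true_mat,
                    sample_scale_factors = scale_fac, classes = classes,
                    detected = detected))
}

#' Configuration for the aCGH generator
#'
#' Defaults give a desk-scale genome of three 50-Mb chromosomes probed every
#' 25 kb (2,000 probes each), one planted focal high-level amplification
#' (20-fold over about 1.5 Mb, echoing a focal amplicon spanning tens of
#' probes), per-probe Gaussian log2-ratio noise SD 0.2, and 1% isolated
#' outlier probes at magnitude 2.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp)
#' @param probe_spacing bp between consecutive probes
#' @param planted_segments data.frame `chrom, start, end, fold_change`
#'   (1-based inclusive bp; `fold_change` relative to diploid, so log2 ratio
#'   inside is `log2(fold_change)`)
#' @param noise_sd per-probe Gaussian noise SD (log2)
#' @param outlier_rate,outlier_magnitude isolated-probe corruption model
#' @param seed integer RNG seed
#' @return a `cnv_sim_config` list, validated
#' @export
cnv_sim_config <- function(chrom_lengths = c(chr1 = 5e7, chr2 = 5e7,
                                             chr6 = 5e7),
                           probe_spacing = 25000,
                           planted_segments = data.frame(
                             chrom = "chr6", start = 2e7 + 1,
                             end = 2e7 + 15e5, fold_change = 20),
                           noise_sd = 0.2,
                           outlier_rate = 0.01, outlier_magnitude = 2,
                           seed = 1L) {
  cfg <- list(chrom_lengths = chrom_lengths, probe_spacing = probe_spacing,
              planted_segments = planted_segments, noise_sd = noise_sd,
              outlier_rate = outlier_rate,
              outlier_magnitude = outlier_magnitude, seed = as.integer(seed))
  bad <- function(field, msg)
    tf_stop(sprintf("invalid config field '%s': %s", field, msg),
            "tyroflow_config_error")
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0))
    bad("chrom_lengths", "need named positive lengths")
  if (cfg$probe_spacing <= 0) bad("probe_spacing", "must be positive")
  if (cfg$noise_sd < 0) bad("noise_sd", "negative")
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1) bad("outlier_rate",
                                                        "not in [0,1]")
  ps <- cfg$planted_segments
  if (!is.null(ps) && nrow(ps)) {
    if (any(!ps$chrom %in% names(cfg$chrom_lengths)))
      bad("planted_segments", "unknown chromosome")
    if (any(ps$fold_change <= 0)) bad("planted_segments", "fold_change <= 0")
    if (any(ps$start < 1) ||
        any(ps$end > cfg$chrom_lengths[ps$chrom]) || any(ps$start > ps$end))
      bad("planted_segments", "segment outside chromosome bounds")
    for (ch in unique(ps$chrom)) {
      s <- ps[ps$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        bad("planted_segments", paste0("overlapping segments on ", ch))
    }
  }
  class(cfg) <- "cnv_sim_config"
  cfg
}

#' Simulate an aCGH probe series with planted copy-number segments
#'
#' Probes are placed every `probe_spacing` bp. The log2 ratio is
#' `log2(fold_change)` plus Gaussian noise inside planted segments, pure noise
#' elsewhere; a fraction `outlier_rate` of probes is further perturbed by
#' `+/- outlier_magnitude`. The truth records the exact breakpoint probe
#' indices per chromosome.
#'
#' @param config a [cnv_sim_config()]
#' @return list with `probes` (data.frame `chrom, position, probe_id,
#'   log2_ratio`) and `truth` (planted segments with probe index bounds,
#'   outlier probe ids)
#' @export
simulate_acgh <- function(config = cnv_sim_config()) {
  stopifnot(inherits(config, "cnv_sim_config"))
  set.seed(config$seed)
  out <- list(); truth_seg <- list()
  for (ch in names(config$chrom_lengths)) {
    posn <- seq(config$probe_spacing, config$chrom_lengths[[ch]],
                by = config$probe_spacing)
    lr <- rnorm(length(posn), 0, config$noise_sd)
    ps <- config$planted_segments
    if (!is.null(ps) && nrow(ps)) {
      for (r in which(ps$chrom == ch)) {
        inside <- posn >= ps$start[r] & posn <= ps$end[r]
        lr[inside] <- lr[inside] + log2(ps$fold_change[r])
        truth_seg[[length(truth_seg) + 1L]] <- data.frame(
          chrom = ch, start = ps$start[r], end = ps$end[r],
          fold_change = ps$fold_change[r],
          probe_first = which(inside)[1],
          probe_last = which(inside)[sum(inside)])
      }
    }
    out[[ch]] <- data.frame(chrom = ch, position = posn,
                            probe_id = sprintf("%s_p%06d", ch,
                                               seq_along(posn)),
                            log2_ratio = lr, stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, out)
  rownames(probes) <- NULL
  n_out <- 0L; out_ids <- character(0)
  if (config$outlier_rate > 0) {
    hit <- runif(nrow(probes)) < config$outlier_rate
    sign <- sample(c(-1, 1), sum(hit), replace = TRUE)
    probes$log2_ratio[hit] <- probes$log2_ratio[hit] +
      sign * config$outlier_magnitude
    n_out <- sum(hit); out_ids <- probes$probe_id[hit]
  }
  tf_log("synthdata", "simulate_acgh", probes = nrow(probes),
         outliers = n_out)
  list(probes = probes,
       truth = list(segments = if (length(truth_seg))
         do.call(rbind, truth_seg) else NULL,
         outlier_probes = out_ids))
}
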