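## End-to-end orchestration: one config drives preprocess -> diffstats ->
## signature -> enrichment -> network -> summarize (and cnv when probes are
## given), with a run manifest (versions, seeds, checksums, row counts) and
## structured logging. Re-running with the same config and inputs reproduces
## all outputs bit-identically under the fixed seeds.

run_config_defaults <- function() {
  list(
    inputs = list(evidence = NULL, spikeins = NULL, gmt = NULL,
                  mouse_edges = NULL, human_edges = NULL,
                  orthologues = NULL, ks_edges = NULL, probes = NULL,
                  classes = NULL),
    min_loc_prob = 0.75,
    presence_fraction = 0.75,
    impute_k = 10,
    impute_fallback = "row_min",
    aggregate = "sum",
    q_threshold = 0.05,
    omnibus_q = NULL,
    rf_threshold = 1.2,
    rf_n_trees = 2000,
    cbs_alpha = 0.01,
    cbs_n_permutations = 1000,
    cbs_min_width = 2,
    smooth_trim_sd = 3,
    smooth_window = 5,
    merge_delta = 0.2,
    seed = 1L)
}

#' Assemble and validate a pipeline run configuration
#'
#' Defaults carry the pipeline's canonical tunables (localization filter
#' 0.75, presence fraction 0.75, k-NN k = 10 with `row_min` fallback,
#' q < 0.05, random-forest importance > 1.2, CBS alpha 0.01 with 1000
#' permutations, state thresholds -0.5/0.5/1.5, merge delta 0.2). Unknown
#' keys are rejected; the fully resolved config is written into the run
#' manifest.
#'
#' @param ... overrides of the default fields (see
#'   `tyroflow:::run_config_defaults()`), or a single named list
#' @param path optional YAML file of overrides
#' @return validated `run_config` list
#' @export
run_config <- function(..., path = NULL) {
  cfg <- run_config_defaults()
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  if (!is.null(path)) over <- utils::modifyList(yaml::read_yaml(path), over)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    tf_stop(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
            "tyroflow_config_error")
  if (!is.null(over$inputs)) {
    ui <- setdiff(names(over$inputs), names(cfg$inputs))
    if (length(ui))
      tf_stop(paste0("unknown input key(s): ", paste(ui, collapse = ", ")),
              "tyroflow_config_error")
    cfg$inputs <- utils::modifyList(cfg$inputs, over$inputs)
    over$inputs <- NULL
  }
  cfg <- utils::modifyList(cfg, over, keep.null = TRUE)
  stopifnot(cfg$min_loc_prob >= 0, cfg$min_loc_prob <= 1,
            cfg$presence_fraction > 0, cfg$presence_fraction <= 1,
            cfg$impute_k >= 1, cfg$q_threshold > 0, cfg$rf_n_trees >= 1,
            cfg$cbs_alpha > 0, cfg$cbs_alpha < 1)
  cfg$impute_fallback <- match.arg(cfg$impute_fallback,
                                   c("row_min", "col_mean"))
  class(cfg) <- "run_config"
  cfg
}

write_csv_out <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes preprocess, differential statistics, the two-step signature,
#' pathway enrichment and network construction when the relevant inputs are
#' present in the config, and the aCGH arm when probes are given. All outputs
#' land in `out_dir` as CSV/TSV/JSON; a `manifest.json` records the resolved
#' config, seeds, row counts and md5 checksums of every output. A stage
#' failure aborts with the stage name; outputs of completed stages are kept.
#'
#' @param config a [run_config()]
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly; the manifest describes everything written
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("tyroflow")),
    r_version = R.version.string,
    config = unclass(config), outputs = list(), counts = list())
  stage <- function(name, expr) {
    tf_log("pipeline", paste0("stage_start:", name))
    tryCatch(expr, error = function(e)
      tf_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "tyroflow_stage_error"))
  }
  inp <- config$inputs
  if (is.null(inp$evidence) || is.null(inp$classes))
    tf_stop("config must name evidence and classes inputs",
            "tyroflow_config_error")
  classes_df <- read.delim(inp$classes, sep = "\t", stringsAsFactors = FALSE)
  classes <- setNames(classes_df$class, classes_df$sample)

  mat_imp <- NULL; contrasts <- NULL; calls <- NULL

  ## ---- preprocess ----
  mat_imp <- stage("preprocess", {
    ev <- read_evidence(inp$evidence)
    manifest$counts$evidence_rows <- nrow(ev)
    ev <- filter_evidence(ev, config$min_loc_prob)
    manifest$counts$evidence_filtered <- nrow(ev)
    spk <- if (!is.null(inp$spikeins)) read_spikeins(inp$spikeins) else NULL
    fac <- compute_spikein_factors(ev, spk)
    mat <- collapse_to_sites(ev, fac, classes, aggregate = config$aggregate)
    manifest$counts$sites_quantified <- nrow(mat$values)
    keep <- reproducible_sites(mat, config$presence_fraction)
    manifest$counts$sites_reproducible <- length(keep)
    mat <- subset_sites(mat, keep)
    mi <- impute(mat, k = config$impute_k, fallback = config$impute_fallback)
    write_matrix(mi, file.path(out_dir, "matrix.tsv"))
    mi
  })

  ## ---- diffstats ----
  contrasts <- stage("diffstats", {
    ct <- fit_moderated_contrasts(mat_imp)
    calls <- call_class_specific(ct, config$q_threshold, config$omnibus_q)
    ct$call <- attr(calls, "call_column")
    write_csv_out(ct, file.path(out_dir, "contrasts.csv"))
    manifest$counts$class_specific <- lapply(calls, length)
    jsonlite::write_json(calls, file.path(out_dir, "class_specific.json"),
                         auto_unbox = FALSE)
    ct
  })

  ## ---- signature ----
  stage("signature", {
    model <- train_two_step(mat_imp, threshold = config$rf_threshold,
                            n_trees = config$rf_n_trees, seed = config$seed)
    write_signature(model, file.path(out_dir, "signature.json"))
    manifest$counts$signature_sites <- length(model$selected_sites)
  })

  ## ---- enrichment ----
  if (!is.null(inp$gmt)) stage("enrichment", {
    sets <- read_gmt(inp$gmt)
    background <- unique(parse_site_key(mat_imp$sites)$protein_id)
    for (cl in names(calls)) {
      fg <- unique(parse_site_key(calls[[cl]])$protein_id)
      if (!length(fg)) next
      res <- hypergeom_enrich(fg, background, sets)
      write_csv_out(res, file.path(out_dir,
                                   paste0("enrichment_", cl, ".csv")))
    }
  })

  ## ---- network ----
  if (!is.null(inp$mouse_edges)) stage("network", {
    me <- read_edges(inp$mouse_edges)
    he <- if (!is.null(inp$human_edges)) read_edges(inp$human_edges) else NULL
    ortho <- if (!is.null(inp$orthologues))
      read_orthologues(inp$orthologues) else NULL
    ks <- if (!is.null(inp$ks_edges)) read_edges(inp$ks_edges) else NULL
    for (cl in names(calls)) {
      prots <- unique(parse_site_key(calls[[cl]])$protein_id)
      if (!length(prots)) next
      net <- build_network(prots, me, he, ortho, ks)
      write_network(net, file.path(out_dir, paste0("network_", cl, ".tsv")),
                    file.path(out_dir, paste0("network_", cl, ".graphml")))
    }
  })

  ## ---- summarize ----
  stage("summarize", {
    cl_res <- hcluster(mat_imp)
    jsonlite::write_json(list(row_order = cl_res$row_order,
                              col_order = cl_res$col_order,
                              row_heights = cl_res$row_hclust$height,
                              col_heights = cl_res$col_hclust$height),
                         file.path(out_dir, "clustering.json"),
                         digits = NA)
    per_class_sets <- lapply(sort(unique(mat_imp$classes)), function(cl) {
      cols <- which(mat_imp$classes == cl)
      mat_imp$sites[rowSums(mat_imp$observed[, cols, drop = FALSE]) > 0]
    })
    names(per_class_sets) <- sort(unique(mat_imp$classes))
    ov <- overlap_counts(per_class_sets)
    jsonlite::write_json(list(regions = as.list(ov$regions),
                              totals = as.list(ov$totals),
                              union_size = ov$union_size),
                         file.path(out_dir, "overlap.json"),
                         auto_unbox = TRUE)
  })

  ## ---- cnv ----
  if (!is.null(inp$probes)) stage("cnv", {
    pr <- read_probes(inp$probes)
    pr <- normalise_probes(pr)
    pr <- smooth_outliers(pr, config$smooth_trim_sd, config$smooth_window)
    seg <- cbs_segment(pr, alpha = config$cbs_alpha,
                       n_permutations = config$cbs_n_permutations,
                       min_width = config$cbs_min_width, seed = config$seed)
    seg <- classify_segments(seg)
    seg <- merge_levels(seg, config$merge_delta)
    write_seg(seg, file.path(out_dir, "segments.seg"))
    write_amplified_bed(seg, file.path(out_dir, "amplified.bed"))
    manifest$counts$segments <- nrow(seg)
  })

  outs <- list.files(out_dir, full.names = TRUE)
  outs <- outs[basename(outs) != "manifest.json"]
  manifest$outputs <- lapply(setNames(outs, basename(outs)), function(f)
    list(md5 = unname(tools::md5sum(f)), bytes = file.size(f)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  tf_log("pipeline", "done", out_dir = out_dir)
  invisible(out_dir)
}
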