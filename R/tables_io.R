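## On-disk formats: evidence TSV, GMT gene sets, probe/edge/orthologue TSV,
## SEG-like segmentation output. Readers validate strictly and never silently
## drop rows; every exclusion downstream is counted and logged.

EVIDENCE_COLS <- c("sample", "protein", "gene", "residue", "position",
                   "loc_prob", "intensity", "flags")

#' Canonical pY site key
#'
#' Renders (protein accession, residue, 1-based position) as e.g.
#' `"P35569_Y608"`. The rendering is bijective and sorts lexicographically by
#' protein then position within equal-width padding-free keys.
#'
#' @param protein_id protein accession (no underscores enforced on parse side)
#' @param residue single residue letter, `"Y"` for tyrosine
#' @param position 1-based integer residue index
#' @return character vector of site keys
#' @export
site_key <- function(protein_id, residue, position) {
  stopifnot(all(position >= 1))
  paste0(protein_id, "_", residue, position)
}

#' Parse canonical site keys back into components
#' @param keys character vector as produced by [site_key()]
#' @return data.frame with protein_id, residue, position
#' @export
parse_site_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+)_([A-Z])([0-9]+)$", keys))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    tf_stop(paste0("malformed site key(s): ",
                   paste(keys[bad], collapse = ", ")), "tyroflow_format_error")
  data.frame(protein_id = vapply(m, `[`, "", 2L),
             residue    = vapply(m, `[`, "", 3L),
             position   = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

flags_to_string <- function(is_spikein, is_contaminant, is_reverse) {
  vapply(seq_along(is_spikein), function(i) {
    f <- c("spikein", "contaminant", "reverse")[
      c(is_spikein[i], is_contaminant[i], is_reverse[i])]
    if (length(f)) paste(f, collapse = ";") else ""
  }, "")
}

#' Read a MaxQuant-Evidence-style pY peptide table
#'
#' Expects a TSV with columns `sample, protein, gene, residue, position,
#' loc_prob, intensity, flags` (the `flags` field holds semicolon-separated
#' tokens among `spikein`, `contaminant`, `reverse`). Full MaxQuant
#' `evidence.txt` exports can be pointed at via `col_map`, a named character
#' vector mapping the required names to the file's actual header names.
#' Contaminant/reverse rows are retained but flagged; removal is a downstream
#' filtering step.
#'
#' @param path file path
#' @param col_map optional named character vector, e.g.
#'   `c(intensity = "Intensity")`
#' @return data.frame of evidence records with typed columns `sample_id,
#'   protein_id, gene_symbol, residue, position, localization_prob,
#'   raw_intensity, is_spikein, is_contaminant, is_reverse`
#' @export
read_evidence <- function(path, col_map = NULL) {
  if (!file.exists(path))
    tf_stop(paste0("evidence file not found: ", path), "tyroflow_io_error")
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  want <- EVIDENCE_COLS
  have <- want
  if (!is.null(col_map)) {
    stopifnot(!is.null(names(col_map)))
    have[match(names(col_map), want)] <- unname(col_map)
  }
  missing_cols <- setdiff(have, names(raw))
  if (length(missing_cols))
    tf_stop(paste0("evidence file ", path, " lacks required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "tyroflow_format_error")
  d <- raw[have]
  names(d) <- want
  n <- nrow(d)
  num <- function(col, name) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !(col %in% c("", "NA")))
    if (length(bad))
      tf_stop(sprintf("unparseable %s at line(s) %s of %s", name,
                      paste(bad + 1L, collapse = ","), path),
              "tyroflow_format_error")
    x
  }
  pos <- num(d$position, "position")
  lp  <- num(d$loc_prob, "loc_prob")
  int <- num(d$intensity, "intensity")
  if (any(!is.na(lp) & (lp < 0 | lp > 1)))
    tf_stop(sprintf("localization_prob outside [0,1] at line(s) %s of %s",
                    paste(which(lp < 0 | lp > 1) + 1L, collapse = ","), path),
            "tyroflow_format_error")
  if (any(!is.na(pos) & pos < 1))
    tf_stop("position must be >= 1", "tyroflow_format_error")
  if (any(!is.na(int) & int < 0))
    tf_stop("raw_intensity must be >= 0", "tyroflow_format_error")
  fl <- strsplit(d$flags, ";", fixed = TRUE)
  has <- function(tok) vapply(fl, function(f) tok %in% f, NA)
  out <- data.frame(
    sample_id = d$sample, protein_id = d$protein, gene_symbol = d$gene,
    residue = d$residue, position = as.integer(pos),
    localization_prob = lp, raw_intensity = int,
    is_spikein = has("spikein"), is_contaminant = has("contaminant"),
    is_reverse = has("reverse"), stringsAsFactors = FALSE)
  if (n == 0) out else out
}

#' Write evidence records in the dialect read by [read_evidence()]
#' @param records data.frame as returned by [read_evidence()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_evidence <- function(records, path) {
  d <- data.frame(sample = records$sample_id, protein = records$protein_id,
                  gene = records$gene_symbol, residue = records$residue,
                  position = records$position,
                  loc_prob = records$localization_prob,
                  intensity = records$raw_intensity,
                  flags = flags_to_string(records$is_spikein,
                                          records$is_contaminant,
                                          records$is_reverse),
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spike-in standard declarations
#'
#' TSV with columns `standard` (peptide id, matching `protein` of the spike-in
#' evidence rows) and `amount_pmol`.
#' @param path file path
#' @return data.frame with `standard`, `amount_pmol`
#' @export
read_spikeins <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("standard", "amount_pmol"))
    if (!col %in% names(d))
      tf_stop(paste0("spike-in file lacks column: ", col),
              "tyroflow_format_error")
  if (any(d$amount_pmol <= 0))
    tf_stop("spike-in amounts must be positive", "tyroflow_format_error")
  d[c("standard", "amount_pmol")]
}

#' @rdname read_spikeins
#' @param spikeins data.frame with `standard`, `amount_pmol`
#' @export
write_spikeins <- function(spikeins, path) {
  write.table(spikeins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member gene symbols. Members are
#' uppercased on read (case-insensitive matching downstream) and deduplicated.
#'
#' @param path GMT file
#' @return named list of character vectors; `attr(,"description")` per set kept
#'   in a `descriptions` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- list(); attr(out, "descriptions") <- character(0); return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short))
    tf_stop(sprintf("GMT line(s) %s have fewer than 3 fields",
                    paste(short, collapse = ",")), "tyroflow_format_error")
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, "", 2L),
                                         names(sets))
  sets
}

#' Read an aCGH probe table
#'
#' TSV with columns `chrom, position, probe_id, log2_ratio`. Output is sorted
#' by (chrom, position); duplicate probe ids are allowed (averaged later by
#' [normalise_probes()]).
#'
#' @param path file path
#' @return data.frame sorted by chrom then position
#' @export
read_probes <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "position", "probe_id", "log2_ratio")
  miss <- setdiff(need, names(d))
  if (length(miss))
    tf_stop(paste0("probe file lacks column(s): ",
                   paste(miss, collapse = ", ")), "tyroflow_format_error")
  if (any(is.na(d$position)) || any(d$position < 1))
    tf_stop("probe positions must be 1-based positive integers",
            "tyroflow_format_error")
  d <- d[order(d$chrom, d$position), need, drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @rdname read_probes
#' @param probes probe data.frame
#' @export
write_probes <- function(probes, path) {
  write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction edge list
#'
#' TSV with columns `node_a, node_b, provenance` (`mouse` or `human`) and
#' optional `directed` (logical; true only for kinase->substrate edges).
#' Undirected edges are stored with sorted endpoints and deduplicated; symbols
#' are uppercased for matching.
#'
#' @param path file path
#' @return data.frame `node_a, node_b, provenance, directed`
#' @export
read_edges <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("node_a", "node_b", "provenance")
  miss <- setdiff(need, names(d))
  if (length(miss))
    tf_stop(paste0("edge file lacks column(s): ",
                   paste(miss, collapse = ", ")), "tyroflow_format_error")
  if (!"directed" %in% names(d)) d$directed <- FALSE
  bad <- !d$provenance %in% c("mouse", "human")
  if (any(bad))
    tf_stop(sprintf("edge line(s) %s: provenance must be mouse|human",
                    paste(which(bad) + 1L, collapse = ",")),
            "tyroflow_format_error")
  d$node_a <- toupper(d$node_a); d$node_b <- toupper(d$node_b)
  und <- !d$directed
  swap <- und & d$node_a > d$node_b
  tmp <- d$node_a[swap]; d$node_a[swap] <- d$node_b[swap]; d$node_b[swap] <- tmp
  d <- unique(d[c("node_a", "node_b", "provenance", "directed")])
  rownames(d) <- NULL
  d
}

#' Read a mouse-to-human orthologue table
#'
#' TSV with columns `mouse, human`; must be at most 1:1 per mouse gene
#' (many-to-many rows are rejected: the table must be pre-resolved).
#'
#' @param path file path
#' @return named character vector mapping uppercased mouse symbol to
#'   uppercased human symbol
#' @export
read_orthologues <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("mouse", "human"), names(d))
  if (length(miss))
    tf_stop(paste0("orthologue file lacks column(s): ",
                   paste(miss, collapse = ", ")), "tyroflow_format_error")
  mu <- toupper(d$mouse)
  if (anyDuplicated(mu))
    tf_stop(paste0("orthologue table is not 1:1 for mouse gene(s): ",
                   paste(unique(mu[duplicated(mu)]), collapse = ", ")),
            "tyroflow_format_error")
  setNames(toupper(d$human), mu)
}

#' Write segmentation results in a SEG-like TSV
#'
#' Columns: `sample, chrom, start, end, n_probes, seg_mean, state, level`
#' (1-based inclusive bp intervals).
#' @param segments segmentation data.frame
#' @param path output path
#' @export
write_seg <- function(segments, path) {
  need <- c("sample", "chrom", "start", "end", "n_probes", "seg_mean", "state")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    tf_stop(paste0("segment table lacks column(s): ",
                   paste(miss, collapse = ", ")), "tyroflow_format_error")
  if (!"level" %in% names(segments)) segments$level <- NA_integer_
  write.table(segments[c(need, "level")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Serialise / deserialise an intensity matrix
#'
#' The matrix travels as a sites-by-samples TSV plus a JSON sidecar holding
#' the observation mask, per-cell provenance and sample class labels.
#'
#' @param mat a `py_matrix` (see [py_matrix()])
#' @param path TSV path; sidecar written at `paste0(path, ".json")`
#' @export
write_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "py_matrix"))
  d <- data.frame(site = mat$sites, mat$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(samples = mat$samples,
               classes = as.list(mat$classes),
               observed = unname(apply(mat$observed, 1, as.logical,
                                       simplify = FALSE)),
               provenance = unname(apply(mat$provenance, 1, as.character,
                                         simplify = FALSE)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  d <- read.delim(path, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(d[-1])
  rownames(vals) <- d$site
  obs <- do.call(rbind, lapply(seq_len(nrow(vals)), function(i)
    as.logical(side$observed[i, ])))
  prov <- do.call(rbind, lapply(seq_len(nrow(vals)), function(i)
    as.character(side$provenance[i, ])))
  dimnames(obs) <- dimnames(prov) <- dimnames(vals)
  py_matrix(vals, classes = unlist(side$classes), observed = obs,
            provenance = prov)
}
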