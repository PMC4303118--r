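## Hypergeometric pathway over-representation with Benjamini-Hochberg
## correction. One-sided upper tail: p = P(X >= k) for k foreground hits in a
## set of size K within a background of size N, foreground size n.

#' Hypergeometric gene-set over-representation
#'
#' The foreground must be a subset of the background; gene sets are first
#' intersected with the background (sets with empty intersection are skipped
#' and logged). Symbols are matched case-insensitively. Raw p-values are
#' upper-tail hypergeometric probabilities; BH adjustment is applied across
#' all tested sets.
#'
#' @param foreground character vector of genes of interest
#' @param background character vector, the gene universe (e.g. all genes with
#'   a quantified pY site)
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()])
#' @return data.frame sorted by `p_adj` with columns `set_name, k, K, n, N,
#'   p_raw, p_adj, genes`
#' @export
hypergeom_enrich <- function(foreground, background, gene_sets) {
  fg <- unique(toupper(foreground))
  bg <- unique(toupper(background))
  absent <- setdiff(fg, bg)
  if (length(absent))
    tf_stop(paste0("foreground gene(s) absent from background: ",
                   paste(absent, collapse = ", ")),
            "tyroflow_enrichment_error")
  N <- length(bg); n <- length(fg)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(toupper(gene_sets[[nm]])), bg)
    if (!length(members)) {
      tf_log("enrichment", "set_skipped_empty_intersection", set = nm)
      return(NULL)
    }
    K <- length(members)
    hits <- intersect(members, fg)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_raw = p,
               genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (!length(rows))
    return(data.frame(set_name = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), genes = character(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out <- out[order(out$p_adj, out$p_raw, out$set_name),
             c("set_name", "k", "K", "n", "N", "p_raw", "p_adj", "genes")]
  rownames(out) <- NULL
  out
}
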