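## Provenance-annotated protein interaction network over class-specific
## proteins: mouse edges, human edges borrowed through 1:1 orthologue
## mapping, and a directed kinase->substrate overlay. Backed by igraph behind
## the module contracts.

#' Map mouse gene symbols to human orthologues
#'
#' @param genes character vector of mouse gene symbols
#' @param ortho named character vector (mouse -> human, as from
#'   [read_orthologues()]); matching is case-insensitive
#' @return list with `mapped` (named character vector mouse -> human) and
#'   `unmapped` (character vector, never silently dropped)
#' @export
map_orthologues <- function(genes, ortho) {
  g <- toupper(genes)
  names(ortho) <- toupper(names(ortho))
  hit <- g %in% names(ortho)
  list(mapped = setNames(unname(ortho[g[hit]]), genes[hit]),
       unmapped = genes[!hit])
}

#' Build the annotated interaction network
#'
#' Induces the subgraph on `proteins` (gene symbols, case-folded): mouse
#' edges directly, human edges after translating the protein set through the
#' orthologue map. Each undirected edge carries provenance `mouse`, `human`
#' or `both` (present in both sources). Kinase->substrate edges are kept as a
#' separate directed overlay and by default do not contribute to hub degree.
#'
#' @param proteins character vector of gene symbols (node set)
#' @param mouse_edges,human_edges edge data.frames from [read_edges()] (the
#'   `provenance` column is ignored here; the argument determines it)
#' @param ortho orthologue map (mouse -> human) or `NULL` (mouse evidence
#'   only)
#' @param ks_edges optional directed kinase->substrate edge data.frame
#' @param node_class optional named vector of class labels per node
#' @param node_intensity optional named numeric vector (mean phospho
#'   intensity) per node
#' @return object of class `annotated_network`: `graph` (igraph, undirected,
#'   edge attr `provenance`), `ks_edges`, `nodes` data.frame with degree
#' @export
build_network <- function(proteins, mouse_edges = NULL, human_edges = NULL,
                          ortho = NULL, ks_edges = NULL,
                          node_class = NULL, node_intensity = NULL) {
  nodes <- unique(toupper(proteins))
  canon <- function(e) {
    if (is.null(e) || !nrow(e)) return(character(0))
    a <- toupper(e$node_a); b <- toupper(e$node_b)
    keep <- a %in% nodes & b %in% nodes & a != b
    a <- a[keep]; b <- b[keep]
    unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
  }
  m_keys <- canon(mouse_edges)
  ## translate the node set into human space, induce, translate back
  h_keys <- character(0)
  if (!is.null(human_edges) && nrow(human_edges)) {
    if (!is.null(ortho)) {
      mp <- map_orthologues(nodes, ortho)
      hum2mouse <- setNames(toupper(names(mp$mapped)), toupper(mp$mapped))
      he <- human_edges
      a <- toupper(he$node_a); b <- toupper(he$node_b)
      keep <- a %in% names(hum2mouse) & b %in% names(hum2mouse) & a != b
      a <- hum2mouse[a[keep]]; b <- hum2mouse[b[keep]]
      h_keys <- unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
    }
  }
  all_keys <- union(m_keys, h_keys)
  prov <- ifelse(all_keys %in% m_keys & all_keys %in% h_keys, "both",
                 ifelse(all_keys %in% m_keys, "mouse", "human"))
  ep <- if (length(all_keys))
    do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
  else matrix(character(0), 0, 2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ep[, 1][seq_len(nrow(ep))],
               to = ep[, 2][seq_len(nrow(ep))],
               provenance = prov, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(nodes), stringsAsFactors = FALSE))
  ks <- NULL
  if (!is.null(ks_edges) && nrow(ks_edges)) {
    a <- toupper(ks_edges$node_a); b <- toupper(ks_edges$node_b)
    keep <- a %in% nodes & b %in% nodes
    ks <- unique(data.frame(kinase = a[keep], substrate = b[keep],
                            stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(g)
  nd <- data.frame(node = names(deg), degree = as.integer(deg),
                   stringsAsFactors = FALSE)
  if (!is.null(node_class))
    nd$class <- unname(node_class[nd$node])
  if (!is.null(node_intensity))
    nd$mean_intensity <- unname(node_intensity[nd$node])
  structure(list(graph = g, ks_edges = ks, nodes = nd),
            class = "annotated_network")
}

#' @export
print.annotated_network <- function(x, ...) {
  pv <- table(igraph::E(x$graph)$provenance)
  cat(sprintf("annotated_network: %d nodes, %d undirected edges (%s), %d ks\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              paste(names(pv), pv, sep = "=", collapse = " "),
              if (is.null(x$ks_edges)) 0L else nrow(x$ks_edges)))
  invisible(x)
}

#' Rank network hubs by degree
#'
#' Stable ordering: degree descending, then node id ascending (deterministic
#' tie-break). Kinase->substrate overlay edges do not count toward degree.
#'
#' @param network an `annotated_network`
#' @param top_n number of nodes to return (default all)
#' @return data.frame `node, degree` in rank order
#' @export
rank_hubs <- function(network, top_n = Inf) {
  nd <- network$nodes
  nd <- nd[order(-nd$degree, nd$node), , drop = FALSE]
  rownames(nd) <- NULL
  head(nd, min(top_n, nrow(nd)))
}

#' Export a network as edge-list TSV and GraphML
#' @param network an `annotated_network`
#' @param tsv_path edge-list TSV path (`node_a, node_b, provenance`)
#' @param graphml_path optional GraphML path
#' @export
write_network <- function(network, tsv_path, graphml_path = NULL) {
  e <- igraph::as_data_frame(network$graph, what = "edges")
  names(e)[1:2] <- c("node_a", "node_b")
  if (!is.null(network$ks_edges) && nrow(network$ks_edges)) {
    ks <- data.frame(node_a = network$ks_edges$kinase,
                     node_b = network$ks_edges$substrate,
                     provenance = "kinase_substrate",
                     stringsAsFactors = FALSE)
    e <- rbind(e, ks)
  }
  write.table(e, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  invisible(tsv_path)
}
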