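#' Merge subpathways into a global regulatory network
#'
#' Union of the member edges (gene-gene and miRNA-target) of a set of
#' subpathways, typically the significant ones of a run.  Each edge's
#' weight is the number of distinct subpathways whose induced subgraph
#' contains it, with the contributing subpathway ids kept as
#' provenance.  Node weights follow the display convention of such
#' networks: a miRNA is weighted by its number of distinct linked
#' genes, a gene by its number of distinct linked miRNAs.  Nodes carry
#' a differential flag taken from the differential set.  Compound edge
#' labels are dropped in the network view; no new edges are inferred.
#'
#' @param subpathways List of `"subpathway"` objects.
#' @param rmpgs Named pathway graph collection; every subpathway must
#'   reference a pathway id present here.
#' @param diff A [differential_set()].
#' @return An object of class `"regulatory_network"`: a list with
#'   `nodes` (id, kind, differential, weight, subpathway count),
#'   `edges` (node_a, node_b, weight, subpathway_ids) and `graph`
#'   (weighted igraph).
#' @export
merge_network <- function(subpathways, rmpgs, diff) {
  rmpgs <- as_pathway_collection(rmpgs)
  stopifnot(inherits(diff, "differential_set"))
  for (sp in subpathways) {
    stopifnot(inherits(sp, "subpathway"))
    if (!sp$pathway_id %in% names(rmpgs)) {
      stop("subpathway '", sp$subpathway_id,
           "' references unknown pathway graph '", sp$pathway_id, "'",
           call. = FALSE)
    }
  }
  if (!length(subpathways)) {
    return(empty_regulatory_network())
  }
  edge_rows <- lapply(subpathways, function(sp) {
    if (!igraph::ecount(sp$graph)) return(NULL)
    el <- igraph::as_edgelist(sp$graph)
    data.frame(node_a = pmin(el[, 1], el[, 2]),
               node_b = pmax(el[, 1], el[, 2]),
               subpathway = sp$subpathway_id, stringsAsFactors = FALSE)
  })
  edge_rows <- do.call(rbind, edge_rows)
  node_rows <- do.call(rbind, lapply(subpathways, function(sp) {
    data.frame(id = igraph::V(sp$graph)$name,
               kind = igraph::V(sp$graph)$kind,
               subpathway = sp$subpathway_id, stringsAsFactors = FALSE)
  }))

  edges <- if (is.null(edge_rows)) {
    data.frame(node_a = character(), node_b = character(),
               weight = integer(), subpathway_ids = character(),
               stringsAsFactors = FALSE)
  } else {
    key <- paste(edge_rows$node_a, edge_rows$node_b, sep = "\r")
    prov <- lapply(split(edge_rows$subpathway, key),
                   function(x) sort(unique(x)))
    ab <- do.call(rbind, strsplit(names(prov), "\r", fixed = TRUE))
    out <- data.frame(node_a = ab[, 1], node_b = ab[, 2],
                      weight = lengths(prov),
                      subpathway_ids = vapply(prov, paste, character(1),
                                              collapse = ";"),
                      stringsAsFactors = FALSE)
    out <- out[order(out$node_a, out$node_b), , drop = FALSE]
    rownames(out) <- NULL
    out
  }

  node_prov <- lapply(split(node_rows$subpathway, node_rows$id),
                      function(x) sort(unique(x)))
  ids <- sort(unique(node_rows$id))
  kind <- vapply(ids, function(i)
    node_rows$kind[match(i, node_rows$id)], character(1))
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = ids, kind = unname(kind),
                          stringsAsFactors = FALSE))
  if (nrow(edges)) {
    igraph::E(g)$weight <- edges$weight
    igraph::E(g)$subpathway_ids <- edges$subpathway_ids
  }
  weight <- vapply(ids, function(i) {
    nb <- igraph::neighbors(g, i)
    if (kind[[i]] == "miRNA") sum(nb$kind == "gene")
    else sum(nb$kind == "miRNA")
  }, numeric(1))
  nodes <- data.frame(id = ids, kind = unname(kind),
                      differential = ids %in% c(diff$genes, diff$mirnas),
                      weight = as.integer(unname(weight)),
                      n_subpathways = lengths(node_prov[ids]),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "regulatory_network")
}

empty_regulatory_network <- function() {
  structure(list(
    nodes = data.frame(id = character(), kind = character(),
                       differential = logical(), weight = integer(),
                       n_subpathways = integer(), stringsAsFactors = FALSE),
    edges = data.frame(node_a = character(), node_b = character(),
                       weight = integer(), subpathway_ids = character(),
                       stringsAsFactors = FALSE),
    graph = igraph::make_empty_graph(0, directed = FALSE)),
    class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes (%d miRNAs), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "miRNA"), nrow(x$edges)))
  invisible(x)
}

#' Rank hub miRNAs of a regulatory network
#'
#' miRNAs ordered by number of distinct target genes in the merged
#' network (descending), ties broken by the number of subpathways the
#' miRNA participates in (descending), then by id.
#'
#' @param net A `"regulatory_network"`.
#' @param top Number of miRNAs to return.
#' @return Data frame with columns `mirna`, `n_targets`,
#'   `n_subpathways`.
#' @export
hub_mirnas <- function(net, top = 10) {
  stopifnot(inherits(net, "regulatory_network"), top >= 1)
  m <- net$nodes[net$nodes$kind == "miRNA", , drop = FALSE]
  out <- data.frame(mirna = m$id, n_targets = m$weight,
                    n_subpathways = m$n_subpathways,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targets, -out$n_subpathways, out$mirna), ,
             drop = FALSE]
  rownames(out) <- NULL
  head(out, top)
}

#' Write a regulatory network as node and edge TSV files
#'
#' @param net A `"regulatory_network"`.
#' @param nodes_path,edges_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_network_tsv <- function(net, nodes_path, edges_path) {
  stopifnot(inherits(net, "regulatory_network"))
  write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(nodes = nodes_path, edges = edges_path))
}

#' Export a regulatory network to GraphML
#'
#' Writes the weighted graph with node kind/differential attributes so
#' external viewers can reproduce size/width-scaled renderings.
#'
#' @param net A `"regulatory_network"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  g <- net$graph
  igraph::V(g)$differential <-
    net$nodes$differential[match(igraph::V(g)$name, net$nodes$id)]
  igraph::V(g)$weight <-
    net$nodes$weight[match(igraph::V(g)$name, net$nodes$id)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
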