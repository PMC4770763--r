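#' Embed miRNA regulators into a pathway graph
#'
#' For each miRNA in the interaction table with at least one verified
#' target among the graph's gene nodes, adds a miRNA node and one
#' undirected edge per (miRNA, in-graph target) pair.  miRNAs with no
#' in-graph target are omitted.  The gene-gene structure is untouched.
#' Edges are stored undirected so miRNA-target links participate in
#' shortest-path computations exactly like gene-gene links; the
#' regulatory direction (miRNA represses gene) is implied by the node
#' kinds.
#'
#' Interactions are expected to be deduplicated and filtered to
#' low-throughput evidence for the graph's species
#' (see [deduplicate_interactions()], [filter_low_throughput()]); this
#' is the caller's responsibility and is not re-checked here.
#'
#' @param graph A [pathway_graph()].
#' @param interactions Interaction data frame with columns `mirna` and
#'   `target`.
#' @return The reconstructed graph, of class `c("rmpg", "pathway_graph")`.
#' @export
embed_mirnas <- function(graph, interactions) {
  stopifnot(inherits(graph, "pathway_graph"),
            is.data.frame(interactions),
            all(c("mirna", "target") %in% names(interactions)))
  g <- graph$graph
  gene_ids <- igraph::V(g)$name[igraph::V(g)$kind == "gene"]
  hits <- interactions[interactions$target %in% gene_ids, , drop = FALSE]
  hits <- unique(hits[, c("mirna", "target")])
  hits <- hits[order(hits$mirna, hits$target), , drop = FALSE]
  if (nrow(hits)) {
    mirnas <- sort(unique(hits$mirna))
    new <- setdiff(mirnas, igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(new), name = new, kind = "miRNA")
    g <- igraph::add_edges(g, rbind(hits$mirna, hits$target),
                           kind = "mirna-target", compounds = "")
  }
  out <- graph
  out$graph <- g
  class(out) <- unique(c("rmpg", class(graph)))
  out
}

rmpg_counts <- function(p) {
  g <- p$graph
  kinds <- if (igraph::vcount(g)) igraph::V(g)$kind else character()
  ekinds <- if (igraph::ecount(g)) igraph::E(g)$kind else character()
  mir_idx <- which(kinds == "miRNA")
  targets <- if (length(mir_idx)) {
    unique(unlist(lapply(
      igraph::adjacent_vertices(g, mir_idx), function(v) v$name)))
  } else character()
  data.frame(pathway_id = p$pathway_id,
             n_nodes = igraph::vcount(g),
             n_genes = sum(kinds == "gene"),
             n_mirnas = sum(kinds == "miRNA"),
             n_targets = length(targets),
             n_gene_gene_edges = sum(ekinds == "gene-gene"),
             n_mirna_target_edges = sum(ekinds == "mirna-target"),
             stringsAsFactors = FALSE)
}

#' Summarize the composition of a pathway graph collection
#'
#' Reports, per graph, the number of nodes, genes, miRNAs, targets
#' (genes with at least one incident miRNA edge), gene-gene edges and
#' miRNA-target edges, together with the arithmetic means over the
#' collection and the number of distinct miRNAs embedded anywhere in
#' the collection (a miRNA embedded in several pathways counts once
#' globally, and once per pathway in the per-pathway table).
#'
#' @param rmpgs A list of [pathway_graph()]/RMPG objects (non-empty).
#' @return A list of class `"rmpg_summary"` with elements `per_pathway`
#'   (data frame), `means` (named numeric vector over the count columns)
#'   and `n_distinct_mirnas_global`.
#' @export
summarize_rmpgs <- function(rmpgs) {
  rmpgs <- as_pathway_collection(rmpgs)
  if (!length(rmpgs)) {
    stop("cannot summarize an empty collection (means undefined)",
         call. = FALSE)
  }
  per <- do.call(rbind, c(lapply(rmpgs, rmpg_counts),
                          list(make.row.names = FALSE)))
  count_cols <- setdiff(names(per), "pathway_id")
  means <- colMeans(per[count_cols])
  all_mirnas <- unlist(lapply(rmpgs, function(p) {
    g <- p$graph
    if (igraph::vcount(g)) igraph::V(g)$name[igraph::V(g)$kind == "miRNA"]
    else character()
  }))
  structure(list(per_pathway = per, means = means,
                 n_distinct_mirnas_global = length(unique(all_mirnas))),
            class = "rmpg_summary")
}

#' @export
print.rmpg_summary <- function(x, ...) {
  cat(sprintf("<rmpg_summary> %d pathway graph(s), %d distinct miRNA(s)\n",
              nrow(x$per_pathway), x$n_distinct_mirnas_global))
  cat("  means per graph:\n")
  for (nm in names(x$means)) {
    cat(sprintf("    %-22s %.2f\n", nm, x$means[[nm]]))
  }
  invisible(x)
}

#' Extract node ids of one kind from a pathway graph
#'
#' @param p A [pathway_graph()].
#' @param kind `"gene"` or `"miRNA"`.
#' @return Character vector of node ids.
#' @export
pathway_nodes <- function(p, kind = c("gene", "miRNA")) {
  kind <- match.arg(kind)
  g <- p$graph
  if (!igraph::vcount(g)) return(character())
  igraph::V(g)$name[igraph::V(g)$kind == kind]
}
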