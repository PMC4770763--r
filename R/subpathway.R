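#' Map differential molecules onto a pathway graph
#'
#' Signature nodes are the graph's nodes (genes or miRNAs) that are
#' differentially expressed under the studied condition.
#'
#' @param rmpg A [pathway_graph()] (typically miRNA-embedded).
#' @param diff A [differential_set()].
#' @return A list of class `"signature_set"` with elements `rmpg_id`
#'   and `nodes` (sorted character vector).
#' @export
map_signatures <- function(rmpg, diff) {
  stopifnot(inherits(rmpg, "pathway_graph"),
            inherits(diff, "differential_set"))
  g <- rmpg$graph
  nodes <- if (igraph::vcount(g)) igraph::V(g)$name else character()
  structure(list(rmpg_id = rmpg$pathway_id,
                 nodes = sort(intersect(c(diff$genes, diff$mirnas), nodes))),
            class = "signature_set")
}

#' Candidate node sets under the lenient-distance rule
#'
#' For every unordered pair of signature nodes, the shortest path
#' between them is inspected.  The pair is grouped into one candidate
#' set when some minimum-length path carries at most `n` non-signature
#' molecules strictly between the endpoints (signature molecules on the
#' path do not count against `n`: the rule bounds the number of
#' non-differential molecules tolerated between two differential ones).
#' The emitted set is the pair plus the interior nodes of ALL
#' minimum-length paths between the two, so the result does not depend
#' on an arbitrary traversal order.  Every signature also contributes
#' its own singleton set, so isolated signatures survive to the merge
#' step.
#'
#' @param rmpg A [pathway_graph()].
#' @param sig A `"signature_set"` from [map_signatures()] (or a
#'   character vector of node ids).
#' @param n Non-negative integer: maximum number of non-signature
#'   molecules permitted on the connecting shortest path.
#' @return A list of character vectors (candidate node sets).
#' @export
candidate_sets <- function(rmpg, sig, n = 1) {
  stopifnot(inherits(rmpg, "pathway_graph"), n >= 0)
  nodes <- if (inherits(sig, "signature_set")) sig$nodes else as.character(sig)
  g <- rmpg$graph
  if (length(nodes)) {
    stopifnot(all(nodes %in% igraph::V(g)$name))
  }
  sets <- lapply(nodes, function(v) v)        # singleton seeds
  if (length(nodes) >= 2) {
    d <- igraph::distances(g, v = nodes, to = nodes)
    is_sig <- igraph::V(g)$name %in% nodes
    names(is_sig) <- igraph::V(g)$name
    for (i in seq_len(length(nodes) - 1L)) {
      for (j in seq.int(i + 1L, length(nodes))) {
        dij <- d[i, j]
        if (!is.finite(dij) || dij == 0) next
        interior_len <- dij - 1
        # a path interior of size L can hold at most L signature nodes,
        # so the pair cannot qualify unless L - (#sigs on it) <= n
        if (interior_len > n + (length(nodes) - 2L)) next
        if (interior_len == 0) {
          sets[[length(sets) + 1L]] <- c(nodes[i], nodes[j])
          next
        }
        paths <- igraph::all_shortest_paths(g, from = nodes[i],
                                            to = nodes[j])$vpaths
        interiors <- lapply(paths, function(p) {
          ids <- p$name
          ids[-c(1L, length(ids))]
        })
        nonsig <- vapply(interiors, function(x) sum(!is_sig[x]), numeric(1))
        if (min(nonsig) <= n) {
          sets[[length(sets) + 1L]] <-
            unique(c(nodes[i], nodes[j], unlist(interiors)))
        }
      }
    }
  }
  sets
}

#' Merge candidate sets and extract subpathways
#'
#' Candidate sets sharing at least one node are transitively merged.
#' Each merged set is located in the pathway graph and its induced
#' subgraph extracted; every connected component of that subgraph with
#' at least `s` nodes becomes one subpathway.  Subpathway ids append an
#' ordinal suffix to the pathway id (`"path:00590_1"`, ...), assigned
#' by descending component size with ties broken by the
#' lexicographically smallest member id.
#'
#' @param rmpg A [pathway_graph()].
#' @param candidates List of character vectors (subsets of the graph's
#'   nodes), as from [candidate_sets()].
#' @param s Positive integer: minimum node count of a reported
#'   subpathway.
#' @param signatures Optional character vector of signature node ids,
#'   recorded on each subpathway as its `signature_nodes`.
#' @return A list of `"subpathway"` objects, each a list with elements
#'   `subpathway_id`, `pathway_id`, `pathway_name`, `nodes`, `graph`
#'   (induced igraph) and `signature_nodes`.
#' @export
merge_and_extract <- function(rmpg, candidates, s = 10,
                              signatures = character()) {
  stopifnot(inherits(rmpg, "pathway_graph"), s >= 1)
  g <- rmpg$graph
  candidates <- candidates[lengths(candidates) > 0]
  if (!length(candidates)) return(list())
  allnodes <- unique(unlist(candidates))
  stopifnot(all(allnodes %in% igraph::V(g)$name))

  # transitive merge = connected components of the "co-candidacy" graph
  # (star edges from each set's first member suffice)
  star <- do.call(rbind, lapply(candidates, function(set) {
    if (length(set) == 1L) return(NULL)
    cbind(set[1L], set[-1L])
  }))
  aux <- igraph::graph_from_data_frame(
    if (is.null(star)) data.frame(from = character(), to = character())
    else data.frame(from = star[, 1], to = star[, 2],
                    stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = allnodes))
  memb <- igraph::components(aux)$membership
  merged <- split(names(memb), memb)

  comps <- list()
  for (set in merged) {
    sub <- igraph::induced_subgraph(g, set)
    cm <- igraph::components(sub)$membership
    for (cnodes in split(names(cm), cm)) {
      if (length(cnodes) >= s) comps[[length(comps) + 1L]] <- sort(cnodes)
    }
  }
  if (!length(comps)) return(list())
  sizes <- lengths(comps)
  firsts <- vapply(comps, `[[`, character(1), 1L)
  ord <- order(-sizes, firsts)
  comps <- comps[ord]
  lapply(seq_along(comps), function(k) {
    nodes <- comps[[k]]
    structure(list(
      subpathway_id = paste0(rmpg$pathway_id, "_", k),
      pathway_id = rmpg$pathway_id,
      pathway_name = rmpg$name,
      nodes = nodes,
      graph = igraph::induced_subgraph(g, nodes),
      signature_nodes = sort(intersect(signatures, nodes))),
      class = "subpathway")
  })
}

#' @export
print.subpathway <- function(x, ...) {
  kinds <- igraph::V(x$graph)$kind
  cat(sprintf("<subpathway> %s: %d nodes (%d genes, %d miRNAs), %d signatures\n",
              x$subpathway_id, length(x$nodes), sum(kinds == "gene"),
              sum(kinds == "miRNA"), length(x$signature_nodes)))
  invisible(x)
}

#' Locate miRNA-mediated subpathways in one pathway graph
#'
#' Orchestrates [map_signatures()], [candidate_sets()] and
#' [merge_and_extract()]: differential genes and miRNAs are mapped onto
#' the graph as signature nodes, signatures within lenient distance
#' `n` of each other are grouped (together with the molecules on all
#' their minimum-length connecting paths), overlapping groups are
#' merged, and every connected induced subregion of at least `s` nodes
#' is reported as a subpathway.  Deterministic for fixed inputs.
#'
#' @inheritParams map_signatures
#' @param n,s Lenient-distance parameters; defaults `n = 1`, `s = 10`.
#' @return A list of `"subpathway"` objects (possibly empty).
#' @export
locate_subpathways <- function(rmpg, diff, n = 1, s = 10) {
  sig <- map_signatures(rmpg, diff)
  merge_and_extract(rmpg, candidate_sets(rmpg, sig, n = n), s = s,
                    signatures = sig$nodes)
}

#' Locate subpathways across a pathway graph collection
#'
#' @param rmpgs Named list of pathway graphs.
#' @inheritParams locate_subpathways
#' @return A flat list of `"subpathway"` objects from all graphs.
#' @export
locate_all <- function(rmpgs, diff, n = 1, s = 10) {
  rmpgs <- as_pathway_collection(rmpgs)
  out <- lapply(rmpgs, locate_subpathways, diff = diff, n = n, s = s)
  unname(do.call(c, out))
}
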