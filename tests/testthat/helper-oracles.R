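# Independent oracles used to cross-check the implementation.  They
# deliberately avoid the code paths (phyper, igraph) used by the
# package: the enrichment oracle enumerates draws, the locator oracle
# works on a plain adjacency list with hand-rolled BFS and set merging.

# Exhaustive-enumeration upper-tail hypergeometric probability:
# enumerate every possible draw of `n` from a universe of `m` whose
# first `t` elements are marked, and count draws with >= r marked.
enum_hyper_tail <- function(m, t, n, r) {
  if (r <= 0) return(1)
  if (n == 0) return(0)
  draws <- combn(m, n)
  hits <- colSums(draws <= t)
  mean(hits >= r)
}

# --- brute-force lenient-distance subpathway location ---------------

# adjacency list from an edge matrix (character endpoints)
adj_list <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

bfs_dist <- function(adj, from) {
  d <- setNames(rep(Inf, length(adj)), names(adj))
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!is.finite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

# all minimum-length paths from `from` to `to` by backtracking over
# BFS distance layers
all_shortest_paths_oracle <- function(adj, from, to) {
  d <- bfs_dist(adj, to)          # distance of every node TO the target
  if (!is.finite(d[from])) return(list())
  extend <- function(path) {
    v <- path[length(path)]
    if (v == to) return(list(path))
    nxt <- adj[[v]][d[adj[[v]]] == d[v] - 1]
    do.call(c, lapply(nxt, function(w) extend(c(path, w))))
  }
  extend(from)
}

# candidate sets, transitive merge, induced components and size filter
# on plain data structures
locate_oracle <- function(nodes, edges, signatures, n, s) {
  adj <- adj_list(nodes, edges)
  sets <- lapply(signatures, function(v) v)
  if (length(signatures) >= 2) {
    pairs <- combn(signatures, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      paths <- all_shortest_paths_oracle(adj, a, b)
      if (!length(paths)) next
      nonsig <- vapply(paths, function(p) {
        interior <- p[-c(1, length(p))]
        sum(!(interior %in% signatures))
      }, numeric(1))
      if (min(nonsig) <= n) {
        sets[[length(sets) + 1]] <- unique(unlist(paths))
      }
    }
  }
  # transitive merge by repeated pairwise union
  merged <- list()
  for (set in sets) {
    hit <- which(vapply(merged, function(m) length(intersect(m, set)) > 0,
                        logical(1)))
    if (length(hit)) {
      merged[[hit[1]]] <- union(merged[[hit[1]]],
                                unique(c(set, unlist(merged[hit]))))
      drop <- setdiff(hit, hit[1])
      if (length(drop)) merged <- merged[-drop]
    } else {
      merged[[length(merged) + 1]] <- set
    }
  }
  # induced connected components of each merged set, keep those >= s
  comps <- list()
  for (set in merged) {
    sub_adj <- lapply(adj[set], function(x) intersect(x, set))
    seen <- character()
    for (v in set) {
      if (v %in% seen) next
      comp <- v; queue <- v
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        new <- setdiff(sub_adj[[u]], comp)
        comp <- c(comp, new); queue <- c(queue, new)
      }
      seen <- c(seen, comp)
      if (length(comp) >= s) comps[[length(comps) + 1]] <- sort(comp)
    }
  }
  comps
}

# canonical form for comparing lists of node sets
canon_sets <- function(sets) {
  sets <- unname(lapply(sets, function(s) sort(unname(s))))
  sets[order(vapply(sets, paste, character(1), collapse = "|"))]
}

# random pathway_graph for property tests; returns graph + edge matrix
random_test_graph <- function(n_nodes, p_edge, pathway_id = "path:test") {
  ids <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- if (n_nodes >= 2) combn(ids, 2) else
    matrix(character(), nrow = 2)
  pick <- runif(ncol(pairs)) < p_edge
  edges <- data.frame(from = pairs[1, pick], to = pairs[2, pick],
                      compounds = rep("", sum(pick)),
                      stringsAsFactors = FALSE)
  list(pg = pathway_graph(pathway_id, "random test pathway", "hsa",
                          nodes = ids, edges = edges),
       nodes = ids,
       edges = as.matrix(edges[, c("from", "to")]))
}
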