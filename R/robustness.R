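# One master seed spawns per-replicate seeds so replicate r is
# reproducible in isolation.
replicate_seeds <- function(seed, replicates) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, replicates)
}

#' Randomly delete differential molecules
#'
#' The molecule-deletion stress protocol: for each replicate,
#' `floor(fraction * n)` of the differential genes and, independently,
#' of the differential miRNAs are removed uniformly at random.
#' Background universe counts are unchanged — the deletion emulates the
#' loss of condition-specific signal, not a shrinking genome.
#'
#' @param diff A [differential_set()].
#' @param fraction Deletion fraction in `[0, 1]`.
#' @param replicates Number of independent replicates.
#' @param seed Master seed; replicate-level seeds are derived from it.
#' @return A list of `replicates` differential sets.
#' @export
perturb_molecules <- function(diff, fraction, replicates = 1000, seed = 1) {
  stopifnot(inherits(diff, "differential_set"),
            fraction >= 0, fraction <= 1, replicates >= 1)
  seeds <- replicate_seeds(seed, replicates)
  kg <- floor(fraction * length(diff$genes))
  km <- floor(fraction * length(diff$mirnas))
  lapply(seeds, function(s) {
    set.seed(s)
    genes <- diff$genes
    mirnas <- diff$mirnas
    if (kg > 0) genes <- genes[-sample.int(length(genes), kg)]
    if (km > 0) mirnas <- mirnas[-sample.int(length(mirnas), km)]
    differential_set(genes, mirnas,
                     diff$background_gene_count,
                     diff$background_mirna_count)
  })
}

#' Randomly delete edges from pathway graphs
#'
#' The topology stress protocol: for each replicate and each graph,
#' `floor(fraction * |E|)` edges are removed uniformly at random.  With
#' `edge_classes = "pooled"` (default) gene-gene and miRNA-target edges
#' are drawn from one pool; with `"separate"` the floor count is
#' applied within each edge class.  miRNA nodes left without any edge
#' are pruned so the reconstructed-graph invariant (a miRNA node exists
#' only with at least one target edge) is preserved; gene nodes may
#' become isolated.
#'
#' @param rmpgs Named pathway graph collection.
#' @param fraction Deletion fraction in `[0, 1]`.
#' @param replicates Number of independent replicates.
#' @param seed Master seed.
#' @param edge_classes `"pooled"` or `"separate"`.
#' @return A list of `replicates` pathway graph collections.
#' @export
perturb_edges <- function(rmpgs, fraction, replicates = 1000, seed = 1,
                          edge_classes = c("pooled", "separate")) {
  rmpgs <- as_pathway_collection(rmpgs)
  edge_classes <- match.arg(edge_classes)
  stopifnot(fraction >= 0, fraction <= 1, replicates >= 1)
  seeds <- replicate_seeds(seed, replicates)
  lapply(seeds, function(s) {
    set.seed(s)
    lapply(rmpgs, function(p) {
      g <- p$graph
      ne <- igraph::ecount(g)
      if (ne) {
        drop <- if (edge_classes == "pooled") {
          k <- floor(fraction * ne)
          if (k > 0) sample.int(ne, k) else integer()
        } else {
          unlist(lapply(split(seq_len(ne), igraph::E(g)$kind), function(idx) {
            k <- floor(fraction * length(idx))
            if (k > 0) idx[sample.int(length(idx), k)] else integer()
          }), use.names = FALSE)
        }
        if (length(drop)) g <- igraph::delete_edges(g, drop)
      }
      lonely <- igraph::V(g)[igraph::V(g)$kind == "miRNA" &
                               igraph::degree(g) == 0]
      if (length(lonely)) g <- igraph::delete_vertices(g, lonely)
      out <- p
      out$graph <- g
      out
    })
  })
}

#' Recall of a reference pathway list after perturbation
#'
#' For each perturbed run, the fraction of the reference pathway ids it
#' recovers; summarized by the arithmetic mean over runs.
#'
#' @param reference Non-empty character vector of reference pathway
#'   ids.
#' @param perturbed_runs List of character vectors (pathway ids
#'   significant in each perturbed run).
#' @return A list of class `"recall_summary"` with `per_replicate`,
#'   `mean_recall` and `reference_size`.
#' @export
recall_ratio <- function(reference, perturbed_runs) {
  reference <- unique(as.character(reference))
  if (!length(reference)) {
    stop("'reference' must be a non-empty pathway id set", call. = FALSE)
  }
  per <- vapply(perturbed_runs, function(run)
    length(intersect(run, reference)) / length(reference), numeric(1))
  structure(list(per_replicate = per, mean_recall = mean(per),
                 reference_size = length(reference)),
            class = "recall_summary")
}

#' @export
print.recall_summary <- function(x, ...) {
  cat(sprintf("<recall_summary> mean recall %.3f over %d replicate(s), reference size %d\n",
              x$mean_recall, length(x$per_replicate), x$reference_size))
  invisible(x)
}

#' Perturbation-robustness protocol for the full pipeline
#'
#' Runs the complete identify-and-score pipeline on perturbed inputs
#' and reports, per deletion fraction, the mean recall of a reference
#' significant-pathway list.  A pathway is recalled when ANY of its
#' subpathways passes the FDR threshold in the perturbed run
#' (pathway-level recall).  `mode = "molecules"` deletes differential
#' molecules; `mode = "edges"` deletes graph edges.
#'
#' @param rmpgs Named pathway graph collection.
#' @param diff A [differential_set()].
#' @param reference Reference pathway ids; by default the pathways
#'   significant on the unperturbed input at `fdr_threshold`.
#' @param fractions Numeric vector of deletion fractions.
#' @param replicates Replicates per fraction.
#' @param seed Master seed.
#' @param mode `"molecules"` or `"edges"`.
#' @param n,s Lenient-distance parameters.
#' @param fdr_threshold Significance threshold on the FDR.
#' @param background_mode Passed to [score_subpathways()].
#' @param edge_classes Passed to [perturb_edges()].
#' @return A list with `detail` (data frame: fraction, replicate,
#'   recall), `summary` (data frame: fraction, mean_recall) and
#'   `reference`.
#' @export
run_robustness <- function(rmpgs, diff, reference = NULL,
                           fractions = seq(0.05, 0.30, by = 0.05),
                           replicates = 100, seed = 1,
                           mode = c("molecules", "edges"),
                           n = 1, s = 10, fdr_threshold = 0.01,
                           background_mode = "genome",
                           edge_classes = "pooled") {
  mode <- match.arg(mode)
  rmpgs <- as_pathway_collection(rmpgs)
  significant_pathways <- function(graphs, d) {
    subs <- locate_all(graphs, d, n = n, s = s)
    res <- score_subpathways(subs, d, background_mode = background_mode,
                             rmpgs = graphs)
    unique(res$pathway_id[res$fdr < fdr_threshold])
  }
  if (is.null(reference)) reference <- significant_pathways(rmpgs, diff)
  detail <- list()
  for (f in fractions) {
    runs <- if (mode == "molecules") {
      lapply(perturb_molecules(diff, f, replicates, seed),
             function(d) significant_pathways(rmpgs, d))
    } else {
      lapply(perturb_edges(rmpgs, f, replicates, seed,
                           edge_classes = edge_classes),
             function(gs) significant_pathways(gs, diff))
    }
    rs <- recall_ratio(reference, runs)
    detail[[length(detail) + 1L]] <-
      data.frame(fraction = f, replicate = seq_len(replicates),
                 recall = rs$per_replicate)
  }
  detail <- do.call(rbind, c(detail, list(make.row.names = FALSE)))
  summary <- aggregate(recall ~ fraction, detail, mean)
  names(summary)[2] <- "mean_recall"
  list(detail = detail, summary = summary, reference = reference)
}
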