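#' Build reconstructed pathway graphs from raw inputs
#'
#' Convenience wrapper over the cleaning and embedding steps: the raw
#' interaction table is deduplicated, restricted to low-throughput
#' evidence for the target species, and embedded into every pathway
#' graph of the collection.
#'
#' @param pathways Named list of [pathway_graph()] objects.
#' @param interactions Raw interaction data frame
#'   (see [read_interactions()]).
#' @param species Organism code.
#' @return Named list of miRNA-embedded pathway graphs.
#' @export
build_rmpgs <- function(pathways, interactions, species = "hsa") {
  pathways <- as_pathway_collection(pathways)
  keep <- filter_low_throughput(deduplicate_interactions(interactions),
                                species)
  if (!nrow(keep)) {
    warning("no low-throughput interactions for species '", species,
            "'; graphs will contain no miRNA nodes", call. = FALSE)
  }
  lapply(pathways, embed_mirnas, interactions = keep)
}

#' Identify and score miRNA-mediated subpathways
#'
#' The central pipeline step: locates subpathways in every graph with
#' the lenient-distance rule and scores them with the joint gene+miRNA
#' hypergeometric test, FDR-adjusted over the whole run.  An empty
#' result table is a valid result (no signatures, or none of the
#' candidate regions reach size `s`).
#'
#' @param rmpgs Named pathway graph collection.
#' @param diff A [differential_set()].
#' @param n,s Lenient-distance parameters (defaults 1 and 10).
#' @param background_mode Passed to [score_subpathways()].
#' @param fdr_threshold If non-`NULL`, the returned `results` are
#'   restricted to rows with `fdr <` threshold (the full table is kept
#'   in `all_results`).
#' @return A list with `results` (filtered enrichment table),
#'   `all_results` and `subpathways` (the located objects).
#' @export
run_identify <- function(rmpgs, diff, n = 1, s = 10,
                         background_mode = "genome",
                         fdr_threshold = NULL) {
  rmpgs <- as_pathway_collection(rmpgs)
  subs <- locate_all(rmpgs, diff, n = n, s = s)
  res <- score_subpathways(subs, diff, background_mode = background_mode,
                           rmpgs = rmpgs)
  filtered <- if (is.null(fdr_threshold)) res else
    res[res$fdr < fdr_threshold, , drop = FALSE]
  list(results = filtered, all_results = res, subpathways = subs)
}

baseline_table <- function(rows, which) {
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(pathway_id = character(), pathway_name = character(),
               m = integer(), n = integer(), t = integer(), r = integer(),
               p_value = numeric(), stringsAsFactors = FALSE)
  }
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$fdr, out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline") <- which
  out
}

#' Complete-pathway baseline enrichment tests
#'
#' The two classical comparators, both at the complete-pathway level:
#' gene-only over-representation analysis ([ora_pvalue()]) and the
#' miRNA-only test ([mirna_pvalue()]) in which each miRNA linked to a
#' pathway counts once, however many targets it has there.  Each table
#' carries its own Benjamini-Hochberg FDR family over the pathway
#' collection.
#'
#' @inheritParams run_identify
#' @return A list with data frames `ora` and `mirna`, columns
#'   `pathway_id`, `pathway_name`, `m`, `n`, `t`, `r`, `p_value`,
#'   `fdr`.
#' @export
run_baselines <- function(rmpgs, diff, background_mode = "genome") {
  rmpgs <- as_pathway_collection(rmpgs)
  stopifnot(inherits(diff, "differential_set"))
  u <- universe_from_mode(match.arg(background_mode,
                                    c("genome", "annotated")),
                          diff, rmpgs)
  ora_rows <- lapply(rmpgs, function(p) {
    genes <- pathway_nodes(p, "gene")
    r <- length(intersect(genes, diff$genes))
    data.frame(pathway_id = p$pathway_id, pathway_name = p$name,
               m = u$m_g, n = u$n_g, t = length(genes), r = r,
               p_value = ora_pvalue(u$m_g, u$n_g, length(genes), r),
               stringsAsFactors = FALSE)
  })
  mir_rows <- lapply(rmpgs, function(p) {
    mirs <- pathway_nodes(p, "miRNA")
    r <- length(intersect(mirs, diff$mirnas))
    data.frame(pathway_id = p$pathway_id, pathway_name = p$name,
               m = u$m_mir, n = u$n_mir, t = length(mirs), r = r,
               p_value = mirna_pvalue(u$m_mir, u$n_mir, length(mirs), r),
               stringsAsFactors = FALSE)
  })
  list(ora = baseline_table(unname(ora_rows), "ora"),
       mirna = baseline_table(unname(mir_rows), "mirna"))
}

#' Compare two significant-pathway lists
#'
#' Reproducibility check between two runs (e.g. two independent data
#' sets for the same disease): reports the shared pathway ids and the
#' upper-tail hypergeometric probability of an overlap at least that
#' large given the pathway universe.
#'
#' @param list_a,list_b Character vectors of pathway ids.
#' @param universe Number of pathways in the universe (must be at
#'   least the size of each list).
#' @return A list with `shared` (character vector), `n_shared`,
#'   `size_a`, `size_b`, `universe` and `p_value`.
#' @export
compare_pathway_lists <- function(list_a, list_b, universe) {
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  if (universe < max(length(list_a), length(list_b))) {
    stop("'universe' (", universe, ") is smaller than a list (",
         max(length(list_a), length(list_b)), ")", call. = FALSE)
  }
  shared <- sort(intersect(list_a, list_b))
  list(shared = shared, n_shared = length(shared),
       size_a = length(list_a), size_b = length(list_b),
       universe = as.integer(universe),
       p_value = overlap_pvalue(universe, length(list_a),
                                length(list_b), length(shared)))
}
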