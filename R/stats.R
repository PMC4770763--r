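#' Enrichment count vector for the joint gene+miRNA test
#'
#' Bundles the eight integers feeding the pooled hypergeometric
#' statistic: the background universe sizes (`m_g` genes in the entire
#' genome, `m_mir` miRNAs in the entire miRNAome), the differential
#' counts (`n_g`, `n_mir`), the subpathway composition (`t_g` genes,
#' `t_mir` miRNAs) and the differential members of the subpathway
#' (`r_g`, `r_mir`).
#'
#' @param m_g,m_mir,n_g,n_mir,t_g,t_mir,r_g,r_mir Non-negative integers.
#' @return An object of class `"enrichment_counts"` (named list).
#' @export
enrichment_counts <- function(m_g, m_mir, n_g, n_mir,
                              t_g, t_mir, r_g, r_mir) {
  x <- list(m_g = m_g, m_mir = m_mir, n_g = n_g, n_mir = n_mir,
            t_g = t_g, t_mir = t_mir, r_g = r_g, r_mir = r_mir)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v)) {
      stop("'", nm, "' must be a single non-negative integer", call. = FALSE)
    }
    x[[nm]] <- as.integer(v)
  }
  check_le <- function(a, b, na, nb) {
    if (x[[na]] > x[[nb]]) {
      stop("invalid enrichment counts: ", na, " (", x[[na]],
           ") must be <= ", nb, " (", x[[nb]], ")", call. = FALSE)
    }
  }
  check_le(x$n_g, x$m_g, "n_g", "m_g")
  check_le(x$n_mir, x$m_mir, "n_mir", "m_mir")
  check_le(x$t_g, x$m_g, "t_g", "m_g")
  check_le(x$t_mir, x$m_mir, "t_mir", "m_mir")
  check_le(x$r_g, x$n_g, "r_g", "n_g")
  check_le(x$r_g, x$t_g, "r_g", "t_g")
  check_le(x$r_mir, x$n_mir, "r_mir", "n_mir")
  check_le(x$r_mir, x$t_mir, "r_mir", "t_mir")
  structure(x, class = "enrichment_counts")
}

# Upper-tail hypergeometric P(X >= r) for X ~ Hyper(total m, marked t,
# drawn n), via the survival function in log space, clamped to [0,1].
hyper_upper_tail <- function(m, t, n, r) {
  if (r <= 0) return(1)
  if (r > min(t, n)) return(0)
  p <- phyper(r - 1, t, m - t, n, lower.tail = FALSE)
  min(max(p, 0), 1)
}

#' Joint gene+miRNA subpathway enrichment P-value
#'
#' Exact upper-tail hypergeometric probability of observing at least
#' `r_g + r_mir` subpathway molecules among `n_g + n_mir` differential
#' molecules drawn from a pooled universe of `m_g + m_mir` molecules of
#' which `t_g + t_mir` belong to the subpathway:
#' \deqn{P = 1 - \sum_{k=0}^{r_g+r_{mir}-1}
#'   \frac{\binom{t_g+t_{mir}}{k}
#'         \binom{m_g+m_{mir}-t_g-t_{mir}}{n_g+n_{mir}-k}}
#'        {\binom{m_g+m_{mir}}{n_g+n_{mir}}}}
#' Genes and miRNAs are treated as exchangeable draws from one urn, so
#' a subpathway can reach significance through its differential genes,
#' its differential miRNA regulators, or both jointly.
#'
#' @param counts An [enrichment_counts()] object.
#' @return A probability in `[0, 1]`.
#' @export
subpathway_pvalue <- function(counts) {
  if (!inherits(counts, "enrichment_counts")) {
    counts <- do.call(enrichment_counts, as.list(counts))
  }
  hyper_upper_tail(counts$m_g + counts$m_mir,
                   counts$t_g + counts$t_mir,
                   counts$n_g + counts$n_mir,
                   counts$r_g + counts$r_mir)
}

#' Gene-only over-representation P-value
#'
#' Classical ORA: the same upper-tail hypergeometric test restricted to
#' gene counts, applied at the complete-pathway level.
#'
#' @param m_g Gene universe size.
#' @param n_g Number of differential genes.
#' @param t_g Number of genes in the pathway.
#' @param r_g Number of differential genes in the pathway.
#' @return A probability in `[0, 1]`.
#' @export
ora_pvalue <- function(m_g, n_g, t_g, r_g) {
  c <- enrichment_counts(m_g, 0, n_g, 0, t_g, 0, r_g, 0)
  hyper_upper_tail(c$m_g, c$t_g, c$n_g, c$r_g)
}

#' miRNA-only enrichment P-value
#'
#' The miRNA-level analogue of ORA at the complete-pathway level: each
#' miRNA linked to the pathway counts once, regardless of how many of
#' its targets the pathway contains.
#'
#' @param m_mir miRNA universe (miRNAome) size.
#' @param n_mir Number of differential miRNAs.
#' @param t_mir Number of distinct miRNAs linked to the pathway.
#' @param r_mir Number of distinct differential miRNAs linked to it.
#' @return A probability in `[0, 1]`.
#' @export
mirna_pvalue <- function(m_mir, n_mir, t_mir, r_mir) {
  c <- enrichment_counts(0, m_mir, 0, n_mir, 0, t_mir, 0, r_mir)
  hyper_upper_tail(c$m_mir, c$t_mir, c$n_mir, c$r_mir)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up false discovery rate adjustment, order-preserving with the
#' input vector.
#'
#' @param p_values Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) &&
      (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Significance of the overlap between two pathway lists
#'
#' Upper-tail hypergeometric probability of sharing at least `shared`
#' pathways when two lists of `size_a` and `size_b` pathways are drawn
#' from a universe of `universe` pathways.  Used for reproducibility
#' analyses across independent data sets; symmetric in `size_a` and
#' `size_b`.
#'
#' @param universe Positive integer, number of pathways in the universe.
#' @param size_a,size_b List sizes (each `<= universe`).
#' @param shared Number of shared pathways (`<= min(size_a, size_b)`).
#' @return A probability in `[0, 1]`.
#' @export
overlap_pvalue <- function(universe, size_a, size_b, shared) {
  for (v in list(universe, size_a, size_b, shared)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v)) {
      stop("all arguments must be single non-negative integers",
           call. = FALSE)
    }
  }
  if (universe < 1) stop("'universe' must be positive", call. = FALSE)
  if (size_a > universe || size_b > universe) {
    stop("list sizes cannot exceed the universe size", call. = FALSE)
  }
  if (shared > min(size_a, size_b)) {
    stop("'shared' cannot exceed the smaller list size", call. = FALSE)
  }
  hyper_upper_tail(universe, size_a, size_b, shared)
}

subpathway_count_row <- function(sp, diff, m_g, m_mir, n_g, n_mir) {
  kinds <- igraph::V(sp$graph)$kind
  ids <- igraph::V(sp$graph)$name
  genes <- ids[kinds == "gene"]
  mirs <- ids[kinds == "miRNA"]
  enrichment_counts(m_g, m_mir, n_g, n_mir,
                    length(genes), length(mirs),
                    length(intersect(genes, diff$genes)),
                    length(intersect(mirs, diff$mirnas)))
}

universe_from_mode <- function(background_mode, diff, rmpgs) {
  if (background_mode == "genome") {
    list(m_g = diff$background_gene_count,
         m_mir = diff$background_mirna_count,
         n_g = length(diff$genes), n_mir = length(diff$mirnas))
  } else {
    if (is.null(rmpgs)) {
      stop("background_mode = 'annotated' requires the RMPG collection",
           call. = FALSE)
    }
    genes <- unique(unlist(lapply(rmpgs, pathway_nodes, kind = "gene")))
    mirs <- unique(unlist(lapply(rmpgs, pathway_nodes, kind = "miRNA")))
    list(m_g = length(genes), m_mir = length(mirs),
         n_g = length(intersect(diff$genes, genes)),
         n_mir = length(intersect(diff$mirnas, mirs)))
  }
}

#' Score located subpathways
#'
#' Computes the eight enrichment counts for every subpathway, the joint
#' gene+miRNA hypergeometric P-value, and Benjamini-Hochberg FDR values
#' adjusted jointly over all subpathways of the run (one FDR family per
#' result list, not per pathway).
#'
#' With `background_mode = "genome"` (default) the universe sizes are
#' the caller-supplied background counts of the differential set — the
#' entire genome and miRNAome.  With `"annotated"` the universe is the
#' union of molecules across the supplied pathway graph collection, the
#' common ORA convention; differential counts are then restricted to
#' that universe.
#'
#' @param subpathways List of `"subpathway"` objects.
#' @param diff A [differential_set()].
#' @param background_mode `"genome"` or `"annotated"`.
#' @param rmpgs Pathway graph collection; required for `"annotated"`.
#' @return A data frame (class `"enrichment_table"`) with the ids, the
#'   eight counts, `p_value` and `fdr`, sorted by `fdr` then `p_value`;
#'   attributes `background_mode`, `m_g` and `m_mir` record the
#'   universe used.
#' @export
score_subpathways <- function(subpathways, diff,
                              background_mode = c("genome", "annotated"),
                              rmpgs = NULL) {
  background_mode <- match.arg(background_mode)
  stopifnot(inherits(diff, "differential_set"))
  u <- universe_from_mode(background_mode, diff, rmpgs)
  rows <- lapply(subpathways, function(sp) {
    stopifnot(inherits(sp, "subpathway"))
    cnt <- subpathway_count_row(sp, diff, u$m_g, u$m_mir, u$n_g, u$n_mir)
    data.frame(subpathway_id = sp$subpathway_id,
               pathway_id = sp$pathway_id,
               pathway_name = sp$pathway_name,
               as.data.frame(unclass(cnt)),
               p_value = subpathway_pvalue(cnt),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    empty_enrichment_table()
  }
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$fdr, out$p_value, out$subpathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "background_mode") <- background_mode
  attr(out, "m_g") <- u$m_g
  attr(out, "m_mir") <- u$m_mir
  class(out) <- c("enrichment_table", class(out))
  out
}

empty_enrichment_table <- function() {
  data.frame(subpathway_id = character(), pathway_id = character(),
             pathway_name = character(),
             m_g = integer(), m_mir = integer(), n_g = integer(),
             n_mir = integer(), t_g = integer(), t_mir = integer(),
             r_g = integer(), r_mir = integer(),
             p_value = numeric(), stringsAsFactors = FALSE)
}

#' Write an enrichment result table to TSV
#'
#' A comment line records the background mode and universe sizes so a
#' report is self-describing; an optional FDR threshold filters rows.
#'
#' @param results Data frame from [score_subpathways()] or the baseline
#'   functions.
#' @param path Output path.
#' @param fdr_threshold Keep rows with `fdr <` this value; `NULL` keeps
#'   all rows.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path, fdr_threshold = NULL) {
  if (!is.null(fdr_threshold)) {
    results <- results[results$fdr < fdr_threshold, , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  mode <- attr(results, "background_mode")
  if (!is.null(mode)) {
    writeLines(sprintf("# background_mode=%s m_g=%d m_mir=%d", mode,
                       attr(results, "m_g"), attr(results, "m_mir")), con)
  }
  write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
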