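#' Specification for the synthetic pathway fixture generator
#'
#' Defines the shape of a simulated study: a collection of connected
#' random metabolic-style pathway graphs, a raw miRNA-target
#' interaction table (with redundant and high-throughput rows so the
#' cleaning steps are exercised), and a differential molecule set in
#' which one pathway carries a planted, densely differential connected
#' subregion targeted by differential miRNAs, against a uniform
#' low-rate differential background.
#'
#' Defaults are sized after real reconstructed metabolic pathway
#' collections: ~50 genes and ~140 gene-gene edges per pathway, a few
#' embeddable miRNAs per pathway, a planted region of 12 molecules at
#' 90% signature density versus a 5% differential background, and
#' off-pathway background molecules so the genome/miRNAome universes
#' exceed the annotated molecules.
#'
#' @param n_pathways Number of pathway graphs.
#' @param genes_per_pathway Length-2 integer range of genes per
#'   pathway.
#' @param edge_density Probability of each extra gene-gene edge beyond
#'   the connecting spanning tree.
#' @param n_mirnas Number of distinct miRNAs in the interaction table.
#' @param targets_per_mirna Length-2 integer range of verified targets
#'   per miRNA.
#' @param planted_pathway_index Index of the pathway carrying the
#'   planted region.
#' @param planted_region_size Number of genes in the planted connected
#'   region (must fit in the pathway and be at least the default
#'   minimum subpathway size, 10).
#' @param planted_mirnas Number of differential miRNAs wired to the
#'   planted region.
#' @param planted_signature_fraction Fraction of planted-region genes
#'   that are differential.
#' @param background_signature_fraction Differential fraction among all
#'   other genes and miRNAs (on- and off-pathway).
#' @param off_pathway_genes,off_pathway_mirnas Background molecules not
#'   annotated to any pathway (they enlarge the universes and the
#'   differential lists but never map onto a graph).
#' @param species Organism code stamped on all outputs.
#' @param seed Seed fixing all randomness.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_pathways = 12,
                         genes_per_pathway = c(40, 60),
                         edge_density = 0.08,
                         n_mirnas = 40,
                         targets_per_mirna = c(2, 5),
                         planted_pathway_index = 1,
                         planted_region_size = 12,
                         planted_mirnas = 3,
                         planted_signature_fraction = 0.9,
                         background_signature_fraction = 0.05,
                         off_pathway_genes = 1400,
                         off_pathway_mirnas = 60,
                         species = "hsa",
                         seed = 1) {
  check_species(species)
  stopifnot(n_pathways >= 1, length(genes_per_pathway) == 2,
            genes_per_pathway[1] <= genes_per_pathway[2],
            edge_density >= 0, edge_density <= 1,
            n_mirnas >= 1, length(targets_per_mirna) == 2,
            planted_pathway_index >= 1,
            planted_pathway_index <= n_pathways,
            planted_region_size >= 1,
            planted_mirnas >= 0, planted_mirnas <= n_mirnas,
            planted_signature_fraction >= 0,
            planted_signature_fraction <= 1,
            background_signature_fraction >= 0,
            background_signature_fraction <= 1)
  if (planted_region_size > genes_per_pathway[1]) {
    stop("planted_region_size (", planted_region_size,
         ") exceeds the smallest possible pathway (",
         genes_per_pathway[1], " genes)", call. = FALSE)
  }
  structure(as.list(environment()), class = "fixture_spec")
}

# Connected random graph: random recursive spanning tree plus
# Bernoulli(edge_density) extra edges.
random_connected_edges <- function(ids, density) {
  n <- length(ids)
  edges <- if (n >= 2) {
    data.frame(from = ids[vapply(2:n, function(i)
      sample.int(i - 1L, 1L), integer(1))],
      to = ids[2:n], stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character())
  }
  if (n >= 3 && density > 0) {
    pairs <- combn(ids, 2)
    pick <- stats::runif(ncol(pairs)) < density
    extra <- data.frame(from = pairs[1, pick], to = pairs[2, pick],
                        stringsAsFactors = FALSE)
    edges <- rbind(edges, extra)
  }
  edges
}

# Connected region of `size` nodes grown by breadth-first search from a
# random start.
grow_region <- function(graph, size) {
  start <- sample(igraph::V(graph)$name, 1)
  ord <- igraph::bfs(graph, root = start, order = TRUE)$order
  region <- igraph::V(graph)$name[ord[seq_len(size)]]
  stopifnot(igraph::is_connected(igraph::induced_subgraph(graph, region)))
  region
}

#' Generate a synthetic pathway study
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `"pathway_fixture"` with elements
#'   `pathways` (named list of [pathway_graph()]), `interactions` (raw
#'   table, including planted redundant and high-throughput rows),
#'   `diff` ([differential_set()]) and `truth` (planted pathway id,
#'   planted node ids, planted signature ids).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  gene_counter <- 0L
  pathways <- list()
  pathway_genes <- list()
  for (i in seq_len(spec$n_pathways)) {
    ng <- sample(seq(spec$genes_per_pathway[1], spec$genes_per_pathway[2]),
                 1)
    ids <- sprintf("G%05d", gene_counter + seq_len(ng))
    gene_counter <- gene_counter + ng
    edges <- random_connected_edges(ids, spec$edge_density)
    edges$compounds <- sprintf("C%05d", sample.int(99999, nrow(edges)))
    pid <- sprintf("path:t%04d", i)
    pathways[[pid]] <- pathway_graph(pid, sprintf("synthetic pathway %d", i),
                                     spec$species, nodes = ids,
                                     edges = edges)
    pathway_genes[[pid]] <- ids
  }

  planted_pid <- names(pathways)[spec$planted_pathway_index]
  region <- grow_region(pathways[[planted_pid]]$graph,
                        spec$planted_region_size)

  all_genes <- unlist(pathway_genes, use.names = FALSE)
  mirna_ids <- sprintf("mir-%03d", seq_len(spec$n_mirnas))
  planted_mirs <- if (spec$planted_mirnas > 0) {
    mirna_ids[seq_len(spec$planted_mirnas)]
  } else character()

  rows <- list()
  add_row <- function(mirna, target, evidence = "low_throughput",
                      source = "synthA") {
    rows[[length(rows) + 1L]] <<- data.frame(
      mirna = mirna, target = target, species = spec$species,
      evidence = evidence, source = source, stringsAsFactors = FALSE)
  }
  for (m in planted_mirs) {
    k <- min(length(region), sample(2:4, 1))
    for (tgt in sample(region, k)) add_row(m, tgt)
  }
  for (m in setdiff(mirna_ids, planted_mirs)) {
    k <- sample(seq(spec$targets_per_mirna[1], spec$targets_per_mirna[2]), 1)
    for (tgt in sample(all_genes, k)) add_row(m, tgt)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # redundant rows from a second source and high-throughput-only noise,
  # so deduplication and evidence filtering have work to do
  ndup <- max(1L, floor(0.1 * nrow(tab)))
  dup <- tab[sample.int(nrow(tab), ndup), , drop = FALSE]
  dup$source <- "synthB"
  noise_mirs <- sample(mirna_ids, max(1L, floor(0.2 * spec$n_mirnas)))
  noise <- data.frame(mirna = noise_mirs,
                      target = sample(all_genes, length(noise_mirs)),
                      species = spec$species, evidence = "high_throughput",
                      source = "synthHT", stringsAsFactors = FALSE)
  interactions <- rbind(tab, dup, noise)
  interactions <- interactions[sample.int(nrow(interactions)), , drop = FALSE]
  rownames(interactions) <- NULL

  pick <- function(pool, fraction) {
    k <- floor(fraction * length(pool))
    if (k > 0) sample(pool, k) else character()
  }
  off_genes <- sprintf("X%05d", seq_len(spec$off_pathway_genes))
  off_mirs <- sprintf("mirx-%03d", seq_len(spec$off_pathway_mirnas))
  diff_genes <- c(pick(region, spec$planted_signature_fraction),
                  pick(setdiff(all_genes, region),
                       spec$background_signature_fraction),
                  pick(off_genes, spec$background_signature_fraction))
  diff_mirs <- c(planted_mirs,
                 pick(c(setdiff(mirna_ids, planted_mirs), off_mirs),
                      spec$background_signature_fraction))
  diff <- differential_set(
    diff_genes, diff_mirs,
    background_gene_count = length(all_genes) + length(off_genes),
    background_mirna_count = length(mirna_ids) + length(off_mirs))

  truth <- list(planted_pathway_id = planted_pid,
                planted_nodes = sort(c(region, planted_mirs)),
                planted_signatures = sort(intersect(
                  c(region, planted_mirs),
                  c(diff$genes, diff$mirnas))))
  structure(list(pathways = pathways, interactions = interactions,
                 diff = diff, truth = truth, spec = spec),
            class = "pathway_fixture")
}

#' Write a fixture to disk as plain-text files
#'
#' Emits `pathways.tsv` (exchange format), `interactions.tsv`,
#' `diff_genes.txt`, `diff_mirnas.txt`, `background.tsv` (universe
#' sizes) and `truth.tsv` (planted pathway and node manifest), all
#' re-readable with the package readers.
#'
#' @param fixture A `"pathway_fixture"` from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "pathway_fixture"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create fixture directory '", dir, "'", call. = FALSE)
  }
  paths <- c(pathways = file.path(dir, "pathways.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             diff_genes = file.path(dir, "diff_genes.txt"),
             diff_mirnas = file.path(dir, "diff_mirnas.txt"),
             background = file.path(dir, "background.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_pathway_tsv(fixture$pathways, paths[["pathways"]])
  write.table(fixture$interactions, paths[["interactions"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sort(fixture$diff$genes), paths[["diff_genes"]])
  writeLines(sort(fixture$diff$mirnas), paths[["diff_mirnas"]])
  write.table(data.frame(
    background_gene_count = fixture$diff$background_gene_count,
    background_mirna_count = fixture$diff$background_mirna_count),
    paths[["background"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(
    planted_pathway_id = fixture$truth$planted_pathway_id,
    node = fixture$truth$planted_nodes,
    signature = fixture$truth$planted_nodes %in%
      fixture$truth$planted_signatures),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a fixture directory back
#'
#' @param dir Directory written by [write_fixture()].
#' @return A list with `pathways`, `interactions`, `diff` and `truth`.
#' @export
read_fixture <- function(dir) {
  bg <- read.delim(file.path(dir, "background.tsv"), sep = "\t")
  truth <- read.delim(file.path(dir, "truth.tsv"), sep = "\t",
                      stringsAsFactors = FALSE)
  list(pathways = read_pathway_tsv(file.path(dir, "pathways.tsv")),
       interactions = read_interactions(file.path(dir, "interactions.tsv")),
       diff = differential_set(
         read_id_list(file.path(dir, "diff_genes.txt")),
         read_id_list(file.path(dir, "diff_mirnas.txt")),
         bg$background_gene_count[1], bg$background_mirna_count[1]),
       truth = list(planted_pathway_id = truth$planted_pathway_id[1],
                    planted_nodes = sort(truth$node),
                    planted_signatures = sort(truth$node[truth$signature])))
}
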