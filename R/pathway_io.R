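#' Supported organism codes
#'
#' Three-letter KEGG-style organism codes accepted by the readers.
#' @export
SPECIES_CODES <- c("cel", "dme", "dre", "hsa", "mmu", "rno")

check_species <- function(species) {
  if (!is.character(species) || length(species) != 1L ||
      !(species %in% SPECIES_CODES)) {
    stop("'species' must be one of: ", paste(SPECIES_CODES, collapse = ", "),
         call. = FALSE)
  }
  species
}

#' Construct a pathway graph
#'
#' A pathway graph is an undirected [igraph::igraph] whose vertices are
#' molecule ids with a `kind` attribute (`"gene"` or `"miRNA"`) and whose
#' edges carry a `kind` attribute (`"gene-gene"` or `"mirna-target"`) and a
#' `compounds` attribute (semicolon-joined compound ids, possibly empty).
#' Plain converted pathways contain only gene nodes; once miRNAs are
#' embedded by [embed_mirnas()] the object gains the `"rmpg"` class.
#'
#' @param pathway_id Pathway identifier, e.g. `"path:00590"`.
#' @param name Human-readable pathway name.
#' @param species Organism code (one of [SPECIES_CODES]).
#' @param nodes Character vector of gene ids (may be empty).
#' @param edges Data frame with columns `from`, `to`, `compounds`
#'   (semicolon-joined labels, `""` for none); may have zero rows.
#' @return An object of class `"pathway_graph"`: a list with elements
#'   `pathway_id`, `name`, `species` and `graph`.
#' @export
pathway_graph <- function(pathway_id, name, species, nodes = character(),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             compounds = character())) {
  check_species(species)
  nodes <- unique(as.character(nodes))
  stopifnot(is.data.frame(edges),
            all(c("from", "to") %in% names(edges)))
  if (is.null(edges$compounds)) edges$compounds <- rep("", nrow(edges))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$compounds <- as.character(edges$compounds)
  edges <- edges[edges$from != edges$to, , drop = FALSE]   # no self-loops
  if (nrow(edges)) {
    bad <- setdiff(c(edges$from, edges$to), nodes)
    if (length(bad)) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    edges <- collapse_parallel_edges(edges)
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, kind = rep("gene", length(nodes)),
                          stringsAsFactors = FALSE))
  if (nrow(edges)) {
    igraph::E(g)$kind <- "gene-gene"
  }
  structure(list(pathway_id = pathway_id, name = name,
                 species = species, graph = g),
            class = "pathway_graph")
}

# Merge duplicate undirected edges, unioning their compound label sets.
collapse_parallel_edges <- function(edges) {
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  cmp <- split(edges$compounds, key)
  cmp <- vapply(cmp, function(x) {
    labs <- unique(unlist(strsplit(x[nzchar(x)], ";", fixed = TRUE)))
    paste(sort(labs), collapse = ";")
  }, character(1))
  ab <- do.call(rbind, strsplit(names(cmp), "\r", fixed = TRUE))
  data.frame(from = ab[, 1], to = ab[, 2], compounds = unname(cmp),
             stringsAsFactors = FALSE)
}

#' @export
print.pathway_graph <- function(x, ...) {
  g <- x$graph
  kinds <- if (igraph::vcount(g)) igraph::V(g)$kind else character()
  cat(sprintf("<%s> %s (%s) [%s]\n",
              class(x)[1], x$pathway_id, x$name, x$species))
  cat(sprintf("  nodes: %d (%d genes, %d miRNAs); edges: %d\n",
              igraph::vcount(g), sum(kinds == "gene"),
              sum(kinds == "miRNA"), igraph::ecount(g)))
  invisible(x)
}

#' Parse a KGML pathway document into a pathway graph
#'
#' Converts a KEGG KGML (XML) metabolic pathway description into an
#' undirected graph with genes as nodes and compounds as edge labels.
#' Two gene entries are joined when an `ECrel` relation links them (the
#' relation's compound subtype becomes the edge label) or when they
#' catalyze consecutive reactions, i.e. a product compound of one
#' reaction is a substrate of the other (the shared compounds become the
#' edge labels).  Compound entries never become nodes.  KGML entries
#' listing several gene ids are split into one node per id, each
#' inheriting the entry's relations and reactions.
#'
#' @param x Path to a KGML file, or a single string of KGML text.
#' @param species Organism code (one of [SPECIES_CODES]).
#' @return A [pathway_graph()].
#' @export
parse_kgml <- function(x, species) {
  check_species(species)
  doc <- tryCatch(xml2::read_xml(x), error = function(e) {
    stop("malformed KGML document: ", conditionMessage(e), call. = FALSE)
  })
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("malformed KGML document: no <pathway> element",
                        call. = FALSE)
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid)) pid <- "path:unknown"
  pname <- xml2::xml_attr(root, "title")
  if (is.na(pname)) pname <- pid

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  etype <- xml2::xml_attr(entries, "type")
  eid <- xml2::xml_attr(entries, "id")
  ename <- xml2::xml_attr(entries, "name")
  ereact <- xml2::xml_attr(entries, "reaction")

  is_gene <- !is.na(etype) & etype == "gene"
  is_cpd <- !is.na(etype) & etype == "compound"
  # entry id -> vector of gene ids (multi-gene entries split)
  genes_of <- lapply(seq_along(entries), function(i) {
    if (!is_gene[i]) return(character())
    strsplit(trimws(ename[i]), "\\s+")[[1]]
  })
  names(genes_of) <- eid
  cpd_of <- lapply(seq_along(entries), function(i) {
    if (!is_cpd[i]) return(character())
    strsplit(trimws(ename[i]), "\\s+")[[1]]
  })
  names(cpd_of) <- eid

  nodes <- unique(unlist(genes_of))
  if (!length(nodes)) {
    warning("KGML pathway '", pid, "' contains no gene entries; ",
            "returning an empty graph", call. = FALSE)
    return(pathway_graph(pid, pname, species))
  }

  edge_rows <- list()
  add_edges <- function(ga, gb, compounds) {
    if (!length(ga) || !length(gb)) return()
    pairs <- expand.grid(from = ga, to = gb, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    if (!nrow(pairs)) return()
    pairs$compounds <- paste(sort(unique(compounds)), collapse = ";")
    edge_rows[[length(edge_rows) + 1L]] <<- pairs
  }

  # ECrel relations: enzyme-enzyme links via a shared compound entry
  rels <- xml2::xml_find_all(doc, "/pathway/relation[@type='ECrel']")
  for (rel in rels) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    if (is.na(e1) || is.na(e2)) {
      stop("malformed KGML document: <relation> missing entry1/entry2",
           call. = FALSE)
    }
    subt <- xml2::xml_find_all(rel, "subtype[@name='compound']")
    cpds <- unlist(lapply(xml2::xml_attr(subt, "value"),
                          function(v) cpd_of[[v]]))
    add_edges(genes_of[[e1]], genes_of[[e2]],
              if (is.null(cpds)) character() else cpds)
  }

  # Consecutive reactions: product of one is substrate of the other
  reacts <- xml2::xml_find_all(doc, "/pathway/reaction")
  if (length(reacts)) {
    rname <- xml2::xml_attr(reacts, "name")
    subs <- lapply(reacts, function(r)
      xml2::xml_attr(xml2::xml_find_all(r, "substrate"), "name"))
    prods <- lapply(reacts, function(r)
      xml2::xml_attr(xml2::xml_find_all(r, "product"), "name"))
    # genes catalyzing each reaction (entry@reaction may list several)
    rgenes <- setNames(vector("list", length(reacts)), rname)
    for (i in seq_along(entries)) {
      if (!is_gene[i] || is.na(ereact[i])) next
      for (rn in strsplit(trimws(ereact[i]), "\\s+")[[1]]) {
        rgenes[[rn]] <- c(rgenes[[rn]], genes_of[[eid[i]]])
      }
    }
    for (i in seq_along(reacts)) {
      for (j in seq_along(reacts)) {
        if (i == j) next
        shared <- intersect(prods[[i]], subs[[j]])
        if (length(shared)) {
          add_edges(rgenes[[rname[i]]], rgenes[[rname[j]]], shared)
        }
      }
    }
  }

  edges <- if (length(edge_rows)) {
    do.call(rbind, edge_rows)
  } else {
    data.frame(from = character(), to = character(), compounds = character())
  }
  pathway_graph(pid, pname, species, nodes = nodes, edges = edges)
}

pathway_tsv_columns <- c("pathway_id", "pathway_name", "species",
                         "record", "node_a", "kind_a", "node_b", "kind_b",
                         "edge_kind", "compounds")

#' Write a pathway collection to the exchange TSV format
#'
#' The exchange format is a flat tab-separated file carrying a whole
#' pathway collection: one `node` row per vertex (so isolated vertices
#' survive a round trip) and one `edge` row per undirected edge, with
#' node kinds, edge kind and semicolon-joined compound labels.  It is
#' lossless for both plain pathway graphs and miRNA-embedded graphs.
#'
#' @param pathways A single [pathway_graph()] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_tsv <- function(pathways, path) {
  pathways <- as_pathway_collection(pathways)
  rows <- lapply(pathways, function(p) {
    g <- p$graph
    nr <- data.frame(pathway_id = p$pathway_id, pathway_name = p$name,
                     species = p$species, record = "node",
                     node_a = if (igraph::vcount(g)) igraph::V(g)$name else character(),
                     kind_a = if (igraph::vcount(g)) igraph::V(g)$kind else character(),
                     node_b = "", kind_b = "", edge_kind = "", compounds = "",
                     stringsAsFactors = FALSE)
    if (igraph::ecount(g)) {
      el <- igraph::as_edgelist(g)
      kmap <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
      er <- data.frame(pathway_id = p$pathway_id, pathway_name = p$name,
                       species = p$species, record = "edge",
                       node_a = el[, 1], kind_a = unname(kmap[el[, 1]]),
                       node_b = el[, 2], kind_b = unname(kmap[el[, 2]]),
                       edge_kind = igraph::E(g)$kind,
                       compounds = edge_compounds(g),
                       stringsAsFactors = FALSE)
      rbind(nr, er)
    } else nr
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

edge_compounds <- function(g) {
  cmp <- igraph::edge_attr(g, "compounds")
  if (is.null(cmp)) rep("", igraph::ecount(g)) else ifelse(is.na(cmp), "", cmp)
}

#' Read a pathway collection from the exchange TSV format
#'
#' @param path Path to a file written by [write_pathway_tsv()].
#' @return A named list of [pathway_graph()] objects keyed by pathway id;
#'   graphs containing miRNA nodes carry the `"rmpg"` class.
#' @export
read_pathway_tsv <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "", colClasses = "character",
                    na.strings = NULL)
  missing <- setdiff(pathway_tsv_columns, names(tab))
  if (length(missing)) {
    stop("pathway TSV '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (pid in unique(tab$pathway_id)) {
    sub <- tab[tab$pathway_id == pid, , drop = FALSE]
    nr <- sub[sub$record == "node", , drop = FALSE]
    er <- sub[sub$record == "edge", , drop = FALSE]
    p <- pathway_graph(pid, nr$pathway_name[1], nr$species[1],
                       nodes = nr$node_a[nr$kind_a == "gene"],
                       edges = data.frame(
                         from = er$node_a[er$edge_kind == "gene-gene"],
                         to = er$node_b[er$edge_kind == "gene-gene"],
                         compounds = er$compounds[er$edge_kind == "gene-gene"],
                         stringsAsFactors = FALSE))
    mir_nodes <- nr$node_a[nr$kind_a == "miRNA"]
    if (length(mir_nodes)) {
      me <- er[er$edge_kind == "mirna-target", , drop = FALSE]
      mirna <- ifelse(me$kind_a == "miRNA", me$node_a, me$node_b)
      target <- ifelse(me$kind_a == "miRNA", me$node_b, me$node_a)
      p <- embed_mirnas(p, data.frame(
        mirna = mirna, target = target, species = p$species,
        evidence = "low_throughput", source = "tsv",
        stringsAsFactors = FALSE))
    }
    out[[pid]] <- p
  }
  out
}

as_pathway_collection <- function(x) {
  if (inherits(x, "pathway_graph")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "pathway_graph")))
  setNames(x, vapply(x, `[[`, character(1), "pathway_id"))
}

#' Read a one-id-per-line molecule list
#'
#' Blank lines and lines starting with `#` are ignored; surrounding
#' whitespace is trimmed; duplicates are removed.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Construct a differential molecule set
#'
#' Holds the condition-specific (differentially expressed) gene and
#' mature-miRNA ids together with the background universe sizes used by
#' the enrichment tests: the number of genes in the entire genome and
#' the number of miRNAs in the entire miRNAome (or any caller-chosen
#' universe).
#'
#' @param genes Character vector of differential gene ids.
#' @param mirnas Character vector of differential mature miRNA ids.
#' @param background_gene_count Positive integer, size of the gene
#'   universe; must be at least `length(genes)`.
#' @param background_mirna_count Positive integer, size of the miRNA
#'   universe; must be at least `length(mirnas)`.
#' @return An object of class `"differential_set"`.
#' @export
differential_set <- function(genes, mirnas,
                             background_gene_count,
                             background_mirna_count) {
  genes <- unique(as.character(genes))
  mirnas <- unique(as.character(mirnas))
  stopifnot(length(background_gene_count) == 1L,
            length(background_mirna_count) == 1L,
            background_gene_count >= 1, background_mirna_count >= 1)
  if (length(genes) > background_gene_count) {
    stop("more differential genes (", length(genes),
         ") than background_gene_count (", background_gene_count, ")",
         call. = FALSE)
  }
  if (length(mirnas) > background_mirna_count) {
    stop("more differential miRNAs (", length(mirnas),
         ") than background_mirna_count (", background_mirna_count, ")",
         call. = FALSE)
  }
  structure(list(genes = genes, mirnas = mirnas,
                 background_gene_count = as.integer(background_gene_count),
                 background_mirna_count = as.integer(background_mirna_count)),
            class = "differential_set")
}

#' @export
print.differential_set <- function(x, ...) {
  cat(sprintf("<differential_set> %d genes / %d background, %d miRNAs / %d background\n",
              length(x$genes), x$background_gene_count,
              length(x$mirnas), x$background_mirna_count))
  invisible(x)
}
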