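# Build small KGML documents in code so no XML fixtures are stored.

kgml_doc <- function(entries = "", relations = "", reactions = "",
                     pid = "path:hsa00001", title = "test pathway") {
  paste0('<?xml version="1.0"?>\n',
         '<pathway name="', pid, '" org="hsa" number="00001" title="',
         title, '">\n', entries, relations, reactions, '</pathway>\n')
}

kgml_gene <- function(id, genes, reaction = NULL) {
  paste0('<entry id="', id, '" name="', paste(genes, collapse = " "),
         '" type="gene"',
         if (!is.null(reaction)) paste0(' reaction="',
                                        paste(reaction, collapse = " "), '"'),
         '/>\n')
}

kgml_compound <- function(id, name) {
  paste0('<entry id="', id, '" name="', name, '" type="compound"/>\n')
}

kgml_ecrel <- function(e1, e2, compound_entry = NULL) {
  paste0('<relation entry1="', e1, '" entry2="', e2, '" type="ECrel">\n',
         if (!is.null(compound_entry))
           paste0('  <subtype name="compound" value="', compound_entry,
                  '"/>\n'),
         '</relation>\n')
}

kgml_reaction <- function(name, substrates, products) {
  paste0('<reaction id="', sub("rn:R", "", name), '" name="', name,
         '" type="irreversible">\n',
         paste0('  <substrate id="0" name="', substrates, '"/>\n',
                collapse = ""),
         paste0('  <product id="0" name="', products, '"/>\n',
                collapse = ""),
         '</reaction>\n')
}

# small ready-made pathway_graph: a path A-B-C-D plus isolated E
chain_graph <- function(ids = c("A", "B", "C", "D"), extra = "E",
                        pathway_id = "path:chain") {
  edges <- data.frame(from = ids[-length(ids)], to = ids[-1],
                      compounds = "", stringsAsFactors = FALSE)
  pathway_graph(pathway_id, "chain", "hsa", nodes = c(ids, extra),
                edges = edges)
}

tiny_interactions <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(mirna = r[[1]], target = r[[2]],
               species = if (length(r) > 2) r[[3]] else "hsa",
               evidence = if (length(r) > 3) r[[4]] else "low_throughput",
               source = if (length(r) > 4) r[[5]] else "db1",
               stringsAsFactors = FALSE)
  }))
}
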