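test_that("parse_kgml builds gene graphs from ECrel relations", {
  doc <- kgml_doc(
    entries = paste0(kgml_gene(1, "hsa:A"), kgml_gene(2, "hsa:B"),
                     kgml_compound(3, "cpd:C00010")),
    relations = kgml_ecrel(1, 2, compound_entry = 3))
  pg <- parse_kgml(doc, "hsa")
  expect_s3_class(pg, "pathway_graph")
  expect_setequal(igraph::V(pg$graph)$name, c("hsa:A", "hsa:B"))
  expect_equal(igraph::ecount(pg$graph), 1)
  expect_equal(igraph::E(pg$graph)$compounds, "cpd:C00010")
  # compound entries never become nodes
  expect_false("cpd:C00010" %in% igraph::V(pg$graph)$name)
})

test_that("parse_kgml links genes catalyzing consecutive reactions", {
  # A: X -> Y, B: Y -> Z, C: W -> V; expected: single edge A-B labeled Y
  doc <- kgml_doc(
    entries = paste0(kgml_gene(1, "hsa:A", "rn:R1"),
                     kgml_gene(2, "hsa:B", "rn:R2"),
                     kgml_gene(3, "hsa:C", "rn:R3")),
    reactions = paste0(kgml_reaction("rn:R1", "cpd:X", "cpd:Y"),
                       kgml_reaction("rn:R2", "cpd:Y", "cpd:Z"),
                       kgml_reaction("rn:R3", "cpd:W", "cpd:V")))
  pg <- parse_kgml(doc, "hsa")
  expect_setequal(igraph::V(pg$graph)$name, c("hsa:A", "hsa:B", "hsa:C"))
  el <- igraph::as_edgelist(pg$graph)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("hsa:A", "hsa:B"))
  expect_equal(igraph::E(pg$graph)$compounds, "cpd:Y")
  expect_equal(igraph::degree(pg$graph, "hsa:C"), c("hsa:C" = 0))
})

test_that("parse_kgml handles edgeless, multi-gene and empty documents", {
  # no relations/reactions -> nodes only
  pg <- parse_kgml(kgml_doc(entries = paste0(kgml_gene(1, "hsa:A"),
                                             kgml_gene(2, "hsa:B"))), "hsa")
  expect_setequal(igraph::V(pg$graph)$name, c("hsa:A", "hsa:B"))
  expect_equal(igraph::ecount(pg$graph), 0)

  # multi-gene entries split into one node per id, all inheriting the
  # relation
  doc <- kgml_doc(entries = paste0(kgml_gene(1, c("hsa:A1", "hsa:A2")),
                                   kgml_gene(2, "hsa:B")),
                  relations = kgml_ecrel(1, 2))
  pg2 <- parse_kgml(doc, "hsa")
  expect_setequal(igraph::V(pg2$graph)$name, c("hsa:A1", "hsa:A2", "hsa:B"))
  expect_equal(igraph::ecount(pg2$graph), 2)

  # zero gene entries -> warning and empty graph
  expect_warning(pg3 <- parse_kgml(kgml_doc(entries = kgml_compound(
    1, "cpd:C1")), "hsa"), "no gene entries")
  expect_equal(igraph::vcount(pg3$graph), 0)

  # malformed XML -> parse error
  expect_error(parse_kgml("<pathway", "hsa"), "malformed")
  expect_error(parse_kgml("<notkgml/>", "hsa"), "no <pathway>")
})

test_that("parse_kgml is deterministic and unions ECrel + reaction edges", {
  doc <- kgml_doc(
    entries = paste0(kgml_gene(1, "hsa:A", "rn:R1"),
                     kgml_gene(2, "hsa:B", "rn:R2"),
                     kgml_compound(9, "cpd:CC")),
    relations = kgml_ecrel(1, 2, compound_entry = 9),
    reactions = paste0(kgml_reaction("rn:R1", "cpd:X", "cpd:Y"),
                       kgml_reaction("rn:R2", "cpd:Y", "cpd:Z")))
  pg1 <- parse_kgml(doc, "hsa")
  pg2 <- parse_kgml(doc, "hsa")
  expect_identical(igraph::as_edgelist(pg1$graph),
                   igraph::as_edgelist(pg2$graph))
  # one merged edge carrying labels from both sources
  expect_equal(igraph::ecount(pg1$graph), 1)
  expect_setequal(strsplit(igraph::E(pg1$graph)$compounds, ";")[[1]],
                  c("cpd:CC", "cpd:Y"))
})

test_that("pathway_graph rejects self-loops and undeclared endpoints", {
  pg <- pathway_graph("path:x", "x", "hsa", nodes = c("A", "B"),
                      edges = data.frame(from = c("A", "A"),
                                         to = c("B", "A"),
                                         compounds = c("", "")))
  expect_equal(igraph::ecount(pg$graph), 1)   # self-loop dropped
  expect_error(pathway_graph("path:x", "x", "hsa", nodes = "A",
                             edges = data.frame(from = "A", to = "Z")),
               "not declared")
  expect_error(pathway_graph("path:x", "x", "xx"), "species")
})

test_that("exchange TSV round-trips pathway collections losslessly", {
  g1 <- chain_graph(pathway_id = "path:c1")
  g2 <- embed_mirnas(chain_graph(ids = c("P", "Q", "R", "S"), extra = "T",
                                 pathway_id = "path:c2"),
                     tiny_interactions(list("mir-9", "P"),
                                       list("mir-9", "R")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_tsv(list(g1, g2), path)
  back <- read_pathway_tsv(path)
  expect_named(back, c("path:c1", "path:c2"))
  for (pair in list(list(g1, back[["path:c1"]]),
                    list(g2, back[["path:c2"]]))) {
    a <- pair[[1]]$graph; b <- pair[[2]]$graph
    expect_setequal(igraph::V(b)$name, igraph::V(a)$name)
    expect_identical(
      setNames(igraph::V(b)$kind, igraph::V(b)$name)[igraph::V(a)$name],
      setNames(igraph::V(a)$kind, igraph::V(a)$name))
    ea <- apply(igraph::as_edgelist(a), 1,
                function(x) paste(sort(x), collapse = "|"))
    eb <- apply(igraph::as_edgelist(b), 1,
                function(x) paste(sort(x), collapse = "|"))
    expect_setequal(eb, ea)
  }
  expect_s3_class(back[["path:c2"]], "rmpg")
  # second round trip is byte-identical (determinism of the writer)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_tsv(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("interaction reader enforces columns and logs dropped rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\ttarget\tspecies\tevidence\tsource",
               "mir-1\tPPAP2C\thsa\tlow_throughput\tdb1",
               "mir-1\t\thsa\tlow_throughput\tdb1",
               "mir-2\tALDH2\thsa\thigh_throughput\tdb2"), path)
  expect_message(tab <- read_interactions(path), "dropped 1 row")
  expect_equal(nrow(tab), 2)

  # duplicated rows pass through the reader untouched
  writeLines(c("mirna\ttarget\tspecies\tevidence\tsource",
               rep("mir-1\tPPAP2C\thsa\tlow_throughput\tdb1", 2)), path)
  expect_equal(nrow(read_interactions(path)), 2)

  # custom column names; missing mandatory column errors with names
  writeLines(c("mir\tgene\torg\tev\tdb",
               "mir-1\tPPAP2C\thsa\tlow_throughput\tdb1"), path)
  tab <- read_interactions(path, columns = c(
    mirna = "mir", target = "gene", species = "org", evidence = "ev",
    source = "db"))
  expect_equal(tab$target, "PPAP2C")
  expect_error(read_interactions(path), "missing column")
})

test_that("deduplication merges evidence and sources per key", {
  recs <- tiny_interactions(
    list("mir-1", "PPAP2C", "hsa", "high_throughput", "dbA"),
    list("mir-1", "PPAP2C", "hsa", "low_throughput", "dbB"),
    list("mir-1", "PPAP2C", "mmu", "high_throughput", "dbA"),
    list("mir-7", "NT5E", "hsa", "low_throughput", "dbA"))
  out <- deduplicate_interactions(recs)
  expect_equal(nrow(out), 3)
  merged <- out[out$mirna == "mir-1" & out$species == "hsa", ]
  expect_equal(merged$evidence, "low_throughput")
  expect_equal(merged$source, "dbA;dbB")
  # idempotence
  expect_identical(deduplicate_interactions(out), out)
  # disjoint keys: length preserved
  expect_equal(nrow(deduplicate_interactions(recs[3:4, ])), 2)
})

test_that("planted duplicates collapse to the brute-force key count", {
  set.seed(42)
  base <- tiny_interactions(
    list("mir-1", "A"), list("mir-1", "B"), list("mir-2", "A"),
    list("mir-3", "C"), list("mir-4", "D"), list("mir-5", "E"))
  dup <- base[sample.int(6, 4, replace = FALSE), ]
  dup$source <- "db2"
  recs <- rbind(base, dup)[sample.int(10), ]
  out <- deduplicate_interactions(recs)
  expect_equal(nrow(out),
               length(unique(paste(recs$mirna, recs$target, recs$species))))
  expect_equal(nrow(out), 6)
})

test_that("low-throughput filtering selects by evidence and species", {
  recs <- tiny_interactions(
    list("m1", "A", "hsa", "low_throughput"),
    list("m2", "B", "hsa", "high_throughput"),
    list("m3", "C", "mmu", "low_throughput"),
    list("m4", "D", "hsa", "low_throughput"),
    list("m5", "E", "rno", "high_throughput"))
  out <- filter_low_throughput(recs, "hsa")
  expect_setequal(out$mirna, c("m1", "m4"))
  expect_equal(nrow(filter_low_throughput(
    recs[recs$evidence == "high_throughput", ], "hsa")), 0)
  # filtered keys are a subset of the deduplicated keys
  dd <- deduplicate_interactions(recs)
  ft <- filter_low_throughput(dd, "hsa")
  expect_true(all(paste(ft$mirna, ft$target) %in%
                    paste(dd$mirna, dd$target)))
})

test_that("precursor mapping unions matures and reports unmapped", {
  pmap <- list("pre-X" = c("X-3p", "X-5p"), "pre-Y" = "Y-5p",
               "pre-Z" = c("Z-3p", "Z-5p"), "pre-W" = c("W-5p", "X-3p"))
  expect_equal(map_precursors("pre-X", pmap),
               list(mature = c("X-3p", "X-5p"), unmapped = character()))
  expect_equal(map_precursors(character(), pmap),
               list(mature = character(), unmapped = character()))
  # 4 mapped precursors; matures overlap so the union has 6 distinct
  # ids, and the missing precursor is reported rather than dropped
  res <- map_precursors(c("pre-X", "pre-Y", "pre-Z", "pre-W", "pre-NOPE"),
                        pmap)
  expect_equal(res$unmapped, "pre-NOPE")
  expect_equal(res$mature,
               sort(unique(c("X-3p", "X-5p", "Y-5p", "Z-3p", "Z-5p",
                             "W-5p"))))
  expect_length(res$mature, 6)
})

test_that("precursor map reader builds the mapping from TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("precursor\tmature", "pre-X\tX-3p", "pre-X\tX-5p",
               "pre-Y\tY-5p"), path)
  pmap <- read_precursor_map(path)
  expect_equal(pmap, list("pre-X" = c("X-3p", "X-5p"), "pre-Y" = "Y-5p"))
})

test_that("differential sets validate their universe sizes", {
  d <- differential_set(c("A", "B"), "m1", 10, 5)
  expect_equal(d$background_gene_count, 10L)
  expect_error(differential_set(letters, "m1", 10, 5), "background_gene")
  expect_error(differential_set("A", c("m1", "m2"), 10, 1),
               "background_mirna")
})

test_that("id list reader skips blanks and comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "A", "", "  B ", "A"), path)
  expect_equal(read_id_list(path), c("A", "B"))
})
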