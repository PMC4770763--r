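test_that("enrichment counts validate their inequalities by name", {
  expect_s3_class(enrichment_counts(10, 5, 4, 2, 3, 2, 2, 1),
                  "enrichment_counts")
  expect_error(enrichment_counts(10, 5, 11, 2, 3, 2, 2, 1), "n_g.*m_g")
  expect_error(enrichment_counts(10, 5, 4, 2, 3, 2, 4, 1), "r_g.*t_g")
  expect_error(enrichment_counts(10, 5, 4, 2, 3, 6, 2, 1), "t_mir.*m_mir")
  expect_error(enrichment_counts(10, 5, 4, 2, 3, 2, 2, 3), "r_mir")
  expect_error(enrichment_counts(-1, 5, 4, 2, 3, 2, 2, 1), "non-negative")
})

test_that("degenerate tails are analytically exact", {
  # empty sum: no differential member -> P = 1
  expect_equal(subpathway_pvalue(enrichment_counts(10, 5, 4, 2, 3, 2, 0, 0)),
               1)
  # subpathway is the whole universe -> every draw hits -> P = 1
  expect_equal(subpathway_pvalue(
    enrichment_counts(10, 5, 4, 2, 10, 5, 4, 2)), 1)
  expect_equal(ora_pvalue(100, 10, 5, 0), 1)
  expect_equal(mirna_pvalue(50, 5, 3, 0), 1)
  # degenerate miRNA universe: everything differential
  expect_equal(mirna_pvalue(5, 5, 5, 5), 1)
})

test_that("worked joint example matches exhaustive enumeration of draws", {
  # m_g=10, m_mir=5, n_g=4, n_mir=2, t_g=3, t_mir=2, r_g=2, r_mir=1:
  # enumerate all C(15,6) draws, count those with >= 3 of the 5
  # subpathway molecules
  cnt <- enrichment_counts(10, 5, 4, 2, 3, 2, 2, 1)
  expect_equal(subpathway_pvalue(cnt), enum_hyper_tail(15, 5, 6, 3),
               tolerance = 1e-12)
})

test_that("pooled, gene-only and miRNA-only tails agree with the enumeration oracle", {
  set.seed(123)
  for (i in 1:80) {
    m <- sample(4:16, 1)
    t <- sample.int(m, 1)
    n <- sample.int(m, 1)
    r <- sample.int(min(t, n), 1)
    want <- enum_hyper_tail(m, t, n, r)
    m_g <- sample(0:m, 1)
    # the same pooled urn split arbitrarily between genes and miRNAs
    t_g <- max(0, min(t, m_g) - sample(0:1, 1))
    n_g <- max(0, min(n, m_g) - sample(0:1, 1))
    r_g <- min(r, n_g, t_g)
    ok <- tryCatch({
      cnt <- enrichment_counts(m_g, m - m_g, n_g, n - n_g,
                               t_g, t - t_g, r_g, r - r_g)
      expect_equal(subpathway_pvalue(cnt), want, tolerance = 1e-12)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      # split violated a marginal inequality; the pooled urn is still
      # checked through the gene-only route below
    }
    expect_equal(ora_pvalue(m, n, t, r), want, tolerance = 1e-12)
    expect_equal(mirna_pvalue(m, n, t, r), want, tolerance = 1e-12)
  }
})

test_that("gene-only test is the joint test with zero miRNA counts", {
  set.seed(7)
  for (i in 1:25) {
    m <- sample(5:60, 1); t <- sample.int(m, 1); n <- sample.int(m, 1)
    r <- sample.int(min(t, n), 1)
    expect_identical(ora_pvalue(m, n, t, r),
                     subpathway_pvalue(enrichment_counts(m, 0, n, 0,
                                                         t, 0, r, 0)))
  }
})

test_that("p-value is monotone non-increasing in the differential member count", {
  cnt <- function(r) enrichment_counts(40, 10, 12, 4, 8, 3, r, 0)
  p <- vapply(0:8, function(r) subpathway_pvalue(cnt(r)), numeric(1))
  expect_true(all(diff(p) <= 1e-15))
  expect_equal(p[1], 1)
})

test_that("BH adjustment matches the textbook step-up computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  # hand computation: sorted p (0.01,0.02,0.04), k-th value p*(m/k),
  # then cumulative minimum from the largest rank
  expect_equal(bh_fdr(c(0.04, 0.01, 0.02)),
               c(0.04, 0.03, 0.03))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  m <- length(p)
  manual <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(bh_fdr(p), manual)
  expect_gte(min(bh_fdr(p)), min(p))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, -0.2)), "\\[0, 1\\]")
})

test_that("pathway-list overlap significance reproduces known values", {
  # two liver-cancer runs sharing 15 of 29/18 significant pathways out
  # of a 152-pathway collection
  expect_equal(overlap_pvalue(152, 29, 18, 15), 2.33e-10,
               tolerance = 0.005)
  expect_equal(overlap_pvalue(152, 20, 14, 7), 4.60e-04,
               tolerance = 0.005)
  expect_equal(overlap_pvalue(100, 10, 8, 0), 1)
  # symmetric in the two list sizes
  set.seed(9)
  for (i in 1:20) {
    u <- sample(20:200, 1)
    a <- sample.int(u, 1); b <- sample.int(u, 1)
    k <- sample.int(min(a, b), 1)
    expect_equal(overlap_pvalue(u, a, b, k), overlap_pvalue(u, b, a, k),
                 tolerance = 1e-12)
    # and equal to the gene-only enrichment with the same urn
    expect_equal(overlap_pvalue(u, a, b, k), ora_pvalue(u, a, b, k),
                 tolerance = 1e-12)
  }
  expect_error(overlap_pvalue(10, 12, 5, 3), "exceed the universe")
  expect_error(overlap_pvalue(10, 5, 4, 5), "smaller list")
})

test_that("scoring composes counts, p-values and one FDR family", {
  fix <- generate_fixture(fixture_spec(seed = 2))
  rmpgs <- build_rmpgs(fix$pathways, fix$interactions, "hsa")
  subs <- locate_all(rmpgs, fix$diff)
  res <- score_subpathways(subs, fix$diff)
  expect_equal(nrow(res), length(subs))
  # each row's p equals the formula applied to its own counts
  for (k in seq_len(nrow(res))) {
    expect_equal(res$p_value[k], subpathway_pvalue(enrichment_counts(
      res$m_g[k], res$m_mir[k], res$n_g[k], res$n_mir[k],
      res$t_g[k], res$t_mir[k], res$r_g[k], res$r_mir[k])))
  }
  expect_equal(sort(res$fdr), res$fdr)
  expect_equal(res$fdr,
               bh_fdr(res$p_value)[order(order(res$fdr, res$p_value))],
               tolerance = 1e-12)
  expect_identical(score_subpathways(list(), fix$diff)$p_value, numeric())

  # genome vs annotated universes
  expect_equal(res$m_g[1], fix$diff$background_gene_count)
  res2 <- score_subpathways(subs, fix$diff, background_mode = "annotated",
                            rmpgs = rmpgs)
  expect_equal(res2$m_g[1],
               length(unique(unlist(lapply(rmpgs, pathway_nodes, "gene")))))
  expect_error(score_subpathways(subs, fix$diff,
                                 background_mode = "annotated"),
               "requires")
})

test_that("the planted subpathway outranks background subpathways", {
  fix <- generate_fixture(fixture_spec(seed = 4))
  rmpgs <- build_rmpgs(fix$pathways, fix$interactions, "hsa")
  run <- run_identify(rmpgs, fix$diff)
  res <- run$all_results
  planted <- res[res$pathway_id == fix$truth$planted_pathway_id, ]
  others <- res[res$pathway_id != fix$truth$planted_pathway_id, ]
  expect_gte(nrow(planted), 1)
  if (nrow(others)) {
    expect_lt(min(planted$p_value), min(others$p_value))
  }
})

test_that("shuffling differential labels washes out the planted signal", {
  fix <- generate_fixture(fixture_spec(seed = 6))
  rmpgs <- build_rmpgs(fix$pathways, fix$interactions, "hsa")
  res <- run_identify(rmpgs, fix$diff)$all_results
  planted_p <- min(res$p_value[res$pathway_id ==
                                 fix$truth$planted_pathway_id])
  all_genes <- unique(unlist(lapply(rmpgs, pathway_nodes, "gene")))
  all_mirs <- unique(unlist(lapply(rmpgs, pathway_nodes, "miRNA")))
  # re-draw the in-pathway signatures uniformly while preserving both
  # the number of mapped signatures and the total differential counts
  n_in_g <- length(intersect(fix$diff$genes, all_genes))
  n_in_m <- length(intersect(fix$diff$mirnas, all_mirs))
  pad <- function(prefix, k) if (k > 0) sprintf("%s%04d", prefix,
                                                seq_len(k)) else character()
  set.seed(88)
  shuffled_p <- replicate(5, {
    d <- differential_set(
      c(sample(all_genes, n_in_g),
        pad("SHUFG", length(fix$diff$genes) - n_in_g)),
      c(sample(all_mirs, n_in_m),
        pad("SHUFM", length(fix$diff$mirnas) - n_in_m)),
      fix$diff$background_gene_count,
      fix$diff$background_mirna_count)
    r <- run_identify(rmpgs, d)$all_results
    if (nrow(r)) min(r$p_value) else 1
  })
  expect_gt(min(shuffled_p), planted_p)
})

test_that("results TSV records the universe and honors the threshold", {
  fix <- generate_fixture(fixture_spec(seed = 2))
  rmpgs <- build_rmpgs(fix$pathways, fix$interactions, "hsa")
  res <- run_identify(rmpgs, fix$diff)$all_results
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_tsv(res, path, fdr_threshold = 0.01)
  lines <- readLines(path)
  expect_match(lines[1], "^# background_mode=genome m_g=")
  expect_equal(length(lines) - 2, sum(res$fdr < 0.01))
})
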