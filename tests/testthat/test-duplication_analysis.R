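cfg <- analysis_config()

test_that("duplicate calling applies identity/coverage thresholds symmetrically", {
  hits <- make_hits(c("a", "a", "b"), c("b", "c", "a"),
                    identity = c(71, 69.9, 75),
                    qcov = c(75, 99, 80), scov = c(80, 99, 85))
  pairs <- call_duplicates(hits, cfg)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gene_a, "a")
  expect_equal(pairs$gene_b, "b")
  # reciprocal hits collapse; the better (lower evalue) one is evidence
  h2 <- make_hits(c("x", "y"), c("y", "x"), identity = c(80, 90),
                  evalue = c(1e-50, 1e-80))
  p2 <- call_duplicates(h2, cfg)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$evalue, 1e-80)
  # permuting rows / swapping query-subject changes nothing
  p3 <- call_duplicates(h2[2:1], cfg)
  expect_equal(as.data.frame(p3), as.data.frame(p2))
  # self hits and boundary: >= is the default reading of "over 70%"
  expect_equal(nrow(call_duplicates(make_hits("a", "a", 99), cfg)), 0L)
  exact <- make_hits("a", "b", 70, qcov = 70, scov = 70)
  expect_equal(nrow(call_duplicates(exact, cfg)), 1L)
  strict <- analysis_config(strict_gt = TRUE)
  expect_equal(nrow(call_duplicates(exact, strict)), 0L)
})

test_that("pair typing follows distance and subgenome rules", {
  genes <- make_genes(c("a1", "a2", "b1", "b2", "u1"),
                      c("A01", "A01", "B03", "B03", "UNPLACED"),
                      c(1e6, 5.2e6, 1e6, 7.2e6, 1))
  pairs <- data.table::data.table(
    gene_a = c("a1", "b1", "a1", "a1"),
    gene_b = c("a2", "b2", "b1", "u1"))
  tp <- type_pairs(pairs, genes, cfg)
  expect_equal(tp$positional_type,
               c("TANDEM", "SEGMENTAL", "DISPERSED", "DISPERSED"))
  expect_equal(tp$genome_scope,
               c("INTRA_A", "INTRA_B", "INTER", "UNKNOWN"))
  expect_equal(tp$distance_bp[1:2], c(4.2e6, 6.2e6))
  # boundary: exactly 5 Mb is tandem (inclusive)
  g5 <- make_genes(c("p", "q"), "A02", c(1, 5e6 + 1))
  t5 <- type_pairs(data.table::data.table(gene_a = "p", gene_b = "q"),
                   g5, cfg)
  expect_equal(t5$positional_type, "TANDEM")
})

test_that("summary equals the brute-force recount and the scope partition closes", {
  w <- tiny_world()
  b <- run_landscape_pipeline(w, cfg)
  for (fam in c("RLK", "RLP")) {
    tp <- b$duplicates[family == fam]
    ds <- b$dup_summary[[fam]]
    want <- oracle_dup_summary(as.data.frame(tp))
    expect_equal(ds$n_events, want$n_events)
    expect_equal(ds$n_duplicated_genes, want$n_duplicated_genes)
    expect_equal(ds$n_tandem_genes, want$n_tandem_genes)
    expect_equal(sum(ds$events_by_scope), ds$n_events)
    # tandem + segmental are exactly the same-chromosome pairs
    same_chr <- !is.na(tp$distance_bp)
    expect_equal(tp$positional_type %in% c("TANDEM", "SEGMENTAL"),
                 same_chr)
  }
  # tiny-instance recount: 3 genes, pairs (a,b), (b,c)
  small <- data.table::data.table(
    gene_a = c("a", "b"), gene_b = c("b", "c"),
    positional_type = "DISPERSED", genome_scope = "INTRA_A")
  o <- oracle_dup_summary(small)
  expect_equal(o$n_events, 2L)
  expect_equal(o$n_duplicated_genes, 3L)
})

test_that("planted duplicates are recovered exactly in the noiseless regime", {
  w <- tiny_world()
  b <- run_landscape_pipeline(w, cfg)
  truth <- w$truth$duplicates
  for (fam in c("RLK", "RLP")) {
    got <- b$duplicates[family == fam]
    want <- truth[family == fam]
    got_keys <- paste(got$gene_a, got$gene_b)
    want_keys <- paste(pmin(want$gene_a, want$gene_b),
                       pmax(want$gene_a, want$gene_b))
    expect_setequal(got_keys, want_keys)   # precision = recall = 1
    merged <- merge(got[, .(gene_a, gene_b, got = positional_type)],
                    want[, .(gene_a = pmin(gene_a, gene_b),
                             gene_b = pmax(gene_a, gene_b),
                             want = positional_type,
                             want_scope = genome_scope)],
                    by = c("gene_a", "gene_b"))
    expect_equal(merged$got, merged$want)
    scope <- merge(got[, .(gene_a, gene_b, got = genome_scope)],
                   want[, .(gene_a = pmin(gene_a, gene_b),
                            gene_b = pmax(gene_a, gene_b),
                            want = genome_scope)],
                   by = c("gene_a", "gene_b"))
    expect_equal(scope$got, scope$want)
  }
})

test_that("paralog calling applies only the E-value rule", {
  genes <- make_genes(c("a", "b", "c"), c("A08", "A06", "B04"),
                      c(1e6, 2e6, 3e6))
  hits <- make_hits(c("a", "a", "b"), c("b", "c", "c"),
                    identity = c(40, 45, 50),
                    evalue = c(1e-25, 1e-15, 1e-60))
  pl <- call_paralogs(hits, genes, cfg)
  expect_equal(nrow(pl), 2L)   # 1e-15 fails; identity is irrelevant
  expect_setequal(paste(pl$gene_a, pl$gene_b), c("a b", "b c"))
  # a mutually-passing trio forms a group of three genes
  hits3 <- make_hits(c("a", "a", "b"), c("b", "c", "c"),
                     identity = 80, evalue = 1e-50)
  pl3 <- call_paralogs(hits3, genes, cfg)
  expect_equal(length(unique(c(pl3$gene_a, pl3$gene_b))), 3L)
  expect_equal(nrow(pl3), 3L)
})

test_that("tandem-cluster labelling requires every consecutive pair to be tandem", {
  clusters <- data.table::data.table(
    cluster_id = c("c1", "c2"), chromosome = "A01", n_members = 3L,
    first_start = 1, last_end = 2, span_bp = 1,
    member_ids = c("a,b,c", "d,e,f"))
  tp <- data.table::data.table(
    gene_a = c("a", "b", "d"), gene_b = c("b", "c", "e"),
    positional_type = c("TANDEM", "TANDEM", "TANDEM"))
  lab <- label_tandem_clusters(clusters, tp)
  expect_equal(lab$tandem, c(TRUE, FALSE))  # e-f missing in c2
})
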