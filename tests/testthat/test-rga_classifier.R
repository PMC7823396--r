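cfg <- analysis_config()

test_that("prescreen keeps genes whose best hit passes the E-value ceiling", {
  hits <- make_hits(c("g1", "g2", "g3", "g3"), "REF",
                    identity = 50,
                    evalue = c(1e-6, 1e-4, 1e-3, 1e-30))
  got <- prescreen_candidates(hits, cfg)
  expect_setequal(got, c("g1", "g3"))     # best hit governs g3
  expect_warning(out <- prescreen_candidates(hits[0], cfg), "empty")
  expect_identical(out, character())
})

test_that("architectures aggregate passing records per class", {
  rec <- data.table::data.table(
    gene_id = "g1",
    domain_class = c(rep("LRR", 4L), "TM", "KINASE_STTK"),
    p_start = 1, p_end = 50, evalue = 1e-10, source_tool = "x",
    signature = "y")
  a <- build_architecture(rec, "g1", cfg)
  expect_true(a$has_lrr && a$has_tm && a$has_kinase)
  expect_false(a$has_lysm || a$has_sp)
  expect_equal(a$n_lrr_repeats, 4L)
  empty <- build_architecture(rec[0], "gX", cfg)
  expect_false(any(unlist(empty[c("has_lrr", "has_lysm", "has_tm",
                                  "has_kinase", "has_sp")])))
  # failing the per-domain E-value ceiling removes the record
  rec2 <- data.table::copy(rec)[domain_class == "KINASE_STTK",
                                evalue := 10]
  expect_false(build_architecture(rec2, "g1", cfg)$has_kinase)
})

test_that("the classification rule table is honoured, with LysM precedence", {
  arch <- function(lrr = FALSE, lysm = FALSE, tm = FALSE, kin = FALSE)
    list(has_lrr = lrr, has_lysm = lysm, has_tm = tm, has_kinase = kin,
         has_sp = FALSE, n_lrr_repeats = 0L)
  expect_equal(classify_gene(arch(lrr = TRUE, tm = TRUE, kin = TRUE),
                             TRUE, cfg), "LRR_RLK")
  expect_equal(classify_gene(arch(lrr = TRUE, tm = TRUE), TRUE, cfg),
               "LRR_RLP")
  expect_equal(classify_gene(arch(lysm = TRUE, tm = TRUE), TRUE, cfg),
               "LYSM_RLP")
  expect_equal(classify_gene(arch(tm = TRUE, kin = TRUE), TRUE, cfg),
               "RLK_OTHER")
  both <- arch(lrr = TRUE, lysm = TRUE, tm = TRUE, kin = TRUE)
  expect_equal(classify_gene(both, TRUE, cfg), "LYSM_RLK")
  cfg_lrr <- analysis_config(ectodomain_priority = "LRR")
  expect_equal(classify_gene(both, TRUE, cfg_lrr), "LRR_RLK")
  # prescreen gates everything, even a perfect architecture
  expect_equal(classify_gene(both, FALSE, cfg), "NON_RGA")
  # kinase + ectodomain without TM is nothing
  expect_equal(classify_gene(arch(lrr = TRUE, kin = TRUE), TRUE, cfg),
               "NON_RGA")
})

test_that("classify_proteome partitions the proteome and matches the per-gene oracle", {
  w <- tiny_world()
  tet <- w$species[[w$tetraploid]]
  cl <- classify_proteome(tet$genes, tet$domains, tet$prescreen_hits, cfg)
  expect_equal(nrow(cl), nrow(tet$genes))
  expect_false(anyNA(cl$class))
  expect_equal(sum(table(cl$class)), nrow(tet$genes))
  # noiseless recovery of planted classes
  truth <- w$truth$classes[species == w$tetraploid]
  merged <- merge(cl[, .(gene_id, got = as.character(class))],
                  truth[, .(gene_id, want = as.character(class))],
                  by = "gene_id")
  expect_equal(merged$got, merged$want)
  # oracle equivalence on a <= 50-gene instance
  pre <- prescreen_candidates(tet$prescreen_hits, cfg)
  sub <- tet$genes[seq_len(50L)]
  dom <- tet$domains[gene_id %in% sub$gene_id]
  got <- classify_proteome(sub, dom, pre, cfg)
  want <- oracle_classify(as.data.frame(got[, .(gene_id)]),
                          as.data.frame(dom), pre, cfg)
  expect_equal(as.character(got$class), want)
})

test_that("domain records for unknown genes warn and are skipped; no-TM proteomes are all NON_RGA", {
  genes <- make_genes(c("g1", "g2"), "A01", c(1e6, 2e6))
  dom <- data.table::data.table(
    gene_id = c("g1", "ghost"), domain_class = "KINASE_STTK",
    p_start = 1, p_end = 99, evalue = 1e-10, source_tool = "x",
    signature = "Pkinase")
  expect_warning(cl <- classify_proteome(genes, dom, c("g1", "g2"), cfg),
                 "unknown gene")
  expect_true(all(cl$class == "NON_RGA"))
})

test_that("tightening the prescreen ceiling only shrinks RGA classes", {
  w <- tiny_world()
  tet <- w$species[[w$tetraploid]]
  counts <- function(e_max) {
    c2 <- analysis_config(prescreen_evalue_max = e_max)
    cl <- classify_proteome(tet$genes, tet$domains, tet$prescreen_hits, c2)
    table(cl$class)
  }
  loose <- counts(1e-5)
  for (e in c(1e-20, 1e-60, 1e-120)) {
    tight <- counts(e)
    for (k in setdiff(RGA_CLASSES, "NON_RGA"))
      expect_lte(tight[[k]], loose[[k]])
    expect_gte(tight[["NON_RGA"]], loose[["NON_RGA"]])
    loose <- tight
  }
})
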