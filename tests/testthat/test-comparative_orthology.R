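cfg <- analysis_config()

test_that("ortholog calling applies the strict E-value bound plus identity/coverage", {
  ga <- make_genes(c("t1", "t2"), "A01", c(1e6, 2e6), species = "tet")
  gb <- make_genes(c("p1", "p2"), "A01", c(1e6, 2e6), species = "prog")
  hits <- make_hits(c("t1", "t2", "t1"), c("p1", "p2", "t2"),
                    identity = c(85, 95, 99),
                    qcov = c(90, 99, 99), scov = c(92, 99, 99),
                    evalue = c(1e-50, 1e-40, 1e-80))
  oo <- call_orthologs(hits, ga, gb, cfg)
  expect_equal(nrow(oo), 1L)             # 1e-40 fails; within-species never
  expect_equal(oo$gene_a, "t1")
  # exactly 1e-45 fails the strict "smaller than" bound
  at_bound <- make_hits("t2", "p2", 90, evalue = 1e-45)
  expect_equal(nrow(call_orthologs(at_bound, ga, gb, cfg)), 0L)
  # symmetric in species order (hit direction)
  rev_hits <- make_hits("p1", "t1", 85, qcov = 92, scov = 90,
                        evalue = 1e-50)
  oo2 <- call_orthologs(rev_hits, ga, gb, cfg)
  expect_equal(oo2$gene_a, "t1")
  expect_equal(oo2$gene_b, "p1")
})

test_that("conservation ledger closes and recovers planted counts", {
  w <- tiny_world()
  b <- run_landscape_pipeline(w, cfg)
  cv <- b$conservation
  expect_equal(cv$tetra_conserved + cv$gained, cv$tetra_total)
  expect_equal(cv$prog_conserved + cv$lost, cv$prog_total)
  truth <- w$truth$ledger
  m <- merge(cv, truth, by = c("family", "sub_genome"),
             suffixes = c("", ".t"))
  expect_equal(m$tetra_conserved, m$tetra_conserved.t)
  expect_equal(m$prog_conserved, m$prog_conserved.t)
  expect_equal(m$gained, m$gained.t)
  expect_equal(m$lost, m$lost.t)
  # unknown species in the pairing is a hard error
  expect_error(
    conservation_ledger(b$classifications[[w$tetraploid]],
                        data.table::rbindlist(
                          b$classifications[unname(w$pairing)]),
                        b$orthologs, c(A = "nope", B = "alsono"), cfg),
    "unknown progenitor")
  # no orthologs at all: conserved 0, gained = total
  cv0 <- conservation_ledger(b$classifications[[w$tetraploid]],
                             data.table::rbindlist(
                               b$classifications[unname(w$pairing)]),
                             b$orthologs[0], w$pairing, cfg)
  expect_true(all(cv0$tetra_conserved == 0))
  expect_equal(cv0$gained, cv0$tetra_total)
})

test_that("synteny chain length equals the brute-force LIS on small instances", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(4:15, 1L)
    perm <- sample.int(n)
    ga <- make_genes(sprintf("t%02d", 1:n), "A03",
                     1e6 + (1:n) * 1e5, species = "tet")
    gb <- make_genes(sprintf("p%02d", 1:n), "A03",
                     1e6 + (1:n) * 1e5, species = "prog")
    oo <- data.table::data.table(
      gene_a = sprintf("t%02d", 1:n), species_a = "tet",
      gene_b = sprintf("p%02d", perm), species_b = "prog")
    sc <- synteny_chains(oo, ga, gb, cfg)
    want <- oracle_lis_length(perm)
    if (want < cfg$synteny_min_chain) {
      expect_equal(nrow(sc$chains), 0L)
    } else {
      expect_equal(sc$chains$length, want)
    }
  }
  # the [3,1,2] instance: LIS length 2 < 3, so no chain
  ga <- make_genes(c("t1", "t2", "t3"), "A01", c(1e6, 2e6, 3e6), "tet")
  gb <- make_genes(c("p1", "p2", "p3"), "A01", c(1e6, 2e6, 3e6), "prog")
  oo <- data.table::data.table(gene_a = c("t1", "t2", "t3"),
                               species_a = "tet",
                               gene_b = c("p3", "p1", "p2"),
                               species_b = "prog")
  expect_equal(nrow(synteny_chains(oo, ga, gb, cfg)$chains), 0L)
})

test_that("a planted inversion breaks synteny for exactly its block", {
  n <- 20L
  inv <- 8:12                      # 5-anchor inverted block
  perm <- seq_len(n)
  perm[inv] <- rev(perm[inv])
  ga <- make_genes(sprintf("t%02d", 1:n), "A05", 1e6 + (1:n) * 1e5, "tet")
  gb <- make_genes(sprintf("p%02d", 1:n), "A05", 1e6 + (1:n) * 1e5, "prog")
  oo <- data.table::data.table(
    gene_a = sprintf("t%02d", 1:n), species_a = "tet",
    gene_b = sprintf("p%02d", perm), species_b = "prog")
  sc <- synteny_chains(oo, ga, gb, cfg)
  expect_equal(sc$chains$length, 16L)  # 15 collinear + 1 from the block
  non_syn <- sc$syntenic[syntenic == FALSE]$gene_id
  expect_true(all(non_syn %in% sprintf("t%02d", inv)))
  expect_equal(length(non_syn), 4L)
})

test_that("already collinear anchors form one full chain, all genes syntenic", {
  ga <- make_genes(sprintf("t%d", 1:4), "A02", (1:4) * 1e6, "tet")
  gb <- make_genes(sprintf("p%d", 1:4), "A02", (1:4) * 1e6, "prog")
  oo <- data.table::data.table(gene_a = sprintf("t%d", 1:4),
                               species_a = "tet",
                               gene_b = sprintf("p%d", 1:4),
                               species_b = "prog")
  sc <- synteny_chains(oo, ga, gb, cfg)
  expect_equal(sc$chains$length, 4L)
  expect_true(all(sc$syntenic$syntenic))
})

test_that("family-size comparison reproduces per-species proportions", {
  w <- tiny_world()
  b <- run_landscape_pipeline(w, cfg)
  ft <- compare_family_sizes(b$classifications)
  expect_setequal(unique(ft$species), names(b$classifications))
  # subfamily counts sum to family counts
  for (sp in unique(ft$species)) {
    x <- ft[species == sp]
    expect_equal(x[row_class == "RLK"]$count,
                 sum(x[row_class %in% c("LRR_RLK", "LYSM_RLK",
                                        "RLK_OTHER")]$count))
    expect_equal(x[row_class == "RLP"]$count,
                 sum(x[row_class %in% c("LRR_RLP", "LYSM_RLP")]$count))
  }
  # zero-RGA species renders 0 and "0.000%"
  none <- data.table::data.table(
    gene_id = "g1", species = "empty", chromosome = "A01",
    sub_genome = "A", class = factor("NON_RGA", levels = RGA_CLASSES),
    family = "NONE")
  ft0 <- build_family_table(list(empty = none))
  expect_true(all(ft0$count == 0L))
  expect_true(all(ft0$pct == "0.000%"))
})
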