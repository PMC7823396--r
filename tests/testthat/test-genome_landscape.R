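cfg <- analysis_config()

test_that("subgenome assignment follows the chromosome naming patterns", {
  expect_equal(assign_subgenome(c("A06", "B08", "UNPLACED", "A11", "B09"),
                                cfg),
               c("A", "B", "NONE", "NONE", "NONE"))
})

test_that("cluster chaining matches the stated rule examples", {
  g <- make_genes(paste0("g", 1:3), "A01", c(100e3, 150e3, 280e3))
  cl <- detect_clusters(g, cfg)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 3L)
  expect_equal(cl$first_start, 100e3)
  expect_equal(cl$last_end, g$end[3L])
  # all gaps over the threshold: nothing
  g2 <- make_genes(paste0("g", 1:3), "A01", c(100e3, 350e3, 600e3))
  expect_equal(nrow(detect_clusters(g2, cfg)), 0L)
  # chaining permits spans beyond the gap threshold
  g3 <- make_genes(paste0("g", 1:3), "A01", c(0, 190e3, 380e3) + 1)
  cl3 <- detect_clusters(g3, cfg)
  expect_equal(nrow(cl3), 1L)
  expect_gt(cl3$span_bp, cfg$cluster_max_gap_bp)
  expect_error(detect_clusters(g[c(2, 1, 3)], cfg), "sorted")
  expect_error(
    detect_clusters(make_genes(c("a", "b"), c("A01", "A02"), c(1, 2)), cfg),
    "single chromosome")
})

test_that("cluster detection equals the brute-force chain oracle and is order-invariant", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:30, 1L)
    starts <- sort(sample.int(3e6, n))
    g <- make_genes(sprintf("g%02d", seq_len(n)), "B03", starts)
    cl <- detect_clusters(g, cfg)
    want <- oracle_clusters(starts, cfg$cluster_max_gap_bp,
                            cfg$cluster_min_genes)
    expect_equal(nrow(cl), length(want))
    got_members <- lapply(cl$member_ids,
                          function(m) strsplit(m, ",")[[1L]])
    want_members <- lapply(want, function(ix) g$gene_id[ix])
    expect_equal(got_members, want_members)
    # chains never overlap: clustered + singleton genes = all genes
    members <- unlist(got_members)
    expect_false(anyDuplicated(members) > 0L)
    expect_equal(sum(cl$n_members) + (n - length(members)), n)
  }
})

test_that("gap shrinking and min-gene raising are monotone", {
  set.seed(5)
  starts <- sort(sample.int(2e6, 20L))
  g <- make_genes(sprintf("g%02d", 1:20), "A05", starts)
  gaps <- c(250e3, 200e3, 120e3, 60e3)
  prev_sizes <- NULL
  for (gp in gaps) {
    cl <- detect_clusters(g, analysis_config(cluster_max_gap_bp = gp))
    sizes <- sort(cl$n_members, decreasing = TRUE)
    if (!is.null(prev_sizes))
      expect_lte(sum(sizes), sum(prev_sizes))
    prev_sizes <- sizes
  }
  n_at <- vapply(2:6, function(k)
    nrow(detect_clusters(g, analysis_config(cluster_min_genes = k))),
    integer(1L))
  expect_true(all(diff(n_at) <= 0))
})

test_that("distribution table closes (mapped + unassigned = total)", {
  w <- tiny_world()
  b <- run_landscape_pipeline(w, cfg)
  cl <- b$classifications[[w$tetraploid]]
  dist <- distribution_table(cl, cfg)
  ms <- dist$mapped_summary
  expect_equal(ms$mapped + ms$unplaced, ms$total)
  expect_equal(sum(dist$per_chromosome$n) + sum(dist$unassigned$n),
               sum(ms$total))
})

test_that("homogeneity labelling distinguishes mixed subfamilies", {
  classes <- data.table::data.table(
    gene_id = c("a", "b", "c", "d", "e", "f"),
    class = c("LRR_RLK", "LRR_RLK", "LRR_RLK",
              "LYSM_RLK", "LRR_RLK", "LRR_RLK"))
  clusters <- data.table::data.table(
    cluster_id = c("x", "y"), chromosome = "A06", n_members = 3L,
    first_start = 1, last_end = 2, span_bp = 1,
    member_ids = c("a,b,c", "d,e,f"))
  lab <- label_homogeneity(clusters, classes)
  expect_equal(lab$homogeneous, c(TRUE, FALSE))
})

test_that("cluster statistics recompute span summaries exactly", {
  clusters <- data.table::data.table(
    cluster_id = c("c1", "c2"), chromosome = c("A03", "B03"),
    n_members = c(3L, 4L), first_start = c(1, 1),
    last_end = c(29451, 293951), span_bp = c(29450, 293950),
    member_ids = c("a,b,c", "d,e,f,g"))
  st <- cluster_statistics(clusters, cfg = cfg)
  expect_equal(st$span_kb_min, 29.45)
  expect_equal(st$span_kb_max, 293.95)
  expect_equal(st$span_kb_mean, 161.70)
  expect_equal(st$n_genes, 7L)
  z <- cluster_statistics(clusters[0], cfg = cfg)
  expect_equal(z$n_clusters, 0L)
  expect_equal(z$span_kb_mean, 0)
  # planted spans: mean equals the arithmetic mean to 2 dp
  set.seed(3)
  spans <- sample.int(300000, 9L)
  cl2 <- data.table::data.table(
    cluster_id = paste0("c", 1:9), chromosome = "A01", n_members = 3L,
    first_start = 1, last_end = spans + 1, span_bp = spans,
    member_ids = "x,y,z")
  st2 <- cluster_statistics(cl2, cfg = cfg)
  expect_equal(st2$span_kb_mean,
               floor(mean(spans) / 10 + 0.5) / 100)
})
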