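cfg <- analysis_config()

test_that("hit-derived distances follow the identity rule with min-symmetrisation", {
  labels <- c("a", "b", "c")
  hits <- make_hits(c("a", "a", "b"), c("b", "b", "c"),
                    identity = c(80, 90, 60))
  d <- distances_from_hits(hits, labels)
  expect_equal(d["a", "b"], 0.10)   # best of 80/90
  expect_equal(d["b", "c"], 0.40)
  expect_equal(d["a", "c"], 1.00)   # no hit
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(d))
})

test_that("three-taxon closed form and input validation", {
  d <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, 3,
              dimnames = list(c("i", "j", "k"), c("i", "j", "k")))
  tree <- neighbor_joining(d)
  expect_s3_class(tree, "phylo")
  expect_equal(ape::Ntip(tree), 3L)
  # branch to leaf i = (d(i,j) + d(i,k) - d(j,k)) / 2 = 2
  lens <- setNames(tree$edge.length[match(seq_len(3L), tree$edge[, 2L])],
                   tree$tip.label)
  expect_equal(unname(lens[c("i", "j", "k")]), c(2, 3, 7))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  bad <- d; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("ties join the lexicographically first pair, deterministically", {
  d <- matrix(1, 5, 5); diag(d) <- 0
  dimnames(d) <- list(letters[1:5], letters[1:5])
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # the first join must be (a, b): they end up as sisters
  expect_equal(group_cut(t1, 3)[[1]], c("a", "b"))
})

test_that("NJ recovers every 4-6 leaf additive tree exactly", {
  skip_if_not_installed("phangorn")
  set.seed(99)
  for (n in 4:6) {
    tops <- phangorn::allTrees(n, rooted = FALSE,
                               tip.label = letters[1:n])
    for (ti in seq_along(tops)) {
      tr <- tops[[ti]]   # [[ restores the multiPhylo compressed tip labels
      tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
      d <- cophenetic(tr)[letters[1:n], letters[1:n]]
      got <- neighbor_joining(d)
      expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(tr)), 0,
                   ignore_attr = TRUE)
      # branch lengths: total tree length and pairwise path lengths match
      expect_equal(sort(got$edge.length),
                   sort(tr$edge.length), tolerance = 1e-8)
      expect_equal(cophenetic(got)[letters[1:n], letters[1:n]], d,
                   tolerance = 1e-8)
    }
  }
})

test_that("NJ matches the quartet least-squares oracle and ape::nj on random matrices", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 4L
    base <- ape::rtree(n, tip.label = letters[1:n])
    base$edge.length <- runif(nrow(base$edge), 0.1, 1)
    d <- cophenetic(base)[letters[1:n], letters[1:n]]
    d <- d + matrix(runif(n * n, 0, 0.02), n, n)  # mild noise
    d <- (d + t(d)) / 2; diag(d) <- 0
    got <- neighbor_joining(d)
    expect_equal(quartet_sister(got, "a"), oracle_quartet(d))
    # independent dual route: same topology as ape::nj
    expect_equal(ape::dist.topo(ape::unroot(got),
                                ape::unroot(ape::nj(d))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("trees are label-permutation invariant and round-trip through Newick", {
  set.seed(31)
  tr <- ape::rtree(8)
  d <- cophenetic(tr)
  got <- neighbor_joining(d)
  perm <- sample.int(8)
  got_p <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(got_p)), 0,
               ignore_attr = TRUE)
  expect_equal(cophenetic(got_p)[rownames(d), rownames(d)],
               cophenetic(got)[rownames(d), rownames(d)],
               tolerance = 1e-8)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(got, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(back, got), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(got$edge.length),
               tolerance = 1e-8)
})

test_that("group_cut honours k across its whole range", {
  # two planted clades joined by a long stem
  nwk <- "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):2.0,e:0.1);"
  tree <- ape::read.tree(text = nwk)
  expect_equal(group_cut(tree, 1), list(sort(tree$tip.label)))
  g2 <- group_cut(tree, 2)
  expect_true(list(c("c", "d")) %in% g2 ||
                any(vapply(g2, function(g) identical(g, c("c", "d")),
                           logical(1L))))
  expect_equal(group_cut(tree, 5), as.list(letters[1:5]))
  expect_error(group_cut(tree, 0), "k must be")
  expect_error(group_cut(tree, 9), "k must not")
})

test_that("a long-stem two-clade tree is split into the planted clades", {
  set.seed(8)
  cladeA <- ape::rtree(4, tip.label = paste0("A", 1:4))
  cladeB <- ape::rtree(4, tip.label = paste0("B", 1:4))
  stem <- ape::read.tree(text = "(x:5,y:5);")
  tr <- ape::bind.tree(stem, cladeA, where = 1)
  tr <- ape::bind.tree(tr, cladeB, where = which(tr$tip.label == "y"))
  d <- cophenetic(tr)
  got <- neighbor_joining(d)
  groups <- group_cut(got, 2)
  sets <- lapply(groups, function(g) sort(g))
  expect_setequal(sets, list(sort(paste0("A", 1:4)),
                             sort(paste0("B", 1:4))))
})
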