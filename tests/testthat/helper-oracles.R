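# Independent oracles (deliberately different code paths from the package).

# Brute-force maximal gap-chains: every maximal contiguous window of genes
# whose consecutive start gaps are all <= gap, of size >= min_genes.
oracle_clusters <- function(starts, gap, min_genes = 3L) {
  n <- length(starts)
  if (n == 0L) return(list())
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && starts[j + 1L] - starts[j] <= gap) j <- j + 1L
    if (j - i + 1L >= min_genes) out[[length(out) + 1L]] <- i:j
    i <- j + 1L
  }
  out
}

# Exhaustive longest strictly-increasing subsequence (subset enumeration).
oracle_lis_length <- function(x) {
  n <- length(x)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    v <- x[idx]
    if (all(diff(v) > 0)) best <- length(idx)
  }
  best
}

# Per-gene rule-table re-derivation of the classifier (scalar loop).
oracle_classify <- function(genes, domains, prescreen_ids, cfg) {
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    rec <- domains[domains$gene_id == g & domains$evalue <= cfg$domain_evalue_max, ]
    has <- function(cl) any(rec$domain_class == cl)
    pre <- g %in% prescreen_ids
    cls <- "NON_RGA"
    if (pre && has("TM")) {
      ecto <- if (has("LYSM")) "LYSM" else if (has("LRR")) "LRR" else "NONE"
      if (has("LYSM") && has("LRR") && cfg$ectodomain_priority == "LRR")
        ecto <- "LRR"
      if (has("KINASE_STTK")) {
        cls <- switch(ecto, LYSM = "LYSM_RLK", LRR = "LRR_RLK",
                      NONE = "RLK_OTHER")
      } else if (ecto != "NONE") {
        cls <- paste0(ecto, "_RLP")
      }
    }
    out[i] <- cls
  }
  out
}

# Direct recount of a duplication summary from the pair list.
oracle_dup_summary <- function(pairs) {
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  tand <- unique(c(pairs$gene_a[pairs$positional_type == "TANDEM"],
                   pairs$gene_b[pairs$positional_type == "TANDEM"]))
  list(n_events = nrow(pairs), n_duplicated_genes = length(genes),
       n_tandem_genes = length(tand),
       by_scope = table(pairs$genome_scope))
}

# Least-squares quartet oracle: fit branch lengths for each of the three
# quartet topologies and pick the best-fitting one.
oracle_quartet <- function(d) {
  taxa <- rownames(d)
  stopifnot(length(taxa) == 4L)
  # topology ((1,2),(3,4)) has path matrix rows for pairs 12,13,14,23,24,34
  design <- function(split) {
    # split: the pair grouped with taxon 1
    o <- setdiff(2:4, split)
    pairs <- t(combn(4L, 2L))
    X <- matrix(0, 6L, 5L)  # e1..e4 pendant, e5 internal
    for (r in seq_len(6L)) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      X[r, i] <- 1; X[r, j] <- 1
      same <- (j == split && i == 1L) || (i == 1L && j == split) ||
        all(c(i, j) %in% o)
      if (!same) X[r, 5L] <- 1
    }
    X
  }
  y <- d[t(combn(4L, 2L))]
  best <- NULL; best_rss <- Inf
  for (split in 2:4) {
    X <- design(split)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best <- split }
  }
  # return the sister taxon of taxon 1 under the best topology
  taxa[best]
}

# Sister of `taxon` in an unrooted 4-leaf phylo tree: the single
# non-trivial bipartition of a quartet pairs the sisters.
quartet_sister <- function(tree, taxon) {
  tree <- ape::unroot(tree)
  splits <- phangorn::as.splits(tree)
  m <- as.matrix(splits)
  lab <- attr(splits, "labels")
  for (r in which(rowSums(m) == 2L)) {
    pair <- lab[m[r, ] == 1L]
    if (taxon %in% pair) return(setdiff(pair, taxon))
    return(setdiff(lab, c(pair, taxon))[1L])
  }
  stop("no non-trivial split found")
}
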