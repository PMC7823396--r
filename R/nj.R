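#' Pairwise distance matrix from all-vs-all similarity hits
#'
#' `d(i, j) = 1 - best_identity(i, j) / 100`, symmetrised by the minimum
#' distance over both hit directions; label pairs without any hit fall back
#' to the maximum distance 1.  This identity-based distance is a declared
#' stand-in for alignment-based distances.
#'
#' @param hits similarity hits among the labelled genes.
#' @param labels ordered gene ids (matrix row/column order).
#' @return symmetric numeric matrix with zero diagonal and `labels` as
#'   dimnames.
#' @export
distances_from_hits <- function(hits, labels) {
  stopifnot(!anyDuplicated(labels))
  n <- length(labels)
  d <- matrix(1, n, n, dimnames = list(labels, labels))
  diag(d) <- 0
  hits <- as.data.table(hits)
  hits <- hits[query_id %in% labels & subject_id %in% labels & !self_hit]
  if (nrow(hits)) {
    i <- match(hits$query_id, labels)
    j <- match(hits$subject_id, labels)
    v <- 1 - hits$pct_identity / 100
    for (k in seq_along(i)) {
      if (v[k] < d[i[k], j[k]]) {
        d[i[k], j[k]] <- v[k]
        d[j[k], i[k]] <- v[k]
      }
    }
  }
  d
}

#' Neighbour-joining tree construction
#'
#' Standard rate-corrected agglomeration: iteratively join the pair
#' minimising `Q(i, j) = (n - 2) d(i, j) - R_i - R_j`, assign branch lengths
#' `l_i = d(i, j) / 2 + (R_i - R_j) / (2 (n - 2))`, and reduce the matrix
#' with `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`.  Exact ties in Q are
#' broken by the lexicographically smallest active index pair, which makes
#' the output bitwise deterministic.  Negative branch lengths are clamped to
#' zero with the deficit moved to the sibling branch (path lengths
#' preserved).
#'
#' @param d symmetric distance matrix with zero diagonal (labels in
#'   dimnames), at least 3 taxa.
#' @return an unrooted `ape::phylo` tree (trifurcating root node).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining requires at least 3 taxa",
                   call. = FALSE)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(!is.finite(d)))
    stop("distance matrix must be symmetric, finite, with zero diagonal",
         call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # newick fragment per active node; leaves start as bare labels
  frag <- labels
  is_leaf <- rep(TRUE, n)
  while (nrow(d) > 2L) {
    m <- nrow(d)
    R <- rowSums(d)
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        Q <- (m - 2) * d[i, j] - R[i] - R[j]
        if (Q < bestQ) { bestQ <- Q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    is_leaf <- c(is_leaf[keep], FALSE)
  }
  # two nodes remain; the final edge carries their full distance.  The last
  # created node is internal: merge the other node into it as a third child.
  d12 <- max(d[1L, 2L], 0)
  a <- frag[2L]; b <- frag[1L]   # frag[2] is the newest (internal) node
  inner <- substr(a, 2L, nchar(a) - 1L)
  nwk <- sprintf("(%s,%s:%.12g);", inner, b, d12)
  tree <- ape::read.tree(text = nwk)
  tree
}

#' Cut a tree into k leaf groups
#'
#' Removes the longest internal edges first (ties broken by edge index);
#' when internal edges are exhausted (only possible for `k` close to the
#' number of leaves), pendant edges in components still holding two or more
#' leaves are removed, longest first.  Connected components define the
#' groups.
#'
#' @param tree an `ape::phylo`.
#' @param k number of groups, `1 <= k <=` number of leaves.
#' @return list of character vectors (sorted leaf labels), ordered by their
#'   first member.
#' @export
group_cut <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k must not exceed the number of leaves", call. = FALSE)
  edges <- tree$edge
  lens <- tree$edge.length
  n_nodes <- max(edges)
  removed <- rep(FALSE, nrow(edges))
  internal <- edges[, 2L] > n

  components <- function() {
    parent <- seq_len(n_nodes)
    find <- function(x) { while (parent[x] != x) x <- parent[x] <<- parent[parent[x]]; x }
    for (e in which(!removed)) {
      a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
      if (a != b) parent[b] <- a
    }
    vapply(seq_len(n_nodes), find, integer(1L))
  }
  leaf_groups <- function(comp) {
    split(seq_len(n), comp[seq_len(n)])
  }
  repeat {
    comp <- components()
    groups <- leaf_groups(comp)
    if (length(groups) >= k) break
    cand <- which(!removed & internal)
    if (!length(cand)) {
      multi <- names(which(table(comp[seq_len(n)]) >= 2L))
      cand <- which(!removed & !internal &
                      comp[edges[, 2L]] %in% as.integer(multi))
      if (!length(cand)) break
    }
    cut <- cand[order(-lens[cand], cand)][1L]
    removed[cut] <- TRUE
  }
  out <- lapply(groups, function(idx) sort(tree$tip.label[idx]))
  out <- unname(out[order(vapply(out, `[`, character(1L), 1L))])
  out
}
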