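# Planted relationship graphs -------------------------------------------------

# Assembles the duplicate-pair graph of one family so that the per-subgenome
# duplicated-gene counts and the event budgets (tandem / segmental /
# dispersed / inter) are met exactly.  Forced edges (tandem-cluster chains,
# planted tandem pairs, segmental mates) come from placement; coverage of the
# remaining duplicated genes is completed with inter edges first, and the
# leftover budgets are spent on extra edges between already-covered genes.
sim_build_duplicates <- function(tet, cfg, fam) {
  genes <- tet$genes
  spec <- cfg$dup[[fam]]
  forced <- tet$forced_edges[family == fam]
  cl_pairs <- forced[role == "TANDEM"]
  seg_pairs <- forced[role == "SEGMENTAL"]

  fam_genes <- genes[family == fam & chromosome != CHROM_UNPLACED]
  sg_of <- setNames(fam_genes$sub_genome, fam_genes$gene_id)
  chr_of <- setNames(fam_genes$chromosome, fam_genes$gene_id)

  edges <- rbindlist(list(
    cl_pairs[, .(gene_a, gene_b, positional_type = "TANDEM")],
    seg_pairs[, .(gene_a, gene_b, positional_type = "SEGMENTAL")]))
  keys <- pair_key(edges$gene_a, edges$gene_b)
  covered <- unique(c(edges$gene_a, edges$gene_b))

  tandem_genes_now <- length(unique(unlist(
    cl_pairs[, c(gene_a, gene_b)])))
  if (tandem_genes_now != spec$tandem_genes)
    stop("sim_config: tandem gene budget (", spec$tandem_genes,
         ") does not match planted tandem structures (",
         tandem_genes_now, ") for ", fam, call. = FALSE)

  need <- list()
  for (sg in c("A", "B")) {
    pool <- fam_genes[sub_genome == sg]$gene_id
    cov_sg <- intersect(covered, pool)
    n_more <- spec$dup_genes[[sg]] - length(cov_sg)
    if (n_more < 0)
      stop("sim_config: forced structures exceed the duplicated-gene ",
           "budget for subgenome ", sg, " (", fam, ")", call. = FALSE)
    cand <- setdiff(pool, cov_sg)
    if (n_more > length(cand))
      stop("sim_config: not enough ", fam, " genes in subgenome ", sg,
           " to reach the duplicated-gene budget", call. = FALSE)
    need[[sg]] <- if (n_more > 0L) sample(cand, n_more) else character()
  }
  inter_budget <- spec$inter_pairs
  m <- min(length(need$A), length(need$B))
  new_edges <- list()
  if (m > 0L)
    new_edges[[length(new_edges) + 1L]] <- data.table(
      gene_a = need$A[seq_len(m)], gene_b = need$B[seq_len(m)],
      positional_type = "DISPERSED")
  leftover <- if (length(need$A) > m) need$A[-seq_len(m)]
              else need$B[-seq_len(m)]
  cov_other <- intersect(covered,
                         names(sg_of)[sg_of == if (length(need$A) > m) "B"
                                      else "A"])
  if (length(leftover)) {
    if (!length(cov_other))
      stop("sim_config: cannot cover leftover genes with inter edges",
           call. = FALSE)
    partners <- rep(cov_other, length.out = length(leftover))
    new_edges[[length(new_edges) + 1L]] <- data.table(
      gene_a = leftover, gene_b = partners,
      positional_type = "DISPERSED")
  }
  inter_used <- m + length(leftover)
  if (inter_used > inter_budget)
    stop("sim_config: inter-pair budget too small to cover the ",
         "duplicated-gene targets (", fam, ")", call. = FALSE)
  if (length(new_edges)) {
    ne <- rbindlist(new_edges)
    # orient inter edges A-side first for readability
    swap <- sg_of[ne$gene_a] == "B"
    tmp <- ne$gene_a[swap]; ne$gene_a[swap] <- ne$gene_b[swap]
    ne$gene_b[swap] <- tmp
    edges <- rbindlist(list(edges, ne))
    keys <- c(keys, pair_key(ne$gene_a, ne$gene_b))
    covered <- unique(c(covered, ne$gene_a, ne$gene_b))
  }

  # spend remaining budgets on extra edges among covered genes
  pick_extra <- function(pool_a, pool_b, n, diff_chrom_required) {
    out_a <- character(n); out_b <- character(n)
    got <- 0L; k <- 0L
    na <- length(pool_a); nb <- length(pool_b)
    max_tries <- 50L * max(n, 1L) * max(na, 1L)
    while (got < n) {
      k <- k + 1L
      if (k > max_tries)
        stop("sim_config: unable to place ", n, " extra edges (", fam,
             "); budgets infeasible", call. = FALSE)
      a <- pool_a[((k - 1L) %% na) + 1L]
      b <- pool_b[((k - 1L + (k - 1L) %/% na) %% nb) + 1L]
      if (a == b) next
      if (diff_chrom_required && chr_of[[a]] == chr_of[[b]]) next
      key <- pair_key(a, b)
      if (key %in% keys) next
      got <- got + 1L
      out_a[got] <- a; out_b[got] <- b
      keys <<- c(keys, key)
    }
    data.table(gene_a = out_a, gene_b = out_b,
               positional_type = "DISPERSED")
  }
  cov_A <- intersect(covered, names(sg_of)[sg_of == "A"])
  cov_B <- intersect(covered, names(sg_of)[sg_of == "B"])
  n_inter_extra <- inter_budget - inter_used
  if (n_inter_extra > 0L)
    edges <- rbindlist(list(edges,
                            pick_extra(cov_A, cov_B, n_inter_extra, FALSE)))
  for (sg in c("A", "B")) {
    n_disp <- spec$dispersed_pairs[[sg]]
    pool <- if (sg == "A") cov_A else cov_B
    if (n_disp > 0L)
      edges <- rbindlist(list(edges,
                              pick_extra(pool, pool, n_disp, TRUE)))
  }
  edges[, family := fam]
  # intended genome scope, for the ground truth
  edges[, genome_scope := fifelse(
    sg_of[gene_a] == sg_of[gene_b],
    paste0("INTRA_", sg_of[gene_a]), "INTER")]
  setorder(edges, gene_a, gene_b)
  edges[]
}

# Ortholog map between one tetraploid subgenome and its progenitor, planted
# collinearly so synteny holds by construction on placed chromosomes.
sim_build_orthologs <- function(tet, prog, cfg, fam, sg) {
  prog_sp <- prog$species[1L]
  spec <- cfg$conservation[[fam]]
  n_t <- spec$tetra[[sg]]; n_p <- spec$prog[[sg]]
  t_genes <- tet$genes[family == fam & sub_genome == sg &
                         chromosome != CHROM_UNPLACED]
  p_genes <- prog[family == fam]
  if (n_t > nrow(t_genes) || n_p > nrow(p_genes))
    stop("sim_config: conserved counts exceed available ", fam,
         " genes for subgenome ", sg, call. = FALSE)
  if (n_p < n_t)
    stop("sim_config: progenitor conserved count below tetraploid ",
         "conserved count is not supported", call. = FALSE)
  edges <- list()
  placed_prog <- any(p_genes$chromosome != CHROM_UNPLACED)
  if (placed_prog) {
    # allocate conserved counts per chromosome (largest remainder, capped)
    chroms <- sort(intersect(unique(t_genes$chromosome),
                             unique(p_genes$chromosome)))
    nt_ch <- vapply(chroms, function(ch) sum(t_genes$chromosome == ch),
                    integer(1L))
    np_ch <- vapply(chroms, function(ch) sum(p_genes$chromosome == ch),
                    integer(1L))
    cap <- pmin(nt_ch, np_ch)
    alloc <- floor(n_t * nt_ch / sum(nt_ch))
    alloc <- pmin(alloc, cap)
    i <- 1L
    while (sum(alloc) < n_t) {
      ix <- ((i - 1L) %% length(chroms)) + 1L
      if (alloc[ix] < cap[ix]) alloc[ix] <- alloc[ix] + 1L
      i <- i + 1L
      if (i > 10000L)
        stop("sim_config: cannot allocate conserved genes over ",
             "chromosomes", call. = FALSE)
    }
    matched_t <- list(); used_p <- character()
    for (j in seq_along(chroms)) {
      if (alloc[j] == 0L) next
      ch <- chroms[j]
      tc <- t_genes[chromosome == ch]
      pc <- p_genes[chromosome == ch]
      sel_t <- tc[sort(sample.int(nrow(tc), alloc[j]))]
      sel_p <- pc[sort(sample.int(nrow(pc), alloc[j]))]
      setorder(sel_t, start); setorder(sel_p, start)
      edges[[length(edges) + 1L]] <- data.table(
        gene_a = sel_t$gene_id, gene_b = sel_p$gene_id)
      matched_t[[length(matched_t) + 1L]] <- sel_t$gene_id
      used_p <- c(used_p, sel_p$gene_id)
    }
    matched_t <- unlist(matched_t)
    extra <- n_p - n_t
    if (extra > 0L) {
      cand <- setdiff(p_genes$gene_id, used_p)
      sel <- sample(cand, extra)
      # link each extra progenitor gene to a conserved tetraploid gene on
      # the same chromosome when possible (harmless to synteny either way)
      p_chr <- setNames(p_genes$chromosome, p_genes$gene_id)
      t_chr <- setNames(t_genes$chromosome, t_genes$gene_id)
      partners <- vapply(sel, function(pg) {
        same <- matched_t[t_chr[matched_t] == p_chr[[pg]]]
        if (length(same)) same[[1L]] else matched_t[[1L]]
      }, character(1L))
      edges[[length(edges) + 1L]] <- data.table(gene_a = partners,
                                                gene_b = sel)
    }
  } else {
    sel_t <- sample(t_genes$gene_id, n_t)
    sel_p <- sample(p_genes$gene_id, n_p)
    edges[[length(edges) + 1L]] <- data.table(
      gene_a = sel_t, gene_b = sel_p[seq_len(n_t)])
    if (n_p > n_t)
      edges[[length(edges) + 1L]] <- data.table(
        gene_a = rep(sel_t, length.out = n_p - n_t),
        gene_b = sel_p[-seq_len(n_t)])
  }
  out <- rbindlist(edges)
  out[, `:=`(family = fam, sub_genome = sg, prog_species = prog_sp)]
  setorder(out, gene_a, gene_b)
  out[]
}
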