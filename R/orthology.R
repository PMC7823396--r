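#' Call cross-species ortholog pairs
#'
#' A pair qualifies when some hit between genes of the two species has
#' `evalue < ortholog_evalue_max` (strict), identity at or above
#' `ortholog_similarity_min` and BOTH coverages at or above
#' `ortholog_coverage_min`.  Many-to-many relationships are permitted unless
#' `cfg$bbh` is set, in which case only best-bidirectional pairs survive.
#' Within-species hits never qualify.
#'
#' @param hits cross-species similarity hits (either direction).
#' @param genes_a,genes_b gene models of the two species.
#' @param cfg an [analysis_config()].
#' @return `data.table`: `gene_a`/`species_a` (first species), `gene_b`/
#'   `species_b`, `pct_identity`, `query_cov`, `subject_cov`, `evalue`.
#' @export
call_orthologs <- function(hits, genes_a, genes_b,
                           cfg = analysis_config()) {
  hits <- as.data.table(hits)
  ga <- as.data.table(genes_a); gb <- as.data.table(genes_b)
  sp_a <- unique(ga$species); sp_b <- unique(gb$species)
  stopifnot(length(sp_a) == 1L, length(sp_b) == 1L, sp_a != sp_b)
  empty <- data.table(gene_a = character(), species_a = character(),
                      gene_b = character(), species_b = character(),
                      pct_identity = numeric(), query_cov = numeric(),
                      subject_cov = numeric(), evalue = numeric())
  if (nrow(hits) == 0L) return(empty)
  in_a <- function(x) x %in% ga$gene_id
  in_b <- function(x) x %in% gb$gene_id
  fwd <- hits[in_a(query_id) & in_b(subject_id)]
  rev <- hits[in_b(query_id) & in_a(subject_id)]
  # orient so gene_a is always the species_a gene
  rev <- rev[, .(query_id = subject_id, subject_id = query_id,
                 pct_identity, query_cov = subject_cov,
                 subject_cov = query_cov, evalue, bitscore)]
  all <- rbindlist(list(
    fwd[, .(query_id, subject_id, pct_identity, query_cov, subject_cov,
            evalue, bitscore)],
    rev), use.names = TRUE)
  if (nrow(all) == 0L) return(empty)
  ok <- all[evalue < cfg$ortholog_evalue_max &
              pass_min(pct_identity, cfg$ortholog_similarity_min, cfg) &
              pass_min(query_cov, cfg$ortholog_coverage_min, cfg) &
              pass_min(subject_cov, cfg$ortholog_coverage_min, cfg)]
  if (nrow(ok) == 0L) return(empty)
  setorder(ok, query_id, subject_id, evalue, -bitscore)
  best <- ok[, .SD[1L], by = .(query_id, subject_id)]
  if (cfg$bbh) {
    setorder(best, query_id, evalue, -bitscore, subject_id)
    best_a <- best[, .SD[1L], by = query_id]
    setorder(best, subject_id, evalue, -bitscore, query_id)
    best_b <- best[, .SD[1L], by = subject_id]
    keys <- intersect(paste(best_a$query_id, best_a$subject_id),
                      paste(best_b$query_id, best_b$subject_id))
    best <- best[paste(query_id, subject_id) %in% keys]
  }
  out <- best[, .(gene_a = query_id, species_a = sp_a,
                  gene_b = subject_id, species_b = sp_b,
                  pct_identity, query_cov, subject_cov, evalue)]
  setorder(out, gene_a, gene_b)
  out[]
}

#' Subgenome-vs-progenitor conservation ledger
#'
#' For each family and each subgenome-to-progenitor pairing (A to the
#' A-genome progenitor, B to the B-genome progenitor): a tetraploid gene is
#' conserved when it has at least one ortholog in the paired progenitor, and
#' vice versa.  Gains are tetraploid genes without orthologs; losses are
#' progenitor genes without orthologs.  The closure invariants
#' `conserved + gained = tetraploid total` and
#' `conserved + lost = progenitor total` are asserted on every run.
#'
#' @param tetra_classification classification of the tetraploid species.
#' @param prog_classifications classification rows of all progenitor species
#'   (one table, `species` column distinguishes them).
#' @param orthologs ortholog pairs (rows for all species pairs; `species_a`
#'   must be the tetraploid).
#' @param pairing named character vector mapping subgenome labels to
#'   progenitor species tags, e.g. `c(A = "Br_syn", B = "Bn_syn")`.
#' @param cfg an [analysis_config()].
#' @return `data.table`, one row per family x subgenome: totals, conserved
#'   counts and percentages (2 decimals), `gained`, `lost`.
#' @export
conservation_ledger <- function(tetra_classification, prog_classifications,
                                orthologs, pairing,
                                cfg = analysis_config()) {
  tt <- as.data.table(tetra_classification)
  pp <- as.data.table(prog_classifications)
  oo <- as.data.table(orthologs)
  missing_sp <- setdiff(unname(pairing), unique(pp$species))
  if (length(missing_sp))
    stop("pairing references unknown progenitor species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  rows <- list()
  for (fam in c("RLK", "RLP")) {
    for (sg in names(pairing)) {
      prog_sp <- pairing[[sg]]
      t_genes <- tt[tt$family == fam & tt$sub_genome == sg &
                      tt$chromosome != CHROM_UNPLACED]$gene_id
      p_genes <- pp[pp$family == fam & pp$species == prog_sp]$gene_id
      oo_fam <- oo[species_b == prog_sp & gene_a %in% t_genes &
                     gene_b %in% p_genes]
      t_cons <- sum(t_genes %in% oo_fam$gene_a)
      p_cons <- sum(p_genes %in% oo_fam$gene_b)
      gained <- length(t_genes) - t_cons
      lost <- length(p_genes) - p_cons
      stopifnot(t_cons + gained == length(t_genes),
                p_cons + lost == length(p_genes))
      rows[[length(rows) + 1L]] <- data.table(
        family = fam, sub_genome = sg, prog_species = prog_sp,
        tetra_total = length(t_genes), tetra_conserved = t_cons,
        tetra_conserved_pct =
          paste0(pct_string(t_cons, length(t_genes)), "%"),
        gained = gained,
        prog_total = length(p_genes), prog_conserved = p_cons,
        prog_conserved_pct =
          paste0(pct_string(p_cons, length(p_genes)), "%"),
        lost = lost)
    }
  }
  rbindlist(rows)[]
}

# Longest strictly-increasing subsequence; returns the indices of one
# maximum-length chain (leftmost reconstruction, deterministic).
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer())
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  out <- integer(len[best])
  k <- len[best]; i <- best
  while (i > 0L) { out[k] <- i; k <- k - 1L; i <- prev[i] }
  out
}

#' Chromosome-level synteny chains from ortholog anchors
#'
#' For every chromosome name shared by the two species, ortholog anchor
#' pairs are sorted by position in species A; the longest strictly
#' increasing subsequence of species-B position ranks forms the chain.
#' Chains with at least `synteny_min_chain` anchors are reported, and a
#' species-A gene is syntenic when it anchors a reported chain.
#'
#' @param orthologs ortholog pairs from [call_orthologs()].
#' @param genes_a,genes_b gene models of the two species.
#' @param cfg an [analysis_config()].
#' @return list: `chains` (`data.table`: `chromosome`, `length`,
#'   `anchor_genes_a`, `anchor_genes_b`) and `syntenic`
#'   (`data.table`: `gene_id`, `syntenic` for every species-A gene in an
#'   anchor).
#' @export
synteny_chains <- function(orthologs, genes_a, genes_b,
                           cfg = analysis_config()) {
  oo <- as.data.table(orthologs)
  ga <- as.data.table(genes_a); gb <- as.data.table(genes_b)
  pos_a <- setNames(ga$start, ga$gene_id)
  pos_b <- setNames(gb$start, gb$gene_id)
  chr_a <- setNames(ga$chromosome, ga$gene_id)
  chr_b <- setNames(gb$chromosome, gb$gene_id)
  shared <- intersect(setdiff(unique(ga$chromosome), CHROM_UNPLACED),
                      setdiff(unique(gb$chromosome), CHROM_UNPLACED))
  chains <- list()
  syn_genes <- character()
  anchor_genes <- character()
  for (ch in sort(shared)) {
    an <- oo[chr_a[gene_a] == ch & chr_b[gene_b] == ch]
    if (nrow(an) == 0L) next
    an[, `:=`(pos_a = pos_a[gene_a], pos_b = pos_b[gene_b])]
    setorder(an, pos_a, pos_b, gene_a, gene_b)
    anchor_genes <- c(anchor_genes, an$gene_a)
    idx <- lis_indices(rank(an$pos_b, ties.method = "min"))
    if (length(idx) < cfg$synteny_min_chain) next
    chain <- an[idx]
    chains[[length(chains) + 1L]] <- data.table(
      chromosome = ch, length = length(idx),
      anchor_genes_a = paste(chain$gene_a, collapse = ","),
      anchor_genes_b = paste(chain$gene_b, collapse = ","))
    syn_genes <- c(syn_genes, chain$gene_a)
  }
  chains <- if (length(chains)) rbindlist(chains) else
    data.table(chromosome = character(), length = integer(),
               anchor_genes_a = character(), anchor_genes_b = character())
  anchor_genes <- sort(unique(anchor_genes))
  syn <- data.table(gene_id = anchor_genes,
                    syntenic = anchor_genes %in% syn_genes)
  list(chains = chains[], syntenic = syn[])
}
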