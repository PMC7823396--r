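#' Simulation configuration
#'
#' Describes the synthetic allotetraploid world: an AABB tetraploid with
#' chromosomes A01-A10 and B01-B08 plus unplaced scaffolds, an A-genome
#' diploid progenitor with placed chromosomes, and a B-genome progenitor on
#' unanchored scaffolds.  The defaults ARE the published landscape of the
#' reference survey this package models: 493 RLK / 228 RLP tetraploid genes
#' (35 / 16 unplaced), 16 RLK + 7 RLP positional clusters holding 62 / 25
#' genes (6 / 6 tandem; one heterogeneous RLK cluster carrying a LysM
#' member), 471 / 110 duplication events (163/308 and 52/58 intra/inter),
#' 413 / 112 duplicated genes, 58 / 52 tandem-duplicated and 16 / 4
#' segmentally duplicated genes, and conservation totals 194/189 (RLK A/B)
#' and 24/65 (RLP) against progenitors retaining 214/227 and 27/72.
#'
#' @param rng_seed integer seed; placements and planted identities change
#'   with the seed, planted count totals never do.
#' @param tetra_counts per-class gene counts of the tetraploid as a
#'   `data.frame(class, A, B, U)` (`U` = unplaced).
#' @param prog_A_counts,prog_B_counts per-class counts for the progenitors
#'   (`data.frame(class, mapped, unplaced)`; the B progenitor is entirely
#'   scaffold-bound so only totals are used).
#' @param clusters planted cluster table: `family`, `chromosome`,
#'   `n_members`, `span_bp`, `tandem`, `n_lysm`.
#' @param dup per-family duplicate budgets (see defaults for the shape).
#' @param conservation per-family conserved counts on both sides of each
#'   subgenome/progenitor pairing.
#' @param species species tags.
#' @param n_chrom_A,n_chrom_B chromosome counts.
#' @param identity_dup_range percent identity range for planted
#'   relationships; `identity_background_max` bounds background noise hits.
#'   The two ranges must be disjoint in the noiseless regime.
#' @param identity_background_max see above.
#' @param coverage_planted_range coverage range for planted relationship
#'   hits.
#' @param n_background_hits noise rows added per hit table.
#' @param n_prescreen_decoys genes passing the prescreen without a receptor
#'   architecture; `n_architecture_decoys` genes with a receptor
#'   architecture that never pass the prescreen (both stay NON_RGA).
#' @param n_architecture_decoys see above.
#' @param slot_bp spacing between planted non-cluster gene loci (chosen so
#'   non-cluster genes can never chain under the 200 kb rule while adjacent
#'   loci stay well inside the 5 Mb tandem distance).
#' @param gene_len_bp,protein_len gene body length and protein length.
#' @return an `rga_sim_config` list.
#' @export
sim_config <- function(rng_seed = 1L,
                       tetra_counts = NULL,
                       prog_A_counts = NULL,
                       prog_B_counts = NULL,
                       clusters = NULL,
                       dup = NULL,
                       conservation = NULL,
                       species = c(tetra = "Bj_syn", prog_A = "Br_syn",
                                   prog_B = "Bn_syn"),
                       n_chrom_A = 10L, n_chrom_B = 8L,
                       identity_dup_range = c(75, 95),
                       identity_background_max = 40,
                       coverage_planted_range = c(90, 100),
                       n_background_hits = 250L,
                       n_prescreen_decoys = 20L,
                       n_architecture_decoys = 10L,
                       slot_bp = 250000L,
                       gene_len_bp = 2000L,
                       protein_len = 500L) {
  if (is.null(tetra_counts))
    tetra_counts <- data.table(
      class = c("LRR_RLK", "LYSM_RLK", "RLK_OTHER",
                "LRR_RLP", "LYSM_RLP", "NON_RGA"),
      A = c(231L, 5L, 0L, 94L, 1L, 40000L),
      B = c(219L, 3L, 0L, 116L, 1L, 39000L),
      U = c(34L, 1L, 0L, 16L, 0L, 709L))
  if (is.null(prog_A_counts))
    prog_A_counts <- data.table(
      class = c("LRR_RLK", "LYSM_RLK", "RLK_OTHER",
                "LRR_RLP", "LYSM_RLP", "NON_RGA"),
      mapped = c(292L, 3L, 0L, 63L, 2L, 45700L),
      unplaced = c(5L, 0L, 0L, 0L, 0L, 33L))
  if (is.null(prog_B_counts))
    prog_B_counts <- data.table(
      class = c("LRR_RLK", "LYSM_RLK", "RLK_OTHER",
                "LRR_RLP", "LYSM_RLP", "NON_RGA"),
      mapped = c(0L, 0L, 0L, 0L, 0L, 0L),
      unplaced = c(312L, 5L, 0L, 175L, 1L, 49333L))
  if (is.null(clusters))
    clusters <- rbindlist(list(
      data.table(family = "RLK",
                 chromosome = c("A03", "A06", "A01", "A02", "A04", "A05",
                                "A07", "A09", "B03", "B01", "B02", "B04",
                                "B05", "B06", "B07", "B08"),
                 n_members = c(3L, 3L, rep(4L, 6L), 4L, rep(4L, 7L)),
                 span_bp = c(29450, 120000, 112132, 112132, 112132, 112132,
                             112132, 112136, 293950, 112132, 112132,
                             112132, 112132, 112132, 112132, 112132),
                 tandem = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE,
                            FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                            FALSE, FALSE),
                 n_lysm = c(0L, 1L, rep(0L, 14L))),
      data.table(family = "RLP",
                 chromosome = c("A03", "A07", "A08", "B03", "B04", "B05",
                                "B06"),
                 n_members = c(3L, 4L, 3L, 4L, 4L, 3L, 4L),
                 span_bp = c(33380, 73380, 73380, 73380, 73380, 73380,
                             186320),
                 tandem = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
                 n_lysm = 0L)))
  if (is.null(dup))
    dup <- list(
      RLK = list(dup_genes = c(A = 209L, B = 204L),
                 tandem_genes = 58L,
                 tandem_extra_pairs = c(A = 8L, B = 9L),
                 segmental_chroms = c("A01", "A02", "A03", "A04",
                                      "B01", "B02", "B03", "B04"),
                 dispersed_pairs = c(A = 62L, B = 58L),
                 inter_pairs = 308L),
      RLP = list(dup_genes = c(A = 52L, B = 60L),
                 tandem_genes = 52L,
                 tandem_extra_pairs = c(A = 4L, B = 11L),
                 segmental_chroms = c("A05", "B05"),
                 dispersed_pairs = c(A = 10L, B = 9L),
                 inter_pairs = 58L))
  if (is.null(conservation))
    conservation <- list(
      RLK = list(tetra = c(A = 194L, B = 189L),
                 prog = c(A = 214L, B = 227L)),
      RLP = list(tetra = c(A = 24L, B = 65L),
                 prog = c(A = 27L, B = 72L)))
  cfg <- list(rng_seed = as.integer(rng_seed),
              tetra_counts = as.data.table(tetra_counts),
              prog_A_counts = as.data.table(prog_A_counts),
              prog_B_counts = as.data.table(prog_B_counts),
              clusters = as.data.table(clusters),
              dup = dup, conservation = conservation,
              species = species,
              n_chrom_A = as.integer(n_chrom_A),
              n_chrom_B = as.integer(n_chrom_B),
              identity_dup_range = identity_dup_range,
              identity_background_max = identity_background_max,
              coverage_planted_range = coverage_planted_range,
              n_background_hits = as.integer(n_background_hits),
              n_prescreen_decoys = as.integer(n_prescreen_decoys),
              n_architecture_decoys = as.integer(n_architecture_decoys),
              slot_bp = as.numeric(slot_bp),
              gene_len_bp = as.numeric(gene_len_bp),
              protein_len = as.integer(protein_len),
              cluster_gap_bp = 200000,
              tandem_max_bp = 5e6)
  if (identity_dup_range[1L] <= identity_background_max)
    stop("identity_dup_range must lie strictly above ",
         "identity_background_max (disjoint regimes)", call. = FALSE)
  structure(cfg, class = "rga_sim_config")
}

sim_chroms <- function(cfg, sg) {
  if (sg == "A") sprintf("A%02d", seq_len(cfg$n_chrom_A))
  else sprintf("B%02d", seq_len(cfg$n_chrom_B))
}

sim_evalue <- function(identity) pmin(pmax(10^(-(identity - 30)), 1e-180), 10)

# Build BLAST-14 shaped hit rows for planted or background gene pairs.
sim_hit_rows <- function(q, s, identity, qcov, scov, plen) {
  qspan <- pmax(1L, round(qcov / 100 * plen))
  sspan <- pmax(1L, round(scov / 100 * plen))
  aln <- pmax(qspan, sspan)
  data.table(
    query_id = q, subject_id = s,
    pct_identity = round(identity, 2),
    aln_length = aln,
    mismatches = pmax(0L, round((100 - identity) / 100 * aln)),
    gap_opens = 0L,
    q_start = 1L, q_end = qspan,
    s_start = 1L, s_end = sspan,
    evalue = sim_evalue(identity),
    bitscore = round(identity * aln / 50, 1),
    query_len = plen, subject_len = plen)
}

# Reciprocal (both BLAST directions) planted hits with fresh draws per row,
# as an all-vs-all search reports.
sim_planted_hits <- function(pairs, cfg) {
  if (nrow(pairs) == 0L)
    return(compute_hit_derived(sim_hit_rows(character(), character(),
                                            numeric(), numeric(), numeric(),
                                            cfg$protein_len)))
  lo <- cfg$identity_dup_range[1L]; hi <- cfg$identity_dup_range[2L]
  clo <- cfg$coverage_planted_range[1L]; chi <- cfg$coverage_planted_range[2L]
  n <- nrow(pairs)
  fwd <- sim_hit_rows(pairs$gene_a, pairs$gene_b,
                      runif(n, lo, hi), runif(n, clo, chi),
                      runif(n, clo, chi), cfg$protein_len)
  rev <- sim_hit_rows(pairs$gene_b, pairs$gene_a,
                      runif(n, lo, hi), runif(n, clo, chi),
                      runif(n, clo, chi), cfg$protein_len)
  compute_hit_derived(rbindlist(list(fwd, rev)))
}

sim_background_hits <- function(pool, forbidden_keys, n, cfg) {
  if (n == 0L || length(pool) < 2L)
    return(compute_hit_derived(sim_hit_rows(character(), character(),
                                            numeric(), numeric(), numeric(),
                                            cfg$protein_len)))
  q <- sample(pool, 3L * n, replace = TRUE)
  s <- sample(pool, 3L * n, replace = TRUE)
  ok <- q != s & !(paste(pmin(q, s), pmax(q, s), sep = "|") %in%
                     forbidden_keys)
  q <- head(q[ok], n); s <- head(s[ok], n)
  m <- length(q)
  compute_hit_derived(sim_hit_rows(
    q, s, runif(m, 20, cfg$identity_background_max),
    runif(m, 30, 100), runif(m, 30, 100), cfg$protein_len))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
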