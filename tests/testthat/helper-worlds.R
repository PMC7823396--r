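# Shared fixtures, built in code.

# Small simulated world: same machinery as the paper-scale fixture but a few
# hundred genes, so module tests stay fast.
tiny_sim_config <- function(rng_seed = 42L) {
  sim_config(
    rng_seed = rng_seed,
    tetra_counts = data.table::data.table(
      class = c("LRR_RLK", "LYSM_RLK", "RLK_OTHER",
                "LRR_RLP", "LYSM_RLP", "NON_RGA"),
      A = c(20L, 1L, 0L, 10L, 0L, 30L),
      B = c(18L, 1L, 0L, 10L, 0L, 30L),
      U = c(2L, 0L, 0L, 1L, 0L, 5L)),
    prog_A_counts = data.table::data.table(
      class = c("LRR_RLK", "LYSM_RLK", "RLK_OTHER",
                "LRR_RLP", "LYSM_RLP", "NON_RGA"),
      mapped = c(15L, 1L, 0L, 8L, 0L, 50L),
      unplaced = c(1L, 0L, 0L, 0L, 0L, 0L)),
    prog_B_counts = data.table::data.table(
      class = c("LRR_RLK", "LYSM_RLK", "RLK_OTHER",
                "LRR_RLP", "LYSM_RLP", "NON_RGA"),
      mapped = 0L,
      unplaced = c(16L, 1L, 0L, 9L, 0L, 60L)),
    clusters = data.table::data.table(
      family = c("RLK", "RLK", "RLP"),
      chromosome = c("A01", "B02", "A03"),
      n_members = c(3L, 4L, 3L),
      span_bp = c(40000, 150000, 50000),
      tandem = c(TRUE, FALSE, TRUE),
      n_lysm = 0L),
    dup = list(
      RLK = list(dup_genes = c(A = 10L, B = 8L),
                 tandem_genes = 7L,
                 tandem_extra_pairs = c(A = 1L, B = 1L),
                 segmental_chroms = c("A02", "B01"),
                 dispersed_pairs = c(A = 2L, B = 2L),
                 inter_pairs = 6L),
      RLP = list(dup_genes = c(A = 6L, B = 4L),
                 tandem_genes = 5L,
                 tandem_extra_pairs = c(A = 0L, B = 1L),
                 segmental_chroms = character(),
                 dispersed_pairs = c(A = 1L, B = 1L),
                 inter_pairs = 4L)),
    conservation = list(
      RLK = list(tetra = c(A = 12L, B = 12L), prog = c(A = 13L, B = 14L)),
      RLP = list(tetra = c(A = 5L, B = 5L), prog = c(A = 6L, B = 6L))),
    n_background_hits = 40L,
    n_prescreen_decoys = 5L,
    n_architecture_decoys = 3L)
}

.fixture_cache <- new.env(parent = emptyenv())

tiny_world <- function(rng_seed = 42L) {
  key <- paste0("tiny", rng_seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_world(tiny_sim_config(rng_seed))
  .fixture_cache[[key]]
}

paper_world <- function() {
  if (is.null(.fixture_cache$paper))
    .fixture_cache$paper <- paper_counts_fixture(rng_seed = 1L)
  .fixture_cache$paper
}

paper_bundle <- function() {
  if (is.null(.fixture_cache$paper_bundle))
    .fixture_cache$paper_bundle <-
      run_landscape_pipeline(paper_world(), analysis_config())
  .fixture_cache$paper_bundle
}

# Minimal hand-written gene-model table.
make_genes <- function(ids, chrom, start, species = "sp", end = start + 999,
                       strand = "+", cfg = analysis_config()) {
  data.table::data.table(
    gene_id = ids, species = species, chromosome = chrom,
    start = start, end = end, strand = strand,
    sub_genome = assign_subgenome(chrom, cfg))
}

# Minimal hit rows with chosen identity / coverage / evalue.
make_hits <- function(q, s, identity, qcov = 95, scov = 95,
                      evalue = 1e-60, plen = 500) {
  qspan <- pmax(1, round(qcov / 100 * plen))
  sspan <- pmax(1, round(scov / 100 * plen))
  dt <- data.table::data.table(
    query_id = q, subject_id = s, pct_identity = identity,
    aln_length = pmax(qspan, sspan), mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = qspan, s_start = 1L, s_end = sspan,
    evalue = evalue, bitscore = identity * 5,
    query_len = plen, subject_len = plen)
  rgascape:::compute_hit_derived(dt)
}
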