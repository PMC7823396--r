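# Domain/prescreen synthesis and world assembly ------------------------------

sim_signature_for <- function(domain_class) {
  reps <- list(LRR = c("LRR_1", "LRR_4", "LRR_8"),
               LYSM = "LysM", TM = "TMhelix",
               KINASE_STTK = c("Pkinase", "Pkinase_Tyr"),
               SIGNAL_PEPTIDE = "SignalP-noTM",
               OTHER = "ZnF_C2H2")
  vapply(domain_class, function(d) {
    r <- reps[[d]]
    r[[1L + (nchar(d) %% length(r))]]
  }, character(1L))
}

# Domain records implied by a truth class; decoy_arch genes get a full
# receptor architecture despite being NON_RGA (they never pass prescreen).
sim_build_domains <- function(genes, cfg, decoy_arch = character()) {
  rows <- list()
  add_gene <- function(id, classes) {
    n <- length(classes)
    p_start <- cumsum(c(1L, rep(60L, n - 1L)))
    rows[[length(rows) + 1L]] <<- data.table(
      gene_id = id, domain_class = classes,
      p_start = p_start, p_end = p_start + 55L,
      evalue = sim_evalue(runif(n, 60, 90)),
      source_tool = ifelse(classes %in% c("TM", "SIGNAL_PEPTIDE"),
                           "phobius", "interproscan"),
      signature = sim_signature_for(classes))
  }
  fam <- genes[class != "NON_RGA"]
  for (i in seq_len(nrow(fam))) {
    cl <- as.character(fam$class[i])
    base <- switch(cl,
      LRR_RLK = c(rep("LRR", 3L + i %% 5L), "TM", "KINASE_STTK"),
      LYSM_RLK = c(rep("LYSM", 1L + i %% 2L), "TM", "KINASE_STTK"),
      RLK_OTHER = c("TM", "KINASE_STTK"),
      LRR_RLP = c(rep("LRR", 3L + i %% 5L), "TM"),
      LYSM_RLP = c("LYSM", "TM"))
    if (i %% 2L) base <- c("SIGNAL_PEPTIDE", base)
    add_gene(fam$gene_id[i], base)
  }
  for (id in decoy_arch)
    add_gene(id, c("LRR", "LRR", "TM", "KINASE_STTK"))
  rbindlist(rows)
}

sim_build_prescreen <- function(genes, cfg, decoy_pass = character()) {
  rga <- genes[class != "NON_RGA"]$gene_id
  n <- length(rga)
  pass <- sim_hit_rows(rga, "RGAdb_REF0001",
                       runif(n, cfg$identity_dup_range[1L],
                             cfg$identity_dup_range[2L]),
                       runif(n, 80, 100), runif(n, 80, 100),
                       cfg$protein_len)
  rows <- list(pass)
  if (length(decoy_pass)) {
    k <- length(decoy_pass)
    rows[[2L]] <- sim_hit_rows(decoy_pass, "RGAdb_REF0001",
                               runif(k, 55, 65), runif(k, 50, 90),
                               runif(k, 50, 90), cfg$protein_len)
  }
  # sub-threshold noise: weak hits that must fail the E <= 1e-5 prescreen
  bg <- genes[class == "NON_RGA"]$gene_id
  nb <- min(50L, length(bg))
  if (nb > 0L) {
    weak <- sample(bg, nb)
    rows[[length(rows) + 1L]] <- sim_hit_rows(
      weak, "RGAdb_REF0001", runif(nb, 25, 33),
      runif(nb, 30, 90), runif(nb, 30, 90), cfg$protein_len)
  }
  compute_hit_derived(rbindlist(rows))
}

#' Simulate an allotetraploid world with planted ground truth
#'
#' Generates the tetraploid and both progenitor gene sets, domain tables,
#' prescreen hits, within-species all-vs-all hits and cross-species hit
#' tables, together with a `truth` component holding every planted
#' relationship.  Deterministic for a fixed `cfg$rng_seed`; planted count
#' totals never depend on the seed.  Ground-truth consistency (cluster
#' geometry, pair distances, budget closure) is checked before returning.
#'
#' @param cfg an [sim_config()].
#' @param out_dir optional directory; when given, [write_world()] is called.
#' @return an `rga_world` list: `species` (per-species `genes`, `domains`,
#'   `prescreen_hits`, `self_hits`), `cross_hits` (per progenitor),
#'   `pairing`, `tetraploid`, `truth`, `sim_config`.
#' @export
simulate_world <- function(cfg = sim_config(), out_dir = NULL) {
  set.seed(cfg$rng_seed)
  tet <- sim_build_tetraploid(cfg)
  progA <- sim_build_progenitor(cfg, "A")
  progB <- sim_build_progenitor(cfg, "B")

  dup_edges <- rbindlist(lapply(c("RLK", "RLP"), function(fam)
    sim_build_duplicates(tet, cfg, fam)))
  orth_edges <- rbindlist(list(
    sim_build_orthologs(tet, progA, cfg, "RLK", "A"),
    sim_build_orthologs(tet, progB, cfg, "RLK", "B"),
    sim_build_orthologs(tet, progA, cfg, "RLP", "A"),
    sim_build_orthologs(tet, progB, cfg, "RLP", "B")))

  dup_keys <- pair_key(dup_edges$gene_a, dup_edges$gene_b)
  self_hits <- rbindlist(list(
    sim_planted_hits(dup_edges, cfg),
    sim_background_hits(tet$genes$gene_id, dup_keys,
                        cfg$n_background_hits, cfg)))
  orth_keys <- pair_key(orth_edges$gene_a, orth_edges$gene_b)
  cross <- list()
  for (sg in c("A", "B")) {
    prog <- if (sg == "A") progA else progB
    e <- orth_edges[prog_species == prog$species[1L]]
    cross[[prog$species[1L]]] <- rbindlist(list(
      sim_planted_hits(e, cfg),
      sim_background_hits(c(tet$genes$gene_id, prog$gene_id), orth_keys,
                          cfg$n_background_hits, cfg)))
  }

  bg_pool <- tet$genes[class == "NON_RGA"]$gene_id
  decoy_pass <- sample(bg_pool, cfg$n_prescreen_decoys)
  decoy_arch <- sample(setdiff(bg_pool, decoy_pass),
                       cfg$n_architecture_decoys)

  species <- list()
  for (x in list(list(g = tet$genes, decoys = TRUE),
                 list(g = progA, decoys = FALSE),
                 list(g = progB, decoys = FALSE))) {
    g <- x$g
    sp <- g$species[1L]
    species[[sp]] <- list(
      genes = g[, .(gene_id, species, chromosome, start, end, strand,
                    sub_genome)],
      domains = sim_build_domains(
        g, cfg, if (x$decoys) decoy_arch else character()),
      prescreen_hits = sim_build_prescreen(
        g, cfg, if (x$decoys) decoy_pass else character()),
      self_hits = if (x$decoys) self_hits else
        compute_hit_derived(sim_hit_rows(character(), character(),
                                         numeric(), numeric(), numeric(),
                                         cfg$protein_len)))
  }

  truth_classes <- rbindlist(list(
    tet$genes[, .(species, gene_id, class, family)],
    progA[, .(species, gene_id, class, family)],
    progB[, .(species, gene_id, class, family)]))
  ledger <- rbindlist(lapply(c("RLK", "RLP"), function(fam)
    rbindlist(lapply(c("A", "B"), function(sg) {
      tt <- sum(tet$genes$family == fam & tet$genes$sub_genome == sg &
                  tet$genes$chromosome != CHROM_UNPLACED)
      prog <- if (sg == "A") progA else progB
      pt <- sum(prog$family == fam)
      ct <- cfg$conservation[[fam]]$tetra[[sg]]
      cp <- cfg$conservation[[fam]]$prog[[sg]]
      data.table(family = fam, sub_genome = sg,
                 prog_species = prog$species[1L],
                 tetra_total = tt, tetra_conserved = ct,
                 gained = tt - ct,
                 prog_total = pt, prog_conserved = cp, lost = pt - cp)
    }))))

  world <- structure(list(
    species = species,
    cross_hits = cross,
    tetraploid = cfg$species[["tetra"]],
    pairing = c(A = cfg$species[["prog_A"]], B = cfg$species[["prog_B"]]),
    truth = list(classes = truth_classes,
                 clusters = tet$clusters,
                 duplicates = dup_edges,
                 orthologs = orth_edges,
                 ledger = ledger),
    sim_config = cfg), class = "rga_world")
  validate_world(world)
  if (!is.null(out_dir)) write_world(world, out_dir)
  world
}

# Generation-time ground-truth consistency checks.
validate_world <- function(world) {
  cfg <- world$sim_config
  tet <- world$species[[world$tetraploid]]$genes
  truth <- world$truth
  lut_chr <- setNames(tet$chromosome, tet$gene_id)
  lut_start <- setNames(tet$start, tet$gene_id)

  # planted clusters obey the chaining rule with margin
  for (i in seq_len(nrow(truth$clusters))) {
    ids <- strsplit(truth$clusters$member_ids[i], ",")[[1L]]
    stopifnot(length(unique(lut_chr[ids])) == 1L)
    gaps <- diff(sort(lut_start[ids]))
    stopifnot(all(gaps <= 0.95 * cfg$cluster_gap_bp))
  }
  # planted pair geometry matches its type
  d <- truth$duplicates
  same <- lut_chr[d$gene_a] == lut_chr[d$gene_b]
  dist <- abs(lut_start[d$gene_a] - lut_start[d$gene_b])
  stopifnot(
    all(same[d$positional_type == "TANDEM"]),
    all(dist[d$positional_type == "TANDEM"] <= cfg$tandem_max_bp),
    all(same[d$positional_type == "SEGMENTAL"]),
    all(dist[d$positional_type == "SEGMENTAL"] > cfg$tandem_max_bp),
    all(!same[d$positional_type == "DISPERSED"]),
    !anyDuplicated(pair_key(d$gene_a, d$gene_b)))
  # budget closure per family
  lut_sg <- setNames(tet$sub_genome, tet$gene_id)
  for (fam in c("RLK", "RLP")) {
    df <- d[family == fam]
    spec <- cfg$dup[[fam]]
    tandem_genes <- unique(unlist(
      df[positional_type == "TANDEM", c(gene_a, gene_b)]))
    seg_genes <- unique(unlist(
      df[positional_type == "SEGMENTAL", c(gene_a, gene_b)]))
    for (sg in c("A", "B")) {
      dup_sg <- unique(c(df$gene_a, df$gene_b))
      dup_sg <- dup_sg[lut_sg[dup_sg] == sg]
      stopifnot(length(dup_sg) == spec$dup_genes[[sg]])
      stopifnot(sum(df$genome_scope == paste0("INTRA_", sg) &
                      df$positional_type == "DISPERSED") ==
                  spec$dispersed_pairs[[sg]])
    }
    stopifnot(
      sum(df$genome_scope == "INTER") == spec$inter_pairs,
      length(tandem_genes) == spec$tandem_genes,
      length(seg_genes) == 2L * length(spec$segmental_chroms))
  }
  # conservation ledger closure
  l <- truth$ledger
  stopifnot(all(l$tetra_conserved + l$gained == l$tetra_total),
            all(l$prog_conserved + l$lost == l$prog_total))
  invisible(world)
}

#' Degrade a simulated world for robustness testing
#'
#' Adds Gaussian jitter to the identity column of every similarity-hit table
#' (clamped to \[0, 100\]) and drops hit rows independently at the given
#' rate.  The ground truth is left untouched so recall/precision can be
#' scored against it.
#'
#' @param world an `rga_world`.
#' @param identity_jitter_sd standard deviation of the identity jitter.
#' @param dropout_rate row dropout probability in \[0, 1\].
#' @param rng_seed seed for the perturbation draws.
#' @return the degraded world.
#' @export
perturb_world <- function(world, identity_jitter_sd = 0, dropout_rate = 0,
                          rng_seed = 1L) {
  stopifnot(inherits(world, "rga_world"))
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]", call. = FALSE)
  if (identity_jitter_sd < 0)
    stop("identity_jitter_sd must be nonnegative", call. = FALSE)
  set.seed(rng_seed)
  degrade <- function(hits) {
    hits <- copy(as.data.table(hits))
    if (nrow(hits) == 0L) return(hits)
    if (identity_jitter_sd > 0)
      hits[, pct_identity := pmin(pmax(
        pct_identity + rnorm(.N, 0, identity_jitter_sd), 0), 100)]
    if (dropout_rate > 0)
      hits <- hits[runif(.N) >= dropout_rate]
    hits
  }
  for (sp in names(world$species)) {
    world$species[[sp]]$self_hits <- degrade(world$species[[sp]]$self_hits)
    world$species[[sp]]$prescreen_hits <-
      degrade(world$species[[sp]]$prescreen_hits)
  }
  for (nm in names(world$cross_hits))
    world$cross_hits[[nm]] <- degrade(world$cross_hits[[nm]])
  world
}

#' The paper-scale fixture world
#'
#' A world generated under the default [sim_config()], i.e. planted with the
#' reference survey's headline tallies, so summary output can be compared
#' against the printed percentages.
#'
#' @param rng_seed seed (totals are seed-invariant).
#' @return an `rga_world`.
#' @export
paper_counts_fixture <- function(rng_seed = 1L) {
  simulate_world(sim_config(rng_seed = rng_seed))
}

#' Write a simulated world to disk / read it back
#'
#' Emits, per species, a GFF3 gene-model file, a domain TSV, a prescreen hit
#' table and an all-vs-all self-hit table, plus one cross-species hit table
#' per progenitor and a `world.yaml` manifest.  `read_world()` reconstructs
#' the world (without ground truth) from such a directory.
#'
#' @param world an `rga_world`.
#' @param dir output directory (created).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(world$species)) {
    w <- world$species[[sp]]
    write_gene_models(w$genes, file.path(dir, paste0(sp, ".gff3")))
    write_domain_table(w$domains, file.path(dir, paste0(sp, ".domains.tsv")))
    write_similarity_hits(w$prescreen_hits,
                          file.path(dir, paste0(sp, ".prescreen.tsv")))
    write_similarity_hits(w$self_hits,
                          file.path(dir, paste0(sp, ".selfhits.tsv")))
  }
  for (nm in names(world$cross_hits))
    write_similarity_hits(world$cross_hits[[nm]],
                          file.path(dir, paste0(world$tetraploid, "-vs-",
                                                nm, ".hits.tsv")))
  yaml::write_yaml(list(tetraploid = world$tetraploid,
                        pairing = as.list(world$pairing)),
                   file.path(dir, "world.yaml"))
  invisible(dir)
}

#' @param cfg an [analysis_config()] used when re-reading gene models.
#' @rdname write_world
#' @export
read_world <- function(dir, cfg = analysis_config()) {
  manifest <- yaml::read_yaml(file.path(dir, "world.yaml"))
  pairing <- unlist(manifest$pairing)
  species <- list()
  for (sp in c(manifest$tetraploid, unname(pairing))) {
    fixed_sg <- if (sp == manifest$tetraploid) NULL else
      names(pairing)[pairing == sp]
    species[[sp]] <- list(
      genes = read_gene_models(file.path(dir, paste0(sp, ".gff3")), sp,
                               cfg, sub_genome = fixed_sg),
      domains = read_domain_table(file.path(dir,
                                            paste0(sp, ".domains.tsv"))),
      prescreen_hits = read_similarity_hits(
        file.path(dir, paste0(sp, ".prescreen.tsv"))),
      self_hits = read_similarity_hits(
        file.path(dir, paste0(sp, ".selfhits.tsv"))))
  }
  cross <- list()
  for (nm in unname(pairing))
    cross[[nm]] <- read_similarity_hits(
      file.path(dir, paste0(manifest$tetraploid, "-vs-", nm, ".hits.tsv")))
  structure(list(species = species, cross_hits = cross,
                 tetraploid = manifest$tetraploid, pairing = pairing,
                 truth = NULL, sim_config = NULL), class = "rga_world")
}
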