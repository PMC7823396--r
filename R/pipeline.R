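#' Run the full landscape analysis on a world
#'
#' End-to-end orchestration: classifies every species, tabulates the
#' chromosomal distribution, detects and labels clusters, calls and types
#' duplicates and paralogs, calls orthologs against both progenitors,
#' builds the conservation ledger and synteny chains, and assembles the
#' family table and denominator audit.
#'
#' @param world an `rga_world` from [simulate_world()] or [read_world()].
#' @param cfg an [analysis_config()].
#' @return an `rga_bundle` list (see components in the source); pass it to
#'   [write_report_tables()] and [build_denominator_audit()].
#' @export
run_landscape_pipeline <- function(world, cfg = analysis_config()) {
  stopifnot(inherits(world, "rga_world"))
  tet_tag <- world$tetraploid

  classifications <- lapply(world$species, function(w)
    classify_proteome(w$genes, w$domains, w$prescreen_hits, cfg))
  tet_cl <- classifications[[tet_tag]]
  tet <- world$species[[tet_tag]]

  distribution <- distribution_table(tet_cl, cfg)
  clusters <- detect_clusters_all(tet_cl, cfg)
  clusters <- label_homogeneity(clusters, tet_cl)

  fam_ids <- split(tet_cl$gene_id, tet_cl$family)
  self <- tet$self_hits
  duplicates <- list(); dup_summary <- list()
  paralogs <- list()
  for (fam in c("RLK", "RLP")) {
    ids <- fam_ids[[fam]]
    if (is.null(ids)) ids <- character()
    hits_fam <- self[query_id %in% ids & subject_id %in% ids]
    pairs <- type_pairs(call_duplicates(hits_fam, cfg), tet$genes, cfg)
    pairs[, family := fam]
    clusters_fam <- label_tandem_clusters(clusters[family == fam], pairs)
    clusters[family == fam, tandem := clusters_fam$tandem]
    ds <- duplication_summary(pairs, tet_cl, fam, cfg)
    ds$tandem_cluster_share <- format_percent(sum(clusters_fam$tandem),
                                              nrow(clusters_fam))
    duplicates[[fam]] <- pairs
    dup_summary[[fam]] <- ds
    pl <- call_paralogs(hits_fam, tet$genes, cfg)
    if (nrow(pl)) pl[, family := fam]
    paralogs[[fam]] <- pl
  }
  duplicates <- rbindlist(duplicates)
  paralogs <- rbindlist(paralogs, fill = TRUE)

  cluster_stats <- list(
    RLK = cluster_statistics(clusters[family == "RLK"], tet_cl, "RLK", cfg),
    RLP = cluster_statistics(clusters[family == "RLP"], tet_cl, "RLP", cfg))

  # orthology per progenitor, per family
  orthologs <- list()
  for (prog_sp in unname(world$pairing)) {
    hits <- world$cross_hits[[prog_sp]]
    prog <- world$species[[prog_sp]]
    prog_cl <- classifications[[prog_sp]]
    for (fam in c("RLK", "RLP")) {
      t_ids <- tet_cl[tet_cl$family == fam]$gene_id
      p_ids <- prog_cl[prog_cl$family == fam]$gene_id
      hits_fam <- hits[(query_id %in% t_ids & subject_id %in% p_ids) |
                         (query_id %in% p_ids & subject_id %in% t_ids)]
      oo <- call_orthologs(hits_fam, tet$genes, prog$genes, cfg)
      if (nrow(oo)) oo[, family := fam]
      orthologs[[paste(prog_sp, fam)]] <- oo
    }
  }
  orthologs <- rbindlist(orthologs, fill = TRUE)

  prog_cls <- rbindlist(classifications[unname(world$pairing)])
  conservation <- conservation_ledger(tet_cl, prog_cls, orthologs,
                                      world$pairing, cfg)

  progA_sp <- world$pairing[["A"]]
  synteny <- synteny_chains(orthologs[species_b == progA_sp],
                            tet$genes, world$species[[progA_sp]]$genes,
                            cfg)

  bundle <- structure(list(
    classifications = classifications,
    family_table = build_family_table(classifications),
    distribution = distribution,
    clusters = clusters,
    cluster_stats = cluster_stats,
    duplicates = duplicates,
    dup_summary = dup_summary,
    paralogs = paralogs,
    orthologs = orthologs,
    conservation = conservation,
    synteny = synteny,
    cfg = cfg), class = "rga_bundle")
  bundle$audit <- build_denominator_audit(bundle)
  bundle
}
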