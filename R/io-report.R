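#' Write the report tables of a result bundle
#'
#' Emits six deterministic, byte-stable TSVs: `family_counts.tsv`,
#' `per_chromosome.tsv`, `clusters.tsv`, `duplicates.tsv`, `orthologs.tsv`
#' and `conservation.tsv`.  An empty bundle yields header-only files;
#' writing the same bundle twice yields byte-identical output.
#'
#' @param bundle an `rga_bundle` from [run_landscape_pipeline()] or
#'   [empty_bundle()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
write_report_tables <- function(bundle, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  emp <- empty_bundle()
  grab <- function(x, fallback) if (is.null(x) || !nrow(x)) fallback else x
  tabs <- list(
    family_counts = grab(bundle$family_table, emp$family_table),
    per_chromosome = grab(bundle$distribution$per_chromosome,
                          emp$distribution$per_chromosome),
    clusters = grab(bundle$clusters, emp$clusters),
    duplicates = grab(bundle$duplicates, emp$duplicates),
    orthologs = grab(bundle$orthologs, emp$orthologs),
    conservation = grab(bundle$conservation, emp$conservation))
  paths <- character()
  for (nm in names(tabs)) {
    tt <- copy(as.data.table(tabs[[nm]]))
    if ("class" %in% names(tt)) tt[, class := as.character(class)]
    setorderv(tt, names(tt)[vapply(tt, is.atomic, logical(1L))])
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    fwrite(tt, p, sep = "\t", eol = "\n")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' An empty result bundle (header-only report tables)
#'
#' @return an `rga_bundle` whose tables have the canonical columns and zero
#'   rows.
#' @export
empty_bundle <- function() {
  structure(list(
    family_table = data.table(species = character(),
                              row_class = character(), count = integer(),
                              total_genes = integer(), pct = character()),
    distribution = list(
      per_chromosome = data.table(chromosome = character(),
                                  class = character(), n = integer()),
      unassigned = data.table(class = character(), n = integer()),
      mapped_summary = data.table(family = character(), total = integer(),
                                  mapped = integer(), unplaced = integer(),
                                  mapped_pct = character())),
    clusters = data.table(cluster_id = character(),
                          chromosome = character(), n_members = integer(),
                          first_start = numeric(), last_end = numeric(),
                          span_bp = numeric(), member_ids = character(),
                          family = character(), homogeneous = logical(),
                          tandem = logical()),
    cluster_stats = list(),
    duplicates = data.table(gene_a = character(), gene_b = character(),
                            pct_identity = numeric(),
                            query_cov = numeric(), subject_cov = numeric(),
                            evalue = numeric(), bitscore = numeric(),
                            positional_type = character(),
                            genome_scope = character(),
                            distance_bp = numeric(), family = character()),
    dup_summary = list(),
    orthologs = data.table(gene_a = character(), species_a = character(),
                           gene_b = character(), species_b = character(),
                           pct_identity = numeric(), query_cov = numeric(),
                           subject_cov = numeric(), evalue = numeric(),
                           family = character()),
    conservation = data.table(family = character(), sub_genome = character(),
                              prog_species = character(),
                              tetra_total = integer(),
                              tetra_conserved = integer(),
                              tetra_conserved_pct = character(),
                              gained = integer(), prog_total = integer(),
                              prog_conserved = integer(),
                              prog_conserved_pct = character(),
                              lost = integer()),
    synteny = NULL,
    cfg = NULL), class = "rga_bundle")
}
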