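#' Map chromosome names to subgenome labels
#'
#' @param chromosome character vector of chromosome names.
#' @param cfg an [analysis_config()]; the `subgenome_regex` patterns decide.
#' @return character vector of `"A"`, `"B"` or `"NONE"`.
#' @export
assign_subgenome <- function(chromosome, cfg = analysis_config()) {
  out <- rep("NONE", length(chromosome))
  out[grepl(cfg$subgenome_regex[["A"]], chromosome)] <- "A"
  out[grepl(cfg$subgenome_regex[["B"]], chromosome)] <- "B"
  out
}

#' Chromosomal distribution of classified family genes
#'
#' @param classification table from [classify_proteome()].
#' @param cfg an [analysis_config()].
#' @return list with `per_chromosome` (counts per chromosome x class for RGA
#'   classes, mapped genes only), `unassigned` (per-class tallies of
#'   unplaced genes) and `mapped_summary` (per family: total, mapped,
#'   unplaced, mapped percentage).
#' @export
distribution_table <- function(classification, cfg = analysis_config()) {
  cl <- as.data.table(classification)[class != "NON_RGA"]
  per_chrom <- cl[chromosome != CHROM_UNPLACED,
                  .(n = .N), by = .(chromosome, class)]
  setorder(per_chrom, chromosome, class)
  unassigned <- cl[chromosome == CHROM_UNPLACED, .(n = .N), by = class]
  setorder(unassigned, class)
  ms <- cl[, .(total = .N,
               mapped = sum(chromosome != CHROM_UNPLACED),
               unplaced = sum(chromosome == CHROM_UNPLACED)),
           by = .(family)]
  setorder(ms, family)
  ms[, mapped_pct := paste0(pct_string(mapped, total), "%"),
     by = seq_len(nrow(ms))]
  stopifnot(all(ms$mapped + ms$unplaced == ms$total))
  list(per_chromosome = per_chrom[], unassigned = unassigned[],
       mapped_summary = ms[])
}

#' Detect positional gene clusters on one chromosome
#'
#' Maximal chains of family genes in which each consecutive gene lies within
#' `cluster_max_gap_bp` of the previous one (gap measured start-to-start by
#' default); chains with at least `cluster_min_genes` members become
#' clusters.  The chaining reading (not total span) is deliberate: reported
#' cluster spans can exceed the gap threshold.
#'
#' @param genes gene models of ONE family on ONE chromosome, sorted by
#'   `start` (unsorted input is a hard error).
#' @param cfg an [analysis_config()].
#' @param cluster_prefix prefix used to build `cluster_id`s.
#' @return `data.table`: `cluster_id`, `chromosome`, `n_members`,
#'   `first_start`, `last_end`, `span_bp`, `member_ids` (comma-joined, in
#'   start order).
#' @export
detect_clusters <- function(genes, cfg = analysis_config(),
                            cluster_prefix = "CL") {
  genes <- as.data.table(genes)
  empty <- data.table(cluster_id = character(), chromosome = character(),
                      n_members = integer(), first_start = numeric(),
                      last_end = numeric(), span_bp = numeric(),
                      member_ids = character())
  if (nrow(genes) == 0L) return(empty)
  if (length(unique(genes$chromosome)) != 1L)
    stop("detect_clusters expects genes from a single chromosome",
         call. = FALSE)
  if (is.unsorted(genes$start))
    stop("detect_clusters expects genes sorted by start", call. = FALSE)
  gap <- if (cfg$gap_anchor == "start-start")
    diff(genes$start)
  else
    genes$start[-1L] - genes$end[-nrow(genes)]
  chain <- cumsum(c(0L, as.integer(gap > cfg$cluster_max_gap_bp)))
  genes[, slot := chain]
  cl <- genes[, .(
    chromosome = chromosome[1L],
    n_members = .N,
    first_start = start[1L],
    last_end = end[.N],
    member_ids = paste(gene_id, collapse = ",")
  ), by = slot][n_members >= cfg$cluster_min_genes]
  if (nrow(cl) == 0L) return(empty)
  cl[, span_bp := last_end - first_start]
  cl[, cluster_id := sprintf("%s_%s_%02d", cluster_prefix, chromosome,
                             seq_len(.N))]
  cl[, slot := NULL]
  setcolorder(cl, c("cluster_id", "chromosome", "n_members",
                    "first_start", "last_end", "span_bp", "member_ids"))
  cl[]
}

#' Detect clusters genome-wide, per family
#'
#' Runs [detect_clusters()] separately for the RLK and RLP families on every
#' named chromosome (unplaced genes cannot cluster).
#'
#' @param classification table from [classify_proteome()] (carries positions).
#' @param cfg an [analysis_config()].
#' @return cluster `data.table` with an extra `family` column.
#' @export
detect_clusters_all <- function(classification, cfg = analysis_config()) {
  cl <- as.data.table(classification)
  out <- list()
  for (fam in c("RLK", "RLP")) {
    g <- cl[family == fam & chromosome != CHROM_UNPLACED]
    setorder(g, chromosome, start, gene_id)
    for (ch in unique(g$chromosome)) {
      res <- detect_clusters(g[chromosome == ch], cfg,
                             cluster_prefix = fam)
      if (nrow(res)) {
        res[, family := fam]
        out[[length(out) + 1L]] <- res
      }
    }
  }
  if (!length(out))
    return(data.table(cluster_id = character(), chromosome = character(),
                      n_members = integer(), first_start = numeric(),
                      last_end = numeric(), span_bp = numeric(),
                      member_ids = character(), family = character()))
  res <- rbindlist(out)
  setorder(res, family, chromosome, first_start)
  res[]
}

#' Summary statistics of one family's clusters
#'
#' Spans are reported in kb with two decimals (exact half-up rounding).
#'
#' @param clusters clusters of one family ([detect_clusters_all()] subset).
#' @param classification optional classification table; when given, the
#'   clustered-gene share of the family's mapped genes is included.
#' @param family family name used with `classification`.
#' @param cfg an [analysis_config()].
#' @return list: `n_clusters`, `n_genes`, `span_kb_min`, `span_kb_max`,
#'   `span_kb_mean`, `by_subgenome` (mean member count per subgenome) and
#'   optionally `clustered_share` (a `percent_cell`).
#' @export
cluster_statistics <- function(clusters, classification = NULL,
                               family = NULL, cfg = analysis_config()) {
  clusters <- as.data.table(clusters)
  if (nrow(clusters) == 0L) {
    out <- list(n_clusters = 0L, n_genes = 0L, span_kb_min = 0,
                span_kb_max = 0, span_kb_mean = 0,
                by_subgenome = data.table(sub_genome = character(),
                                          n_clusters = integer(),
                                          mean_members = numeric()))
  } else {
    sg <- assign_subgenome(clusters$chromosome, cfg)
    by_sg <- data.table(sub_genome = sg, n_members = clusters$n_members)[
      , .(n_clusters = .N, mean_members = mean(n_members)),
      by = sub_genome]
    setorder(by_sg, sub_genome)
    out <- list(
      n_clusters = nrow(clusters),
      n_genes = sum(clusters$n_members),
      span_kb_min = kb_value(min(clusters$span_bp)),
      span_kb_max = kb_value(max(clusters$span_bp)),
      span_kb_mean = kb_value(mean(clusters$span_bp)),
      by_subgenome = by_sg[]
    )
  }
  if (!is.null(classification) && !is.null(family)) {
    cl <- as.data.table(classification)
    n_mapped <- sum(cl$family == family & cl$chromosome != CHROM_UNPLACED)
    out$clustered_share <- format_percent(out$n_genes, n_mapped)
  }
  out
}

#' Label cluster homogeneity
#'
#' A cluster is homogeneous when all its members share one subfamily class
#' (e.g. all LRR-RLK); mixing LysM and LRR members of the same family makes
#' it heterogeneous.
#'
#' @param clusters cluster table.
#' @param classification classification table supplying member classes.
#' @return the cluster table with a logical `homogeneous` column.
#' @export
label_homogeneity <- function(clusters, classification) {
  clusters <- copy(as.data.table(clusters))
  cl <- as.data.table(classification)
  lut <- setNames(as.character(cl$class), cl$gene_id)
  clusters[, homogeneous := vapply(member_ids, function(m) {
    cls <- lut[strsplit(m, ",", fixed = TRUE)[[1L]]]
    length(unique(cls)) == 1L
  }, logical(1L))]
  clusters[]
}
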