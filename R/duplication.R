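#' Call duplicate gene pairs from all-vs-all similarity hits
#'
#' A pair qualifies when some hit between the two genes has identity and
#' BOTH coverages at or above the thresholds (symmetric coverage is the
#' stricter reading of "both the coverage and identity").  Reciprocal hits
#' collapse to one unordered pair (`gene_a < gene_b`); the best hit (lowest
#' E-value, then highest bitscore) is kept as evidence.
#'
#' @param hits similarity hits within one species and one gene family;
#'   self-hits are dropped.
#' @param cfg an [analysis_config()].
#' @return `data.table`: `gene_a`, `gene_b`, `pct_identity`, `query_cov`,
#'   `subject_cov`, `evalue`, `bitscore`, sorted by pair.
#' @export
call_duplicates <- function(hits, cfg = analysis_config()) {
  hits <- as.data.table(hits)
  empty <- data.table(gene_a = character(), gene_b = character(),
                      pct_identity = numeric(), query_cov = numeric(),
                      subject_cov = numeric(), evalue = numeric(),
                      bitscore = numeric())
  if (nrow(hits) == 0L) return(empty)
  ok <- hits[!self_hit &
               pass_min(pct_identity, cfg$dup_identity_min, cfg) &
               pass_min(query_cov, cfg$dup_coverage_min, cfg) &
               pass_min(subject_cov, cfg$dup_coverage_min, cfg)]
  if (nrow(ok) == 0L) return(empty)
  ok[, gene_a := pmin(query_id, subject_id)]
  ok[, gene_b := pmax(query_id, subject_id)]
  setorder(ok, gene_a, gene_b, evalue, -bitscore)
  best <- ok[, .SD[1L], by = .(gene_a, gene_b)]
  out <- best[, .(gene_a, gene_b, pct_identity, query_cov, subject_cov,
                  evalue, bitscore)]
  setorder(out, gene_a, gene_b)
  out[]
}

#' Type duplicate pairs positionally and by genome scope
#'
#' Same chromosome within `tandem_max_distance_bp` (start-to-start,
#' inclusive) is TANDEM; same chromosome beyond it is SEGMENTAL; different
#' chromosomes (or any unplaced gene) is DISPERSED.  Scope is INTRA_A /
#' INTRA_B when both genes share a subgenome, INTER when one is in A and the
#' other in B, UNKNOWN when either gene lacks a subgenome label.
#'
#' @param pairs output of [call_duplicates()].
#' @param genes gene models supplying positions and subgenomes.
#' @param cfg an [analysis_config()].
#' @return `pairs` with `positional_type`, `genome_scope` and `distance_bp`
#'   columns.
#' @export
type_pairs <- function(pairs, genes, cfg = analysis_config()) {
  pairs <- copy(as.data.table(pairs))
  if (nrow(pairs) == 0L) {
    pairs[, `:=`(positional_type = character(), genome_scope = character(),
                 distance_bp = numeric())]
    return(pairs[])
  }
  g <- as.data.table(genes)
  lut_chr <- setNames(g$chromosome, g$gene_id)
  lut_start <- setNames(g$start, g$gene_id)
  lut_sg <- setNames(g$sub_genome, g$gene_id)
  ca <- lut_chr[pairs$gene_a]; cb <- lut_chr[pairs$gene_b]
  sa <- lut_start[pairs$gene_a]; sb <- lut_start[pairs$gene_b]
  ga <- lut_sg[pairs$gene_a]; gb <- lut_sg[pairs$gene_b]
  same_chr <- !is.na(ca) & !is.na(cb) & ca == cb &
    ca != CHROM_UNPLACED
  dist <- ifelse(same_chr, abs(sa - sb), NA_real_)
  ptype <- ifelse(same_chr,
                  ifelse(dist <= cfg$tandem_max_distance_bp,
                         "TANDEM", "SEGMENTAL"),
                  "DISPERSED")
  scope <- rep("UNKNOWN", nrow(pairs))
  scope[ga == "A" & gb == "A"] <- "INTRA_A"
  scope[ga == "B" & gb == "B"] <- "INTRA_B"
  scope[(ga == "A" & gb == "B") | (ga == "B" & gb == "A")] <- "INTER"
  pairs[, `:=`(positional_type = ptype, genome_scope = scope,
               distance_bp = dist)]
  pairs[]
}

#' Summarise duplication events for one family
#'
#' Event counting is pairwise (each unordered passing pair is one event, no
#' transitive closure); a gene is "duplicated" when it appears in at least
#' one pair, "tandem-duplicated" when it appears in at least one TANDEM
#' pair.  Scope tallies partition the events.
#'
#' @param typed_pairs typed pairs from [type_pairs()] for one family.
#' @param classification classification table (for mapped-gene denominators).
#' @param family `"RLK"` or `"RLP"`.
#' @param cfg an [analysis_config()].
#' @return list of counts, percent cells and scope tallies.
#' @export
duplication_summary <- function(typed_pairs, classification, family,
                                cfg = analysis_config()) {
  tp <- as.data.table(typed_pairs)
  cl <- as.data.table(classification)
  fam <- family
  mapped <- cl[cl$family == fam & cl$chromosome != CHROM_UNPLACED]
  dup_genes <- sort(unique(c(tp$gene_a, tp$gene_b)))
  tandem_genes <- sort(unique(unlist(
    tp[positional_type == "TANDEM", c(gene_a, gene_b)])))
  seg_genes <- sort(unique(unlist(
    tp[positional_type == "SEGMENTAL", c(gene_a, gene_b)])))
  scopes <- c("INTRA_A", "INTRA_B", "INTER", "UNKNOWN")
  by_scope <- setNames(integer(4L), scopes)
  if (nrow(tp)) {
    tab <- table(factor(tp$genome_scope, levels = scopes))
    by_scope[names(tab)] <- as.integer(tab)
  }
  stopifnot(sum(by_scope) == nrow(tp))
  sg_lut <- setNames(mapped$sub_genome, mapped$gene_id)
  dup_by_sg <- table(factor(sg_lut[dup_genes], levels = c("A", "B")))
  list(
    family = fam,
    n_events = nrow(tp),
    n_duplicated_genes = length(dup_genes),
    duplicated_genes = dup_genes,
    duplicated_share = format_percent(length(dup_genes), nrow(mapped)),
    n_tandem_genes = length(tandem_genes),
    tandem_share = format_percent(length(tandem_genes),
                                  length(dup_genes)),
    n_segmental_genes = length(seg_genes),
    segmental_share = format_percent(length(seg_genes), length(dup_genes)),
    events_by_scope = by_scope,
    duplicated_by_subgenome = c(A = as.integer(dup_by_sg[["A"]]),
                                B = as.integer(dup_by_sg[["B"]]))
  )
}

#' Call within-genome paralog pairs
#'
#' Applies only the paralog E-value rule (no identity/coverage thresholds;
#' duplicates are the stricter, separate call): pairs of genes at distinct
#' genomic positions with some hit at `evalue <= paralog_evalue_max`.
#'
#' @param hits within-species similarity hits.
#' @param genes gene models (to verify the two positions are distinct).
#' @param cfg an [analysis_config()].
#' @return `data.table` of unordered pairs: `gene_a`, `gene_b`, `evalue`.
#' @export
call_paralogs <- function(hits, genes, cfg = analysis_config()) {
  hits <- as.data.table(hits)
  empty <- data.table(gene_a = character(), gene_b = character(),
                      evalue = numeric())
  if (nrow(hits) == 0L) return(empty)
  ok <- hits[!self_hit & evalue <= cfg$paralog_evalue_max]
  if (nrow(ok) == 0L) return(empty)
  g <- as.data.table(genes)
  lut_chr <- setNames(g$chromosome, g$gene_id)
  lut_start <- setNames(g$start, g$gene_id)
  same_locus <- !is.na(lut_chr[ok$query_id]) &
    lut_chr[ok$query_id] == lut_chr[ok$subject_id] &
    lut_start[ok$query_id] == lut_start[ok$subject_id]
  ok <- ok[!same_locus]
  if (nrow(ok) == 0L) return(empty)
  ok[, gene_a := pmin(query_id, subject_id)]
  ok[, gene_b := pmax(query_id, subject_id)]
  setorder(ok, gene_a, gene_b, evalue)
  out <- ok[, .(evalue = evalue[1L]), by = .(gene_a, gene_b)]
  setorder(out, gene_a, gene_b)
  out[]
}

#' Flag tandem clusters
#'
#' A cluster is a tandem cluster when EVERY consecutive member pair (in
#' start order) is a TANDEM duplicate pair.
#'
#' @param clusters cluster table (one family).
#' @param typed_pairs typed duplicate pairs of the same family.
#' @return the cluster table with a logical `tandem` column.
#' @export
label_tandem_clusters <- function(clusters, typed_pairs) {
  clusters <- copy(as.data.table(clusters))
  tp <- as.data.table(typed_pairs)
  tkeys <- character()
  if (nrow(tp))
    tkeys <- tp[positional_type == "TANDEM",
                paste(gene_a, gene_b, sep = "|")]
  clusters[, tandem := vapply(member_ids, function(m) {
    ids <- strsplit(m, ",", fixed = TRUE)[[1L]]
    a <- pmin(ids[-length(ids)], ids[-1L])
    b <- pmax(ids[-length(ids)], ids[-1L])
    all(paste(a, b, sep = "|") %in% tkeys)
  }, logical(1L))]
  clusters[]
}
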