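#' Analysis configuration
#'
#' Collects every numeric threshold used by the pipeline.  Defaults follow the
#' standard criteria for resistance-gene-analogue surveys: BLASTp prescreen at
#' E <= 1e-5; duplicate calling at >= 70% identity and >= 70% coverage of both
#' sequences; paralogs at E <= 1e-20; orthologs at E < 1e-45 with >= 70%
#' identity and coverage; gene clusters of >= 3 family genes chained within
#' 200 kb; tandem duplicates within 5 Mb on one chromosome.
#'
#' @param prescreen_evalue_max E-value ceiling for the reference-RGA prescreen.
#' @param dup_identity_min,dup_coverage_min percent thresholds for duplicate
#'   pair calling (applied to identity and to BOTH query and subject coverage).
#' @param paralog_evalue_max E-value ceiling for within-genome paralog calling.
#' @param ortholog_evalue_max strict E-value bound for ortholog calling
#'   (a hit qualifies when `evalue < ortholog_evalue_max`).
#' @param ortholog_similarity_min,ortholog_coverage_min percent thresholds for
#'   ortholog calling.
#' @param cluster_min_genes minimum genes in a positional cluster.
#' @param cluster_max_gap_bp maximum distance between consecutive cluster
#'   members (bp).
#' @param tandem_max_distance_bp same-chromosome distance at or below which a
#'   duplicate pair is tandem; beyond it, segmental.
#' @param synteny_min_chain minimum anchors for a reported synteny chain.
#' @param rng_seed integer seed recorded for downstream use.
#' @param domain_evalue_max per-domain-record E-value ceiling when building
#'   architectures (default 1.0: trust the annotator's own reporting cutoff).
#' @param ectodomain_priority which ectodomain wins when a gene carries both
#'   LysM and LRR records: `"LYSM"` (default) or `"LRR"`.
#' @param strict_gt if `TRUE`, "over 70%" thresholds are applied as strict
#'   `>` instead of the default `>=`.
#' @param gap_anchor how the cluster gap is measured: `"start-start"`
#'   (default) or `"end-start"`.
#' @param subgenome_regex named character vector of regular expressions mapping
#'   chromosome names to subgenome labels.
#' @param similarity_metric which hit column plays the role of "similarity"
#'   for orthologs; only `"identity"` is available for plain tabular input.
#' @param bbh if `TRUE`, ortholog calling keeps only best-bidirectional pairs.
#'
#' @return an object of class `rga_config` (a validated list).
#' @export
analysis_config <- function(prescreen_evalue_max = 1e-5,
                            dup_identity_min = 70,
                            dup_coverage_min = 70,
                            paralog_evalue_max = 1e-20,
                            ortholog_evalue_max = 1e-45,
                            ortholog_similarity_min = 70,
                            ortholog_coverage_min = 70,
                            cluster_min_genes = 3L,
                            cluster_max_gap_bp = 200000L,
                            tandem_max_distance_bp = 5000000L,
                            synteny_min_chain = 3L,
                            rng_seed = 1L,
                            domain_evalue_max = 1.0,
                            ectodomain_priority = c("LYSM", "LRR"),
                            strict_gt = FALSE,
                            gap_anchor = c("start-start", "end-start"),
                            subgenome_regex = c(A = "^A(0[1-9]|10)$",
                                                B = "^B0[1-8]$"),
                            similarity_metric = "identity",
                            bbh = FALSE) {
  cfg <- list(
    prescreen_evalue_max = prescreen_evalue_max,
    dup_identity_min = dup_identity_min,
    dup_coverage_min = dup_coverage_min,
    paralog_evalue_max = paralog_evalue_max,
    ortholog_evalue_max = ortholog_evalue_max,
    ortholog_similarity_min = ortholog_similarity_min,
    ortholog_coverage_min = ortholog_coverage_min,
    cluster_min_genes = as.integer(cluster_min_genes),
    cluster_max_gap_bp = as.numeric(cluster_max_gap_bp),
    tandem_max_distance_bp = as.numeric(tandem_max_distance_bp),
    synteny_min_chain = as.integer(synteny_min_chain),
    rng_seed = as.integer(rng_seed),
    domain_evalue_max = domain_evalue_max,
    ectodomain_priority = match.arg(ectodomain_priority),
    strict_gt = isTRUE(strict_gt),
    gap_anchor = match.arg(gap_anchor),
    subgenome_regex = subgenome_regex,
    similarity_metric = similarity_metric,
    bbh = isTRUE(bbh)
  )
  validate_config(cfg)
  structure(cfg, class = "rga_config")
}

validate_config <- function(cfg) {
  num <- c("prescreen_evalue_max", "dup_identity_min", "dup_coverage_min",
           "paralog_evalue_max", "ortholog_evalue_max",
           "ortholog_similarity_min", "ortholog_coverage_min",
           "cluster_min_genes", "cluster_max_gap_bp",
           "tandem_max_distance_bp", "synteny_min_chain",
           "domain_evalue_max")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("config field '", f, "' must be a single positive number",
           call. = FALSE)
  }
  pct <- c("dup_identity_min", "dup_coverage_min",
           "ortholog_similarity_min", "ortholog_coverage_min")
  for (f in pct) {
    if (cfg[[f]] > 100)
      stop("config field '", f, "' is a percentage and must be <= 100",
           call. = FALSE)
  }
  if (!all(c("A", "B") %in% names(cfg$subgenome_regex)))
    stop("subgenome_regex must provide patterns named 'A' and 'B'",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.rga_config <- function(x, ...) {
  cat("<rga_config>\n")
  for (f in setdiff(names(x), "subgenome_regex"))
    cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  cat(sprintf("  %-24s A: %s   B: %s\n", "subgenome_regex",
              x$subgenome_regex[["A"]], x$subgenome_regex[["B"]]))
  invisible(x)
}

#' Read / write an analysis configuration as YAML
#'
#' Only fields present in the file override the defaults of
#' [analysis_config()]; unknown fields are an error.
#'
#' @param path YAML file path.
#' @return `read_config` returns an `rga_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$subgenome_regex))
    raw$subgenome_regex <- unlist(raw$subgenome_regex)
  do.call(analysis_config, raw)
}

#' @param cfg an `rga_config`.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "rga_config"))
  x <- unclass(cfg)
  x$subgenome_regex <- as.list(x$subgenome_regex)
  yaml::write_yaml(x, path)
  invisible(path)
}

# Threshold comparators honouring the strict_gt switch.
pass_min <- function(x, thr, cfg) if (cfg$strict_gt) x > thr else x >= thr
pass_max <- function(x, thr, cfg) if (cfg$strict_gt) x < thr else x <= thr
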