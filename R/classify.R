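#' Prescreen genes against a reference RGA database
#'
#' A gene is retained when at least one of its hits against the reference
#' resistance-gene-analogue database passes the E-value ceiling (the best hit
#' governs).
#'
#' @param hits similarity hits (gene vs reference database), as from
#'   [read_similarity_hits()].
#' @param cfg an [analysis_config()].
#' @return character vector (a set, no duplicates) of retained gene ids.
#' @export
prescreen_candidates <- function(hits, cfg = analysis_config()) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0L) {
    warning("prescreen_candidates: empty hit list", call. = FALSE)
    return(character())
  }
  sort(unique(hits[evalue <= cfg$prescreen_evalue_max]$query_id))
}

#' Build the domain architecture of one gene
#'
#' A domain class is present when at least one of the gene's records of that
#' class passes the per-domain E-value ceiling; `n_lrr_repeats` counts the
#' passing LRR records.
#'
#' @param records domain records (all for `gene_id`), as from
#'   [read_domain_table()].
#' @param gene_id the gene.
#' @param cfg an [analysis_config()].
#' @return list with fields `gene_id`, `has_lrr`, `has_lysm`, `has_tm`,
#'   `has_kinase`, `has_sp`, `n_lrr_repeats`.
#' @export
build_architecture <- function(records, gene_id, cfg = analysis_config()) {
  records <- as.data.table(records)
  if (nrow(records) && any(records$gene_id != gene_id))
    stop("build_architecture: records for foreign gene id(s)", call. = FALSE)
  ok <- records[evalue <= cfg$domain_evalue_max]
  list(
    gene_id = gene_id,
    has_lrr = "LRR" %in% ok$domain_class,
    has_lysm = "LYSM" %in% ok$domain_class,
    has_tm = "TM" %in% ok$domain_class,
    has_kinase = "KINASE_STTK" %in% ok$domain_class,
    has_sp = "SIGNAL_PEPTIDE" %in% ok$domain_class,
    n_lrr_repeats = sum(ok$domain_class == "LRR")
  )
}

#' Classify one gene from its architecture
#'
#' Rule table (applied only to prescreened genes; everything else is
#' `NON_RGA`): a transmembrane helix plus a kinase domain makes an RLK
#' (LysM-RLK, LRR-RLK or RLK-other by ectodomain); a transmembrane helix
#' without a kinase domain plus an ectodomain makes an RLP.  When a gene
#' carries both ectodomains the configured `ectodomain_priority` decides
#' (LysM by default).  The signal peptide is recorded but never used.
#'
#' @param arch list from [build_architecture()].
#' @param prescreened logical: did the gene pass the reference prescreen?
#' @param cfg an [analysis_config()].
#' @return one of [RGA_CLASSES].
#' @export
classify_gene <- function(arch, prescreened, cfg = analysis_config()) {
  if (!isTRUE(prescreened)) return("NON_RGA")
  lysm_first <- cfg$ectodomain_priority == "LYSM"
  if (arch$has_tm && arch$has_kinase) {
    if (arch$has_lysm && (lysm_first || !arch$has_lrr)) return("LYSM_RLK")
    if (arch$has_lrr) return("LRR_RLK")
    if (arch$has_lysm) return("LYSM_RLK")
    return("RLK_OTHER")
  }
  if (arch$has_tm && !arch$has_kinase) {
    if (arch$has_lysm && (lysm_first || !arch$has_lrr)) return("LYSM_RLP")
    if (arch$has_lrr) return("LRR_RLP")
    if (arch$has_lysm) return("LYSM_RLP")
  }
  "NON_RGA"
}

#' Classify a whole proteome
#'
#' Vectorised application of the prescreen + architecture rules to every
#' input gene; the result is a total partition (exactly one class per gene).
#'
#' @param genes gene models ([read_gene_models()]).
#' @param domains domain records ([read_domain_table()]); records for gene
#'   ids absent from `genes` raise a warning and are skipped.
#' @param prescreen either a character vector of prescreened gene ids or a
#'   hit table to pass through [prescreen_candidates()].
#' @param cfg an [analysis_config()].
#' @return `data.table`: `gene_id`, `species`, `chromosome`, `sub_genome`,
#'   `class`, `family`, plus the architecture flags.
#' @export
classify_proteome <- function(genes, domains, prescreen,
                              cfg = analysis_config()) {
  genes <- as.data.table(genes)
  domains <- as.data.table(domains)
  if (is.data.frame(prescreen))
    prescreen <- prescreen_candidates(prescreen, cfg)

  unknown <- setdiff(unique(domains$gene_id), genes$gene_id)
  if (length(unknown)) {
    warning("classify_proteome: skipping domain records for ",
            length(unknown), " unknown gene id(s)", call. = FALSE)
    domains <- domains[!gene_id %in% unknown]
  }
  ok <- domains[evalue <= cfg$domain_evalue_max]
  arch <- ok[, .(
    has_lrr = any(domain_class == "LRR"),
    has_lysm = any(domain_class == "LYSM"),
    has_tm = any(domain_class == "TM"),
    has_kinase = any(domain_class == "KINASE_STTK"),
    has_sp = any(domain_class == "SIGNAL_PEPTIDE"),
    n_lrr_repeats = sum(domain_class == "LRR")
  ), by = gene_id]

  out <- merge(genes, arch, by = "gene_id", all.x = TRUE)
  for (f in c("has_lrr", "has_lysm", "has_tm", "has_kinase", "has_sp"))
    out[is.na(get(f)), (f) := FALSE]
  out[is.na(n_lrr_repeats), n_lrr_repeats := 0L]

  pre <- out$gene_id %in% prescreen
  lysm_first <- cfg$ectodomain_priority == "LYSM"
  ecto_lysm <- out$has_lysm & (lysm_first | !out$has_lrr)
  cls <- rep("NON_RGA", nrow(out))
  rlk <- pre & out$has_tm & out$has_kinase
  rlp <- pre & out$has_tm & !out$has_kinase
  cls[rlk] <- "RLK_OTHER"
  cls[rlk & out$has_lrr] <- "LRR_RLK"
  cls[rlk & ecto_lysm] <- "LYSM_RLK"
  cls[rlp & out$has_lrr] <- "LRR_RLP"
  cls[rlp & ecto_lysm] <- "LYSM_RLP"
  out[, class := factor(cls, levels = RGA_CLASSES)]
  out[, family := class_family(cls)]
  setorder(out, chromosome, start, gene_id)
  out[]
}
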