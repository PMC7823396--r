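#' Default mapping from annotation signatures to internal domain classes
#'
#' Translates external signature names (InterPro/Pfam accessions, Phobius
#' labels, common domain names) into the five internal classes used by the
#' classifier.  Anything not listed maps to `OTHER`.
#'
#' @return named character vector: signature name -> domain class.
#' @export
default_domain_class_map <- function() {
  c(
    # transmembrane helix calls
    TMhelix = "TM", TRANSMEMBRANE = "TM", Phobius_TM = "TM", TM = "TM",
    # serine/threonine kinase domains
    Pkinase = "KINASE_STTK", Pkinase_Tyr = "KINASE_STTK",
    PF00069 = "KINASE_STTK", PF07714 = "KINASE_STTK",
    `Protein kinase domain` = "KINASE_STTK", STTK = "KINASE_STTK",
    KINASE_STTK = "KINASE_STTK",
    # leucine-rich repeats
    LRR = "LRR", LRR_1 = "LRR", LRR_4 = "LRR", LRR_8 = "LRR",
    LRRNT_2 = "LRR", PF00560 = "LRR", PF13855 = "LRR", PF08263 = "LRR",
    `Leucine rich repeat` = "LRR",
    # lysin motifs
    LysM = "LYSM", LYSM = "LYSM", PF01476 = "LYSM",
    # signal peptides
    SIGNAL_PEPTIDE = "SIGNAL_PEPTIDE", `SignalP-noTM` = "SIGNAL_PEPTIDE",
    `SignalP-TM` = "SIGNAL_PEPTIDE", Phobius_SP = "SIGNAL_PEPTIDE",
    OTHER = "OTHER"
  )
}

#' Read a per-gene protein-domain annotation table
#'
#' Expects a tab-separated file with header columns `gene_id`, `signature`,
#' `p_start`, `p_end`, `evalue`, `source` (InterProScan/Phobius-style rows,
#' one domain hit per line).  Signatures are translated through `class_map`;
#' unknown signatures map to `OTHER` and are counted in a message, never
#' dropped.
#'
#' @param path TSV file.
#' @param class_map named vector as from [default_domain_class_map()].
#' @return `data.table` with columns `gene_id`, `domain_class`, `p_start`,
#'   `p_end`, `evalue`, `source_tool`, `signature`.
#' @export
read_domain_table <- function(path, class_map = default_domain_class_map()) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("gene_id", "signature", "p_start", "p_end", "evalue", "source")
  if (!all(need %in% names(dt)))
    stop("domain table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (f in c("p_start", "p_end", "evalue")) {
    v <- suppressWarnings(as.numeric(dt[[f]]))
    bad <- which(is.na(v) & !is.na(dt[[f]]))
    if (length(bad))
      stop("unparseable numeric field '", f, "' at line ",
           bad[[1L]] + 1L, " of ", path, call. = FALSE)
    dt[[f]] <- v
  }
  if (any(dt$p_start < 1) || any(dt$p_end < dt$p_start))
    stop("domain records must satisfy p_start >= 1 and p_end >= p_start",
         call. = FALSE)
  cls <- unname(class_map[dt$signature])
  unknown <- is.na(cls)
  if (any(unknown)) {
    tab <- sort(table(dt$signature[unknown]), decreasing = TRUE)
    message("read_domain_table: ", sum(unknown),
            " record(s) with unmapped signature(s) set to OTHER: ",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "))
    cls[unknown] <- "OTHER"
  }
  out <- data.table(
    gene_id = dt$gene_id,
    domain_class = cls,
    p_start = dt$p_start,
    p_end = dt$p_end,
    evalue = dt$evalue,
    source_tool = dt$source,
    signature = dt$signature
  )
  setorder(out, gene_id, domain_class, p_start, signature)
  out[]
}

#' Write a domain table readable by [read_domain_table()]
#'
#' @param domains `data.table` as returned by [read_domain_table()].
#' @param path output TSV.
#' @export
write_domain_table <- function(domains, path) {
  out <- data.table(
    gene_id = domains$gene_id,
    signature = domains$signature,
    p_start = domains$p_start,
    p_end = domains$p_end,
    evalue = domains$evalue,
    source = domains$source_tool
  )
  fwrite(out, path, sep = "\t", eol = "\n")
  invisible(path)
}
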