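#' Read gene models from a GFF3 file
#'
#' Only features of type `gene` are kept; each must carry an `ID` attribute.
#' Coordinates are GFF3 1-based fully-closed and are preserved unchanged.
#' Sequence names that match neither subgenome pattern become
#' [CHROM_UNPLACED].
#'
#' @param path GFF3 file.
#' @param species species tag stored on every record.
#' @param cfg an [analysis_config()]; supplies the chromosome naming patterns.
#' @param sub_genome optional fixed subgenome label (`"A"`, `"B"` or
#'   `"NONE"`) for diploid species whose whole genome belongs to one
#'   ancestral complement.  When `NULL` (default) the label is derived from
#'   the chromosome name.
#' @return a `data.table` of gene models with columns `gene_id`, `species`,
#'   `chromosome`, `start`, `end`, `strand` (`+`, `-` or `unknown`) and
#'   `sub_genome`, sorted by (chromosome, start, gene_id).
#' @export
read_gene_models <- function(path, species, cfg = analysis_config(),
                             sub_genome = NULL) {
  stopifnot(is.character(species), length(species) == 1L)
  # Pre-scan raw lines so coordinate violations are reported with their line
  # number before the structural parser rejects the file.
  raw <- readLines(path, warn = FALSE)
  body <- !startsWith(raw, "#") & nzchar(raw)
  for (i in which(body)) {
    f <- strsplit(raw[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 5L && f[[3L]] == "gene") {
      s <- suppressWarnings(as.numeric(f[[4L]]))
      e <- suppressWarnings(as.numeric(f[[5L]]))
      if (!is.na(s) && !is.na(e) && e < s)
        stop("gene feature with end < start at line ", i, " of ", path,
             call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("gene feature(s) without an ID attribute in ", path, call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "unknown"
  seqid <- as.character(GenomicRanges::seqnames(gr))
  chrom <- ifelse(chrom_matches(seqid, cfg), seqid, CHROM_UNPLACED)
  genes <- data.table(
    gene_id = ids,
    species = species,
    chromosome = chrom,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand
  )
  genes[, sub_genome := if (is.null(sub_genome))
    assign_subgenome(chromosome, cfg) else sub_genome]
  setorder(genes, chromosome, start, gene_id)
  genes[]
}

chrom_matches <- function(seqid, cfg) {
  grepl(cfg$subgenome_regex[["A"]], seqid) |
    grepl(cfg$subgenome_regex[["B"]], seqid)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]: a write followed by a read reproduces the
#' in-memory records exactly (unplaced genes are emitted on the `UNPLACED`
#' pseudo-sequence).
#'
#' @param genes gene-model `data.table` as returned by [read_gene_models()].
#' @param path output file.
#' @export
write_gene_models <- function(genes, path) {
  genes <- as.data.table(genes)
  strand <- genes$strand
  strand[strand == "unknown"] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = strand
  )
  gr$source <- "rgascape"
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
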