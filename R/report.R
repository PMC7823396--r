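#' Format a percentage with exact half-up rounding
#'
#' Percentages are computed with integer arithmetic
#' (`numerator * 100 * 10^decimals` against `denominator`) so the half-up
#' rounding is exact and free of binary floating-point artefacts; trailing
#' zeros are kept (`"37.50%"`, not `"37.5%"`).
#'
#' @param numerator,denominator nonnegative counts.
#' @param decimals digits after the decimal point (2 for most tables, 3 for
#'   whole-proteome proportions).
#' @return an object of class `percent_cell`: a list with fields
#'   `numerator`, `denominator`, `decimals` and `formatted`.
#' @export
format_percent <- function(numerator, denominator, decimals = 2L) {
  stopifnot(length(numerator) == 1L, length(denominator) == 1L,
            numerator >= 0, denominator >= 0)
  if (denominator == 0) {
    if (numerator > 0)
      stop("format_percent: nonzero numerator with zero denominator",
           call. = FALSE)
    formatted <- paste0(sprintf("%.*f", decimals, 0), "%")
  } else {
    formatted <- paste0(pct_string(numerator, denominator, decimals), "%")
  }
  structure(list(numerator = numerator, denominator = denominator,
                 decimals = as.integer(decimals), formatted = formatted),
            class = "percent_cell")
}

#' @export
print.percent_cell <- function(x, ...) {
  cat(sprintf("%s  (%s / %s)\n", x$formatted,
              format(x$numerator), format(x$denominator)))
  invisible(x)
}

# Vectorised exact half-up percentage string (no trailing "%").
pct_string <- function(num, den, decimals = 2L) {
  scale <- 10^decimals
  v <- num * 100 * scale           # exact for counts far below 2^53
  q <- v %/% den
  r <- v %% den
  cents <- q + (2 * r >= den)
  out <- sprintf("%.*f", decimals, cents / scale)
  out[den == 0 & num == 0] <- sprintf("%.*f", decimals, 0)
  out
}

# Exact half-up rounding of base-pair spans to kb with `decimals` digits.
kb_string <- function(span_bp, decimals = 2L) {
  scale <- 10^decimals
  cents <- floor(span_bp * scale / 1000 + 0.5)
  sprintf("%.*f", decimals, cents / scale)
}

kb_value <- function(span_bp, decimals = 2L) {
  scale <- 10^decimals
  floor(span_bp * scale / 1000 + 0.5) / scale
}

#' Cross-species family-size table
#'
#' Builds the family/subfamily count table (counts plus proportion of total
#' gene content, three decimals) across one or more classified species.
#'
#' @param classifications named list (by species tag) of classification
#'   tables from [classify_proteome()].
#' @return long `data.table`: `species`, `row_class` (RLK, LRR_RLK, LYSM_RLK,
#'   RLK_OTHER, RLP, LRR_RLP, LYSM_RLP), `count`, `total_genes`, `pct`.
#' @export
build_family_table <- function(classifications) {
  stopifnot(length(classifications) >= 1L, !is.null(names(classifications)))
  rows <- list(
    RLK = c("LRR_RLK", "LYSM_RLK", "RLK_OTHER"),
    LRR_RLK = "LRR_RLK", LYSM_RLK = "LYSM_RLK", RLK_OTHER = "RLK_OTHER",
    RLP = c("LRR_RLP", "LYSM_RLP"),
    LRR_RLP = "LRR_RLP", LYSM_RLP = "LYSM_RLP"
  )
  out <- rbindlist(lapply(names(classifications), function(sp) {
    cl <- as.data.table(classifications[[sp]])
    total <- nrow(cl)
    counts <- vapply(rows, function(r) sum(cl$class %in% r), integer(1L))
    data.table(species = sp, row_class = names(rows), count = counts,
               total_genes = total,
               pct = paste0(pct_string(counts, total, 3L), "%"))
  }))
  out[]
}

#' @rdname build_family_table
#' @export
compare_family_sizes <- build_family_table

#' Denominator audit of every reported percentage
#'
#' The source tables mix denominators (total genes, mapped family genes,
#' duplicated genes, cluster counts, subgenome totals).  The audit lists, for
#' every percentage in the result bundle, its numerator, denominator, the
#' denominator's definition, and the formatted cell, so each percentage can
#' be recomputed independently.
#'
#' @param bundle a result bundle from [run_landscape_pipeline()] (or the
#'   empty bundle).
#' @return `data.table`: `table_name`, `label`, `numerator`, `denominator`,
#'   `denominator_definition`, `formatted`.
#' @export
build_denominator_audit <- function(bundle) {
  rows <- list()
  add <- function(tab, label, num, den, def, decimals = 2L) {
    rows[[length(rows) + 1L]] <<- data.table(
      table_name = tab, label = label,
      numerator = as.numeric(num), denominator = as.numeric(den),
      denominator_definition = def,
      formatted = paste0(pct_string(num, den, decimals), "%"))
  }
  if (!is.null(bundle$family_table) && nrow(bundle$family_table)) {
    ft <- bundle$family_table
    for (i in seq_len(nrow(ft)))
      add("family_counts",
          paste(ft$species[i], ft$row_class[i]),
          ft$count[i], ft$total_genes[i],
          paste("predicted coding genes of", ft$species[i]), 3L)
  }
  if (!is.null(bundle$distribution$mapped_summary) &&
      nrow(bundle$distribution$mapped_summary)) {
    ms <- bundle$distribution$mapped_summary
    for (i in seq_len(nrow(ms)))
      add("per_chromosome", paste("mapped share", ms$family[i]),
          ms$mapped[i], ms$total[i],
          paste("all candidate", ms$family[i], "genes"))
  }
  for (fam in names(bundle$cluster_stats)) {
    cs <- bundle$cluster_stats[[fam]]
    if (!is.null(cs$clustered_share))
      add("clusters", paste("clustered share", fam),
          cs$clustered_share$numerator, cs$clustered_share$denominator,
          paste("mapped", fam, "genes"))
  }
  for (fam in names(bundle$dup_summary)) {
    ds <- bundle$dup_summary[[fam]]
    if (is.null(ds)) next
    add("duplicates", paste("duplicated share", fam),
        ds$duplicated_share$numerator, ds$duplicated_share$denominator,
        paste("mapped", fam, "genes"))
    add("duplicates", paste("tandem share", fam),
        ds$tandem_share$numerator, ds$tandem_share$denominator,
        paste("duplicated", fam, "genes"))
    add("duplicates", paste("segmental share", fam),
        ds$segmental_share$numerator, ds$segmental_share$denominator,
        paste("duplicated", fam, "genes"))
    if (!is.null(ds$tandem_cluster_share))
      add("duplicates", paste("tandem-cluster share", fam),
          ds$tandem_cluster_share$numerator,
          ds$tandem_cluster_share$denominator,
          paste(fam, "clusters"))
  }
  if (!is.null(bundle$conservation) && nrow(bundle$conservation)) {
    cv <- bundle$conservation
    for (i in seq_len(nrow(cv))) {
      add("conservation",
          paste("conserved", cv$family[i], "subgenome", cv$sub_genome[i]),
          cv$tetra_conserved[i], cv$tetra_total[i],
          paste("mapped", cv$family[i], "genes in subgenome",
                cv$sub_genome[i]))
      add("conservation",
          paste("conserved", cv$family[i], "progenitor",
                cv$prog_species[i]),
          cv$prog_conserved[i], cv$prog_total[i],
          paste("all", cv$family[i], "genes of", cv$prog_species[i]))
    }
  }
  if (!length(rows))
    return(data.table(table_name = character(), label = character(),
                      numerator = numeric(), denominator = numeric(),
                      denominator_definition = character(),
                      formatted = character()))
  rbindlist(rows)[]
}
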