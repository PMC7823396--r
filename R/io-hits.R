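# BLAST tabular "outfmt 6 std qlen slen" column set.
BLAST14_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                  "mismatches", "gap_opens", "q_start", "q_end",
                  "s_start", "s_end", "evalue", "bitscore",
                  "query_len", "subject_len")

#' Read protein similarity hits (BLAST outfmt 6 + qlen + slen)
#'
#' The file must contain the 12 standard tabular columns extended with
#' `qlen` and `slen` (`-outfmt "6 std qlen slen"`).  Query and subject
#' coverage are computed from the aligned spans and clamped to \[0, 100\]
#' (gapped alignments can nominally exceed the sequence length); self-hits
#' (`query == subject`) are flagged so relationship callers can exclude them.
#'
#' @param path tabular file without header.
#' @return `data.table` with the 14 input columns plus `query_cov`,
#'   `subject_cov` and logical `self_hit`.
#' @export
read_similarity_hits <- function(path) {
  if (file.size(path) == 0) {
    empty <- data.table(query_id = character(), subject_id = character(),
                        pct_identity = numeric(), aln_length = numeric(),
                        mismatches = numeric(), gap_opens = numeric(),
                        q_start = numeric(), q_end = numeric(),
                        s_start = numeric(), s_end = numeric(),
                        evalue = numeric(), bitscore = numeric(),
                        query_len = numeric(), subject_len = numeric())
    return(compute_hit_derived(empty))
  }
  dt <- fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) != 14L)
    stop("similarity table must have exactly 14 columns ",
         "(BLAST -outfmt \"6 std qlen slen\"): ",
         paste(BLAST14_COLS, collapse = " "), "; got ", ncol(dt),
         " column(s)", call. = FALSE)
  setnames(dt, BLAST14_COLS)
  compute_hit_derived(dt)
}

# Shared by the reader and the simulator so coverage semantics cannot drift.
compute_hit_derived <- function(dt) {
  dt <- as.data.table(dt)
  qspan <- abs(dt$q_end - dt$q_start) + 1
  sspan <- abs(dt$s_end - dt$s_start) + 1
  qcov <- 100 * qspan / dt$query_len
  scov <- 100 * sspan / dt$subject_len
  n_over <- sum(qcov > 100) + sum(scov > 100)
  if (n_over > 0)
    warning("clamped ", n_over,
            " coverage value(s) exceeding 100% (gapped alignment spans)",
            call. = FALSE)
  dt[, query_cov := pmin(pmax(qcov, 0), 100)]
  dt[, subject_cov := pmin(pmax(scov, 0), 100)]
  dt[, self_hit := query_id == subject_id]
  dt[]
}

#' Write similarity hits in BLAST outfmt-6 + qlen/slen form
#'
#' Inverse of [read_similarity_hits()]; derived columns are recomputed on
#' read, so a write/read round trip reproduces the records.
#'
#' @param hits hit `data.table`.
#' @param path output file.
#' @export
write_similarity_hits <- function(hits, path) {
  fwrite(as.data.table(hits)[, BLAST14_COLS, with = FALSE], path,
         sep = "\t", eol = "\n", col.names = FALSE)
  invisible(path)
}
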