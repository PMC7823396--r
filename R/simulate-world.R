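# World construction internals -----------------------------------------------

# Places the tetraploid's genes chromosome by chromosome.  Non-cluster loci
# sit on a slot grid (default 250 kb apart: too far to chain into clusters,
# close enough that adjacent loci are tandem-range), planted clusters get
# exact spans, segmental pair mates are forced > 5 Mb apart, background
# (NON_RGA) genes are packed after the family loci.
sim_build_tetraploid <- function(cfg) {
  sp <- cfg$species[["tetra"]]
  counts <- cfg$tetra_counts
  id_counter <- 0L
  new_ids <- function(k) {
    out <- sprintf("%s_g%05d", sp, id_counter + seq_len(k))
    id_counter <<- id_counter + k
    out
  }
  genes <- list(); clusters <- list()
  pair_edges <- list(); seg_edges <- list()

  for (sg in c("A", "B")) {
    chroms <- sim_chroms(cfg, sg)
    cnt <- function(cl) {
      v <- counts[[sg]][match(cl, counts$class)]
      if (is.na(v)) 0L else v
    }
    # per-chromosome unit lists ------------------------------------------
    units <- setNames(vector("list", length(chroms)), chroms)
    add_unit <- function(ch, u) units[[ch]] <<- c(units[[ch]], list(u))

    used <- c(LRR_RLK = 0L, LYSM_RLK = 0L, RLK_OTHER = 0L,
              LRR_RLP = 0L, LYSM_RLP = 0L)
    for (fam in c("RLK", "RLP")) {
      lrr <- paste0("LRR_", fam); lysm <- paste0("LYSM_", fam)
      cl_defs <- cfg$clusters[family == fam &
                                chromosome %in% chroms]
      # clusters
      for (r in seq_len(nrow(cl_defs))) {
        def <- cl_defs[r]
        cls <- rep(lrr, def$n_members)
        if (def$n_lysm > 0L) cls[seq(2L, 1L + def$n_lysm)] <- lysm
        add_unit(def$chromosome, list(type = "cluster", family = fam,
                                      classes = cls, span = def$span_bp,
                                      tandem = def$tandem))
        used[lrr] <- used[lrr] + sum(cls == lrr)
        used[lysm] <- used[lysm] + sum(cls == lysm)
      }
      # segmental pairs (at most one per chromosome, enforced)
      seg_ch <- intersect(cfg$dup[[fam]]$segmental_chroms, chroms)
      for (ch in seg_ch) {
        add_unit(ch, list(type = "seg", family = fam, classes = lrr))
        used[lrr] <- used[lrr] + 2L
      }
      # extra tandem pairs, round-robin over chromosomes
      n_pairs <- cfg$dup[[fam]]$tandem_extra_pairs[[sg]]
      if (n_pairs > 0L) {
        for (k in seq_len(n_pairs)) {
          ch <- chroms[((k - 1L) %% length(chroms)) + 1L]
          add_unit(ch, list(type = "pair", family = fam, classes = lrr))
        }
        used[lrr] <- used[lrr] + 2L * n_pairs
      }
      # singletons fill the remaining per-class budget
      n_lrr_single <- cnt(lrr) - used[lrr]
      n_lysm_single <- cnt(lysm) - used[lysm]
      n_other_single <- if (fam == "RLK") cnt("RLK_OTHER") else 0L
      if (n_lrr_single < 0 || n_lysm_single < 0)
        stop("sim_config: planted structures need more ", fam,
             " genes than the ", sg, " subgenome provides", call. = FALSE)
      single_classes <- c(rep(lrr, n_lrr_single),
                          rep(lysm, n_lysm_single),
                          rep("RLK_OTHER", n_other_single))
      for (k in seq_along(single_classes)) {
        ch <- chroms[((k - 1L) %% length(chroms)) + 1L]
        add_unit(ch, list(type = "single", family = fam,
                          classes = single_classes[[k]]))
      }
    }
    # placement ----------------------------------------------------------
    for (ch in chroms) {
      uu <- units[[ch]]
      if (!length(uu)) uu <- list()
      is_seg <- vapply(uu, function(u) u$type == "seg", logical(1L))
      if (sum(is_seg) > 1L)
        stop("at most one segmental pair per chromosome", call. = FALSE)
      mids <- uu[!is_seg]
      if (length(mids) > 1L) mids <- mids[sample.int(length(mids))]
      seg_unit <- if (any(is_seg)) uu[is_seg][[1L]] else NULL
      cursor <- 1e6
      glen <- cfg$gene_len_bp
      emit <- function(class, fam, start) {
        id <- new_ids(1L)
        genes[[length(genes) + 1L]] <<- data.table(
          gene_id = id, species = sp, chromosome = ch,
          start = start, end = start + glen - 1,
          strand = if (id_counter %% 2L) "+" else "-",
          sub_genome = sg, class = class, family = fam)
        id
      }
      seg_first_id <- NULL; seg_first_start <- NA_real_
      if (!is.null(seg_unit)) {
        seg_first_start <- cursor
        seg_first_id <- emit(seg_unit$classes, seg_unit$family, cursor)
        cursor <- cursor + cfg$slot_bp
      }
      for (u in mids) {
        if (u$type == "single") {
          emit(u$classes, u$family, cursor)
          cursor <- cursor + cfg$slot_bp
        } else if (u$type == "pair") {
          a <- emit(u$classes, u$family, cursor)
          b <- emit(u$classes, u$family, cursor + cfg$slot_bp)
          pair_edges[[length(pair_edges) + 1L]] <- data.table(
            gene_a = a, gene_b = b, family = u$family, role = "TANDEM")
          cursor <- cursor + 2 * cfg$slot_bp
        } else if (u$type == "cluster") {
          n <- length(u$classes)
          first <- cursor
          last_start <- first + u$span - (glen - 1)
          if (last_start <= first)
            stop("cluster span too small for its gene bodies",
                 call. = FALSE)
          starts <- round(seq(first, last_start, length.out = n))
          if (any(diff(starts) > 0.95 * cfg$cluster_gap_bp))
            stop("planted cluster violates the chaining rule margin",
                 call. = FALSE)
          ids <- character(n)
          for (m in seq_len(n)) ids[m] <- emit(u$classes[m], u$family,
                                               starts[m])
          clusters[[length(clusters) + 1L]] <- data.table(
            family = u$family, chromosome = ch, n_members = n,
            first_start = starts[1L], last_end = starts[n] + glen - 1,
            span_bp = starts[n] + glen - 1 - starts[1L],
            tandem = u$tandem, member_ids = paste(ids, collapse = ","))
          if (u$tandem)
            pair_edges[[length(pair_edges) + 1L]] <- data.table(
              gene_a = ids[-n], gene_b = ids[-1L], family = u$family,
              role = "TANDEM")
          cursor <- starts[n] + glen - 1 + cfg$slot_bp
        }
      }
      if (!is.null(seg_unit)) {
        pos2 <- max(cursor, seg_first_start + cfg$tandem_max_bp + 50000)
        b <- emit(seg_unit$classes, seg_unit$family, pos2)
        seg_edges[[length(seg_edges) + 1L]] <- data.table(
          gene_a = seg_first_id, gene_b = b, family = seg_unit$family,
          role = "SEGMENTAL")
        cursor <- pos2 + cfg$slot_bp
      }
      # background genes
      n_bg <- ceiling(cnt("NON_RGA") / length(chroms))
      done <- (match(ch, chroms) - 1L) * n_bg
      n_here <- max(0L, min(n_bg, cnt("NON_RGA") - done))
      if (n_here > 0L) {
        starts <- cursor + (seq_len(n_here) - 1L) * 3000
        ids <- new_ids(n_here)
        genes[[length(genes) + 1L]] <- data.table(
          gene_id = ids, species = sp, chromosome = ch, start = starts,
          end = starts + glen - 1,
          strand = rep(c("+", "-"), length.out = n_here),
          sub_genome = sg, class = "NON_RGA", family = "NONE")
      }
    }
  }
  # unplaced genes
  ucnt <- counts$U
  for (r in seq_len(nrow(counts))) {
    k <- ucnt[r]
    if (k == 0L) next
    ids <- new_ids(k)
    starts <- 1 + (seq_len(k) - 1L) * 10000
    genes[[length(genes) + 1L]] <- data.table(
      gene_id = ids, species = sp, chromosome = CHROM_UNPLACED,
      start = starts, end = starts + cfg$gene_len_bp - 1,
      strand = rep("unknown", k), sub_genome = "NONE",
      class = counts$class[r], family = class_family(counts$class[r]))
  }
  genes <- rbindlist(genes)
  clusters <- rbindlist(clusters)
  list(genes = genes,
       clusters = clusters,
       forced_edges = rbindlist(c(pair_edges, seg_edges)))
}

sim_build_progenitor <- function(cfg, sg) {
  sp <- cfg$species[[paste0("prog_", sg)]]
  counts <- if (sg == "A") cfg$prog_A_counts else cfg$prog_B_counts
  chroms <- sim_chroms(cfg, sg)
  id_counter <- 0L
  new_ids <- function(k) {
    out <- sprintf("%s_g%05d", sp, id_counter + seq_len(k))
    id_counter <<- id_counter + k
    out
  }
  genes <- list()
  fam_classes <- setdiff(counts$class, "NON_RGA")
  # mapped family genes round-robin over chromosomes, on the slot grid
  per_chrom <- setNames(vector("list", length(chroms)), chroms)
  for (cl in fam_classes) {
    k <- counts$mapped[match(cl, counts$class)]
    if (k == 0L) next
    for (i in seq_len(k)) {
      ch <- chroms[((i - 1L) %% length(chroms)) + 1L]
      per_chrom[[ch]] <- c(per_chrom[[ch]], cl)
    }
  }
  glen <- cfg$gene_len_bp
  for (ch in chroms) {
    cls <- per_chrom[[ch]]
    if (length(cls) > 1L) cls <- cls[sample.int(length(cls))]
    n <- length(cls)
    if (n > 0L) {
      starts <- 1e6 + (seq_len(n) - 1L) * cfg$slot_bp
      ids <- new_ids(n)
      genes[[length(genes) + 1L]] <- data.table(
        gene_id = ids, species = sp, chromosome = ch, start = starts,
        end = starts + glen - 1,
        strand = rep(c("+", "-"), length.out = n),
        sub_genome = sg, class = cls, family = class_family(cls))
    }
    # background genes after the family loci
    n_bg_total <- counts$mapped[match("NON_RGA", counts$class)]
    n_bg <- ceiling(n_bg_total / length(chroms))
    done <- (match(ch, chroms) - 1L) * n_bg
    n_here <- max(0L, min(n_bg, n_bg_total - done))
    if (n_here > 0L) {
      base <- 1e6 + length(cls) * cfg$slot_bp
      starts <- base + (seq_len(n_here) - 1L) * 3000
      ids <- new_ids(n_here)
      genes[[length(genes) + 1L]] <- data.table(
        gene_id = ids, species = sp, chromosome = ch, start = starts,
        end = starts + glen - 1,
        strand = rep(c("+", "-"), length.out = n_here),
        sub_genome = sg, class = "NON_RGA", family = "NONE")
    }
  }
  for (r in seq_len(nrow(counts))) {
    k <- counts$unplaced[r]
    if (k == 0L) next
    ids <- new_ids(k)
    starts <- 1 + (seq_len(k) - 1L) * 10000
    genes[[length(genes) + 1L]] <- data.table(
      gene_id = ids, species = sp, chromosome = CHROM_UNPLACED,
      start = starts, end = starts + glen - 1,
      strand = rep("unknown", k), sub_genome = sg,
      class = counts$class[r], family = class_family(counts$class[r]))
  }
  rbindlist(genes)
}
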