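#' Build per-position and per-insertion pileups
#'
#' Aggregates alignment events over all retained reads into the
#' per-position substrate of variant calling: base counts A/C/G/T, the
#' number of reads whose deletion spans each position, total read depth
#' `rd` (matches plus deletion-spanning reads — deletion reads are evidence
#' about a position and belong in the heteroplasmic-fraction denominator),
#' and base-quality summaries. Insertions are merged by (anchor position,
#' inserted sequence). Duplicate-flagged reads are excluded unless
#' `use_duplicates`.
#'
#' @param reads `mt_reads` table (duplicates marked via [mark_duplicates()]).
#' @param ref A `circ_ref`.
#' @param use_duplicates Include duplicate-flagged reads (default FALSE).
#' @return Object of class `mt_pileup`: list with `counts` (L x 4 matrix,
#'   columns A,C,G,T), `del_cov`, `rd`, `median_qs` (all length-L vectors),
#'   `deletions` (data.frame `start`, `len`, `count`), `insertions`
#'   (data.frame `anchor_pos`, `inserted_seq`, `support`, `anchor_rd`,
#'   list-column `quals`), and bookkeeping fields.
#' @export
build_pileup <- function(reads, ref, use_duplicates = FALSE) {
  L <- ref$length
  keep <- !has_flag(reads$flag, FLAG_UNMAPPED) &
          !has_flag(reads$flag, FLAG_SECONDARY)
  if (!use_duplicates) keep <- keep & !reads$duplicate
  reads <- reads[keep, , drop = FALSE]
  n <- nrow(reads)

  mpos <- integer(0); mbase <- character(0); mqual <- integer(0)
  del_rows <- list(); ins_rows <- list()

  if (n > 0) {
    simple <- grepl("^[0-9]+M$", reads$cigar)
    if (any(simple)) {
      sp <- reads$pos[simple]
      sl <- nchar(reads$seq[simple])
      mpos <- normalize_position(ref, sequence(sl, from = sp))
      mbase <- strsplit(paste(reads$seq[simple], collapse = ""), "",
                        fixed = TRUE)[[1]]
      mqual <- utf8ToInt(paste(reads$qual[simple], collapse = "")) - 33L
    }
    complex_idx <- which(!simple)
    if (length(complex_idx) > 0) {
      ops_all <- explode_cigar(reads$cigar[complex_idx])
      cm_pos <- list(); cm_base <- list(); cm_qual <- list()
      for (j in seq_along(complex_idx)) {
        i <- complex_idx[j]
        ops <- ops_all[[j]]
        seq_ch <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
        quals <- utf8ToInt(reads$qual[i]) - 33L
        qi <- 1L; rp <- as.numeric(reads$pos[i])
        for (k in seq_len(nrow(ops))) {
          op <- ops$op[k]; len <- ops$len[k]
          if (op %in% c("M", "=", "X")) {
            idx <- qi:(qi + len - 1L)
            cm_pos[[length(cm_pos) + 1L]] <-
              normalize_position(ref, rp + 0:(len - 1))
            cm_base[[length(cm_base) + 1L]] <- seq_ch[idx]
            cm_qual[[length(cm_qual) + 1L]] <- quals[idx]
            qi <- qi + len; rp <- rp + len
          } else if (op == "I") {
            idx <- qi:(qi + len - 1L)
            ins_rows[[length(ins_rows) + 1L]] <- list(
              anchor = normalize_position(ref, rp - 1),
              seq = paste(seq_ch[idx], collapse = ""),
              quals = quals[idx])
            qi <- qi + len
          } else if (op == "D") {
            if (len >= L) stop("deletion length >= reference length in read ",
                               reads$qname[i])
            del_rows[[length(del_rows) + 1L]] <-
              c(normalize_position(ref, rp), len)
            rp <- rp + len
          } else if (op == "N") {
            rp <- rp + len
          } else if (op == "S") {
            qi <- qi + len
          }
        }
      }
      if (length(cm_pos) > 0) {
        mpos <- c(mpos, unlist(cm_pos))
        mbase <- c(mbase, unlist(cm_base))
        mqual <- c(mqual, unlist(cm_qual))
      }
    }
  }

  base_idx <- match(mbase, c("A", "C", "G", "T"))
  ok <- !is.na(base_idx)
  mpos <- mpos[ok]; base_idx <- base_idx[ok]; mqual <- mqual[ok]
  key <- (mpos - 1L) * 4L + base_idx
  counts <- matrix(tabulate(key, nbins = L * 4L), nrow = L, ncol = 4L,
                   byrow = TRUE, dimnames = list(NULL, c("A", "C", "G", "T")))

  # aggregated deletion events
  if (length(del_rows) > 0) {
    dm <- do.call(rbind, del_rows)
    dk <- paste(dm[, 1], dm[, 2], sep = ":")
    agg <- table(dk)
    parts <- strsplit(names(agg), ":", fixed = TRUE)
    deletions <- data.frame(
      start = as.integer(vapply(parts, `[[`, "", 1)),
      len = as.integer(vapply(parts, `[[`, "", 2)),
      count = as.integer(agg), stringsAsFactors = FALSE)
    deletions <- deletions[order(deletions$start, deletions$len), ,
                           drop = FALSE]
    rownames(deletions) <- NULL
  } else {
    deletions <- data.frame(start = integer(), len = integer(),
                            count = integer())
  }
  del_cov <- integer(L)
  for (r in seq_len(nrow(deletions))) {
    posns <- normalize_position(
      ref, seq(deletions$start[r], length.out = deletions$len[r]))
    del_cov[posns] <- del_cov[posns] + deletions$count[r]
  }

  rd <- as.integer(rowSums(counts) + del_cov)

  # per-position median quality over match bases
  median_qs <- numeric(L)
  if (length(mpos) > 0) {
    med <- vapply(split(mqual, mpos), stats::median, 0)
    median_qs[as.integer(names(med))] <- med
  }
  qsplit <- if (length(key) > 0) split(mqual, key) else list()

  # merged insertions
  if (length(ins_rows) > 0) {
    ik <- vapply(ins_rows, function(x) paste(x$anchor, x$seq, sep = ":"), "")
    grp <- split(seq_along(ins_rows), ik)
    insertions <- data.frame(
      anchor_pos = vapply(grp, function(g) ins_rows[[g[1]]]$anchor, 0L),
      inserted_seq = vapply(grp, function(g) ins_rows[[g[1]]]$seq, ""),
      support = lengths(grp), stringsAsFactors = FALSE)
    insertions$quals <- lapply(grp, function(g)
      unlist(lapply(ins_rows[g], `[[`, "quals")))
    insertions$anchor_rd <- rd[insertions$anchor_pos]
    insertions <- insertions[order(insertions$anchor_pos,
                                   insertions$inserted_seq), , drop = FALSE]
    rownames(insertions) <- NULL
  } else {
    insertions <- data.frame(anchor_pos = integer(), inserted_seq = character(),
                             support = integer(), stringsAsFactors = FALSE)
    insertions$quals <- list()
    insertions$anchor_rd <- integer(0)
  }

  structure(list(ref_name = ref$name, L = L, counts = counts,
                 del_cov = del_cov, rd = rd, median_qs = median_qs,
                 qsplit = qsplit, deletions = deletions,
                 insertions = insertions, n_reads = n),
            class = "mt_pileup")
}

#' @export
print.mt_pileup <- function(x, ...) {
  cat("mtDNA pileup over ", x$L, " positions (", x$n_reads, " reads; ",
      nrow(x$deletions), " deletion event(s), ", nrow(x$insertions),
      " insertion event(s))\n", sep = "")
  invisible(x)
}

# Phred values supporting base b (1..4 = A,C,G,T) at position p
site_quals <- function(pileup, p, b) {
  q <- pileup$qsplit[[as.character((p - 1L) * 4L + b)]]
  if (is.null(q)) integer(0) else q
}

#' Summarize genome coverage
#'
#' Breadth (fraction of positions with any coverage), mean depth, the gap
#' count used for consensus quality screening (positions below `min_rd`),
#' and per-locus median depth and median quality when a locus table is
#' given.
#'
#' @param pileup `mt_pileup`.
#' @param loci Optional locus table ([read_loci()]).
#' @param min_rd Depth below which a position counts as a gap (default 5).
#' @return List with `breadth`, `mean_depth`, `gap_count`, and `per_locus`
#'   data.frame (`locus`, `median_depth`, `median_qs`).
#' @export
summarize_coverage <- function(pileup, loci = NULL, min_rd = 5L) {
  out <- list(breadth = mean(pileup$rd >= 1L),
              mean_depth = mean(pileup$rd),
              gap_count = sum(pileup$rd < min_rd))
  if (!is.null(loci)) {
    rows <- lapply(seq_len(nrow(loci)), function(i) {
      p <- if (loci$start[i] <= loci$end[i]) loci$start[i]:loci$end[i]
           else c(loci$start[i]:pileup$L, 1:loci$end[i])
      data.frame(locus = loci$locus[i],
                 median_depth = stats::median(pileup$rd[p]),
                 median_qs = stats::median(pileup$median_qs[p]),
                 stringsAsFactors = FALSE)
    })
    out$per_locus <- do.call(rbind, rows)
  }
  out
}

#' Dump the per-position pileup as TSV
#'
#' Columns: pos, A, C, G, T, del, rd, median_qs — the per-position assembly
#' table that mismatch calling reads.
#'
#' @param pileup `mt_pileup`.
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  df <- data.frame(pos = seq_len(pileup$L), pileup$counts,
                   del = pileup$del_cov, rd = pileup$rd,
                   median_qs = pileup$median_qs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
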