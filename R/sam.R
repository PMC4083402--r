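# SAM flag bits used throughout
FLAG_PAIRED    <- 0x1L
FLAG_PROPER    <- 0x2L
FLAG_UNMAPPED  <- 0x4L
FLAG_MUNMAP    <- 0x8L
FLAG_REVERSE   <- 0x10L
FLAG_MREVERSE  <- 0x20L
FLAG_READ1     <- 0x40L
FLAG_READ2     <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUP       <- 0x400L
FLAG_SUPPL     <- 0x800L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")
REF_OPS   <- c("M", "D", "N", "=", "X")

#' Split CIGAR strings into operation tables
#'
#' @param cigar Character vector of CIGAR strings (`"*"` allowed).
#' @return List (one element per input) of data.frames with columns `op`
#'   and `len`. Unknown operations are an error.
#' @export
explode_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Za-z=]", cigar))
  lapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (identical(cg, "*")) return(data.frame(op = character(), len = integer()))
    tk <- toks[[i]]
    if (sum(nchar(tk)) != nchar(cg))
      stop("malformed CIGAR string: '", cg, "'")
    op <- substr(tk, nchar(tk), nchar(tk))
    bad <- setdiff(op, c("M", "I", "D", "N", "S", "H", "=", "X"))
    if (length(bad) > 0)
      stop("unknown CIGAR operation '", bad[1], "' in '", cg, "'")
    data.frame(op = op, len = as.integer(substr(tk, 1, nchar(tk) - 1L)),
               stringsAsFactors = FALSE)
  })
}

cigar_query_len <- function(ops) sum(ops$len[ops$op %in% QUERY_OPS])
cigar_ref_len   <- function(ops) sum(ops$len[ops$op %in% REF_OPS])

#' Parse SAM alignments from text
#'
#' Reads SAM-formatted text (path or character vector of lines) into a
#' columnar alignment table. By default unmapped, secondary and
#' supplementary records are dropped; records whose CIGAR query length does
#' not match the sequence length are rejected individually (count reported
#' via attribute `n_rejected` and a warning naming the line numbers).
#'
#' @param input Path to a SAM file or character vector of SAM lines.
#' @param keep_unmapped,keep_secondary Keep records normally filtered out.
#' @param ref Optional `circ_ref`; when given and the header names a
#'   reference, the names must agree.
#' @return data.frame of class `mt_reads` with columns `qname`, `flag`,
#'   `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `seq`, `qual`, plus
#'   logical helper columns `paired`, `reverse`, `duplicate`. Attribute
#'   `n_rejected` counts per-record rejections.
#' @export
read_sam <- function(input, keep_unmapped = FALSE, keep_secondary = FALSE,
                     ref = NULL) {
  lines <- if (length(input) == 1 && !grepl("\n|\t", input)) readLines(input)
           else unlist(strsplit(input, "\n", fixed = TRUE))
  hdr <- grepl("^@", lines)
  if (!is.null(ref)) {
    sq <- lines[hdr][grepl("^@SQ", lines[hdr])]
    if (length(sq) > 0) {
      sn <- sub(".*SN:([^\t]+).*", "\\1", sq)
      if (!ref$name %in% sn)
        stop("SAM header reference name(s) [", paste(sn, collapse = ","),
             "] do not include '", ref$name, "'")
    }
  }
  body_idx <- which(!hdr & nzchar(lines))
  if (length(body_idx) == 0) {
    out <- empty_reads()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad_line <- nf < 11L
  rejected <- integer(0)
  if (any(bad_line)) {
    rejected <- body_idx[bad_line]
    fields <- fields[!bad_line]
    body_idx <- body_idx[!bad_line]
  }
  get <- function(k) vapply(fields, `[[`, "", k)
  df <- data.frame(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    rnext = get(7), pnext = as.integer(get(8)),
    seq = get(10), qual = get(11), stringsAsFactors = FALSE
  )
  # per-record validation: CIGAR query length must equal seq length
  mapped <- !has_flag(df$flag, FLAG_UNMAPPED)
  ops <- explode_cigar(df$cigar)
  qlen <- vapply(ops, cigar_query_len, 0L)
  mism <- mapped & df$cigar != "*" & df$seq != "*" & qlen != nchar(df$seq)
  mism <- mism | (df$seq != "*" & nchar(df$seq) != nchar(df$qual) & df$qual != "*")
  if (any(mism)) {
    rejected <- c(rejected, body_idx[mism])
    df <- df[!mism, , drop = FALSE]
  }
  if (length(rejected) > 0)
    warning(length(rejected), " SAM record(s) rejected (line ",
            paste(rejected, collapse = ","), "): CIGAR/SEQ length mismatch or too few fields")
  keep <- rep(TRUE, nrow(df))
  if (!keep_unmapped) keep <- keep & !has_flag(df$flag, FLAG_UNMAPPED)
  if (!keep_secondary)
    keep <- keep & !has_flag(df$flag, FLAG_SECONDARY) & !has_flag(df$flag, FLAG_SUPPL)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df$paired <- has_flag(df$flag, FLAG_PAIRED)
  df$reverse <- has_flag(df$flag, FLAG_REVERSE)
  df$duplicate <- has_flag(df$flag, FLAG_DUP)
  class(df) <- c("mt_reads", "data.frame")
  attr(df, "n_rejected") <- length(rejected)
  df
}

empty_reads <- function() {
  df <- data.frame(qname = character(), flag = integer(), rname = character(),
                   pos = integer(), mapq = integer(), cigar = character(),
                   rnext = character(), pnext = integer(),
                   seq = character(), qual = character(),
                   paired = logical(), reverse = logical(),
                   duplicate = logical(), stringsAsFactors = FALSE)
  class(df) <- c("mt_reads", "data.frame")
  df
}

#' Write an alignment table back out as SAM text
#'
#' @param reads `mt_reads` table.
#' @param ref `circ_ref` used for the `@SQ` header line.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of SAM lines (invisibly when `path` given).
#' @export
write_sam <- function(reads, ref, path = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", ref$name, "\tLN:", ref$length))
  body <- if (nrow(reads) == 0) character(0) else
    paste(reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
          reads$cigar, reads$rnext, reads$pnext, 0L, reads$seq, reads$qual,
          sep = "\t")
  out <- c(hdr, body)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

phred_from_qual <- function(qual) utf8ToInt(qual) - 33L

#' Walk one read's CIGAR into per-position alignment events
#'
#' Converts an aligned read into the event list that drives pileup and
#' calling: one `match_base` event per reference position covered by an
#' M/=/X op (with that base's Phred score), one `insertion` event per I op
#' anchored at the reference base immediately 5' of the inserted sequence,
#' and one `deletion` event per D op starting at the first deleted position.
#' S/H ops consume query/nothing and emit no events; N skips reference like
#' a deletion but emits no event. All positions are circularly normalized.
#' A leading insertion with no 5' anchor inside the read is anchored at the
#' preceding circular position.
#'
#' @param read One-row `mt_reads` (or list with `pos`, `cigar`, `seq`, `qual`).
#' @param ref A `circ_ref`.
#' @return data.frame with columns `kind`, `ref_pos`, `bases`, `del_len`
#'   and list-column `quals` (integer Phred values per base).
#' @export
walk_cigar <- function(read, ref) {
  ops <- explode_cigar(read$cigar)[[1]]
  seq_ch <- strsplit(read$seq, "", fixed = TRUE)[[1]]
  quals <- phred_from_qual(read$qual)
  qi <- 1L                      # query cursor
  rp <- as.numeric(read$pos)    # reference cursor (unnormalized)
  kind <- character(0); ref_pos <- integer(0); bases <- character(0)
  qlist <- list(); del_len <- integer(0)
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      idx <- qi:(qi + len - 1L)
      kind <- c(kind, rep("match_base", len))
      ref_pos <- c(ref_pos, normalize_position(ref, rp + 0:(len - 1)))
      bases <- c(bases, seq_ch[idx])
      qlist <- c(qlist, as.list(quals[idx]))
      del_len <- c(del_len, rep(0L, len))
      qi <- qi + len; rp <- rp + len
    } else if (op == "I") {
      idx <- qi:(qi + len - 1L)
      kind <- c(kind, "insertion")
      ref_pos <- c(ref_pos, normalize_position(ref, rp - 1))  # 5' anchor
      bases <- c(bases, paste(seq_ch[idx], collapse = ""))
      qlist <- c(qlist, list(quals[idx]))
      del_len <- c(del_len, 0L)
      qi <- qi + len
    } else if (op == "D") {
      kind <- c(kind, "deletion")
      ref_pos <- c(ref_pos, normalize_position(ref, rp))
      bases <- c(bases, "")
      qlist <- c(qlist, list(integer(0)))
      del_len <- c(del_len, len)
      rp <- rp + len
    } else if (op == "N") {
      rp <- rp + len            # reference skip, no event
    } else if (op == "S") {
      qi <- qi + len
    }                            # H: consumes nothing
  }
  out <- data.frame(kind = kind, ref_pos = ref_pos, bases = bases,
                    del_len = del_len, stringsAsFactors = FALSE)
  out$quals <- qlist
  out
}

# Unclipped 5' start of a read: leftmost mapped position minus leading
# clips for forward reads; rightmost ref position plus trailing clips for
# reverse reads (the biological 5' end, the duplicate-group key).
unclipped_start <- function(pos, ops, reverse) {
  n <- nrow(ops)
  if (n == 0) return(pos)
  if (!reverse) {
    lead <- 0L
    for (k in seq_len(n)) {
      if (ops$op[k] %in% c("S", "H")) lead <- lead + ops$len[k] else break
    }
    pos - lead
  } else {
    trail <- 0L
    for (k in rev(seq_len(n))) {
      if (ops$op[k] %in% c("S", "H")) trail <- trail + ops$len[k] else break
    }
    pos + cigar_ref_len(ops) - 1L + trail
  }
}

#' Mark PCR duplicates
#'
#' Duplicate removal precedes all allele counting: PCR duplicates replicate
#' one template molecule and would otherwise distort heteroplasmic
#' fractions. Reads are grouped by fragment identity — the unclipped 5'
#' start and orientation of each mate (for pairs, the key combines both
#' mates) — and within each group the record (or pair) with the highest
#' summed base quality keeps its duplicate flag clear; all others are
#' flagged. Ties break deterministically toward the lexicographically
#' smallest query name.
#'
#' @param reads `mt_reads` table.
#' @param pair_sum Sum both mates' qualities when scoring pairs (default
#'   TRUE); per-read scoring otherwise.
#' @return The same table with the `duplicate` column and the 0x400 flag
#'   bit set on duplicates (and cleared on survivors).
#' @export
mark_duplicates <- function(reads, pair_sum = TRUE) {
  n <- nrow(reads)
  if (n == 0) return(reads)
  ops <- explode_cigar(reads$cigar)
  ustart <- vapply(seq_len(n), function(i)
    unclipped_start(reads$pos[i], ops[[i]], reads$reverse[i]), 0L)
  score <- vapply(reads$qual, function(q) sum(phred_from_qual(q)), 0,
                  USE.NAMES = FALSE)
  endkey <- paste0(ustart, ifelse(reads$reverse, "-", "+"))

  paired <- reads$paired
  dup <- logical(n)
  # paired path: join mates by qname
  if (any(paired)) {
    pi <- which(paired)
    sp <- split(pi, reads$qname[pi])
    frag_key <- character(length(sp)); frag_score <- numeric(length(sp))
    frag_name <- names(sp)
    for (j in seq_along(sp)) {
      idx <- sp[[j]]
      ks <- sort(endkey[idx])
      frag_key[j] <- paste(ks, collapse = "|")
      frag_score[j] <- if (pair_sum) sum(score[idx]) else max(score[idx])
    }
    grp <- split(seq_along(sp), frag_key)
    for (g in grp) {
      if (length(g) <= 1) next
      best <- g[order(-frag_score[g], frag_name[g])][1]
      for (j in setdiff(g, best)) dup[sp[[j]]] <- TRUE
    }
  }
  # unpaired path
  if (any(!paired)) {
    ui <- which(!paired)
    grp <- split(ui, endkey[ui])
    for (g in grp) {
      if (length(g) <= 1) next
      best <- g[order(-score[g], reads$qname[g])][1]
      dup[setdiff(g, best)] <- TRUE
    }
  }
  reads$duplicate <- dup
  reads$flag <- ifelse(dup, bitwOr(reads$flag, FLAG_DUP),
                       bitwAnd(reads$flag, bitwNot(FLAG_DUP)))
  reads
}
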