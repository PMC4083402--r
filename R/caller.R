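#' Filter thresholds for variant calling
#'
#' The calling filters: minimum (median) base quality QS >= 25 and minimum
#' read depth rd >= 5 per position, both inclusive; deletions are judged on
#' their 5 bp upstream and downstream flanking regions (median QS >= 25 and
#' median rd >= 5 on each side); mismatches enter the consensus as the
#' alternate base only at heteroplasmic fraction >= 0.75, otherwise as an
#' IUPAC ambiguity code.
#'
#' @param min_qs Minimum median Phred quality (default 25).
#' @param min_rd Minimum read depth (default 5).
#' @param flank_len Flanking window length for deletion evaluation (default 5).
#' @param consensus_hf Consensus substitution threshold (default 0.75).
#' @param min_alt_reads Minimum reads supporting an alternate allele
#'   (default 1).
#' @return List of class `mt_thresholds`.
#' @export
filter_thresholds <- function(min_qs = 25, min_rd = 5L, flank_len = 5L,
                              consensus_hf = 0.75, min_alt_reads = 1L) {
  stopifnot(min_qs >= 0, min_rd >= 0, flank_len >= 0,
            consensus_hf > 0, consensus_hf <= 1, min_alt_reads >= 0)
  structure(list(min_qs = min_qs, min_rd = as.integer(min_rd),
                 flank_len = as.integer(flank_len),
                 consensus_hf = consensus_hf,
                 min_alt_reads = as.integer(min_alt_reads)),
            class = "mt_thresholds")
}

# round to 2 decimals, half away from zero (0.005 -> 0.01)
round_hf <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100

zygosity_of <- function(hf) ifelse(!is.na(hf) & round_hf(hf) == 1,
                                   "homoplasmic", "heteroplasmic")

new_calls <- function(pos = integer(), ref_allele = character(),
                      alt_allele = character(), vtype = character(),
                      alt_depth = integer(), total_depth = integer(),
                      hf = numeric(), median_qs = numeric(),
                      filter_status = character()) {
  data.frame(pos = as.integer(pos), ref_allele = ref_allele,
             alt_allele = alt_allele, vtype = vtype,
             alt_depth = as.integer(alt_depth),
             total_depth = as.integer(total_depth),
             hf = hf, median_qs = median_qs,
             zygosity = zygosity_of(hf), filter_status = filter_status,
             stringsAsFactors = FALSE)
}

#' Call single-base mismatches from a pileup
#'
#' For every position with depth `rd >= min_rd`, every non-reference base
#' supported by at least `min_alt_reads` reads whose median Phred quality
#' is `>= min_qs` yields a PASS call. The heteroplasmic fraction is the
#' variant read depth over the total read depth at the same position.
#' Multi-allelic sites emit one call per alternate base. Positions where
#' the reference base is N are skipped.
#'
#' @param pileup `mt_pileup`.
#' @param ref `circ_ref`.
#' @param th `mt_thresholds` from [filter_thresholds()].
#' @param verbose Also return failing candidates with their failure status.
#' @return Call table (see [filter_thresholds()] for field semantics):
#'   `pos`, `ref_allele`, `alt_allele`, `vtype`, `alt_depth`,
#'   `total_depth`, `hf`, `median_qs`, `zygosity`, `filter_status`.
#' @export
call_mismatches <- function(pileup, ref, th = filter_thresholds(),
                            verbose = FALSE) {
  BASES <- c("A", "C", "G", "T")
  ref_idx <- match(ref$chars, BASES)       # NA for N
  cand <- which(pileup$counts > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) return(new_calls())
  keep <- !is.na(ref_idx[cand[, 1]]) & cand[, 2] != ref_idx[cand[, 1]]
  cand <- cand[keep, , drop = FALSE]
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, 1]; b <- cand[i, 2]
    cnt <- pileup$counts[p, b]
    if (cnt < th$min_alt_reads) next
    rd <- pileup$rd[p]
    med <- stats::median(site_quals(pileup, p, b))
    status <- if (rd < th$min_rd) "fail_rd"
              else if (med < th$min_qs) "fail_qs"
              else "PASS"
    if (status != "PASS" && !verbose) next
    rows[[i]] <- new_calls(p, BASES[ref_idx[p]], BASES[b], "mismatch",
                           cnt, rd, cnt / rd, med, status)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(new_calls())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call insertions
#'
#' An insertion passes when the read depth at its 5' anchor position is
#' `>= min_rd` and the median Phred quality of the inserted bases across
#' supporting reads is `>= min_qs`. Its heteroplasmic fraction is the
#' supporting-read count over the anchor-position depth (the 5' flanking
#' position is the denominator for insertions). The alternate allele is
#' recorded as anchor base plus inserted sequence.
#'
#' @inheritParams call_mismatches
#' @return Call table.
#' @export
call_insertions <- function(pileup, ref, th = filter_thresholds(),
                            verbose = FALSE) {
  ins <- pileup$insertions
  if (nrow(ins) == 0) return(new_calls())
  rows <- vector("list", nrow(ins))
  for (i in seq_len(nrow(ins))) {
    if (ins$support[i] < th$min_alt_reads) next
    a <- ins$anchor_pos[i]
    rd <- ins$anchor_rd[i]
    med <- stats::median(ins$quals[[i]])
    status <- if (rd < th$min_rd) "fail_rd"
              else if (med < th$min_qs) "fail_qs"
              else "PASS"
    if (status != "PASS" && !verbose) next
    anchor_base <- ref$chars[a]
    hf <- if (rd > 0) ins$support[i] / rd else NA_real_
    rows[[i]] <- new_calls(a, anchor_base,
                           paste0(anchor_base, ins$inserted_seq[i]),
                           "insertion", ins$support[i], rd, hf, med, status)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(new_calls())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call deletions
#'
#' The goodness of a deletion is judged on its 5 bp upstream and 5 bp
#' downstream flanking regions (circularly wrapped near the origin): each
#' side must show a median read depth `>= min_rd` and a median quality
#' `>= min_qs` (median over the flank positions of the per-position median
#' QS). The heteroplasmic fraction is the count of reads carrying this
#' deletion over the total depth at its first deleted position.
#'
#' @inheritParams call_mismatches
#' @return Call table; `pos` is the first deleted position, `ref_allele`
#'   the deleted bases, `alt_allele` the empty string.
#' @export
call_deletions <- function(pileup, ref, th = filter_thresholds(),
                           verbose = FALSE) {
  dels <- pileup$deletions
  if (nrow(dels) == 0) return(new_calls())
  rows <- vector("list", nrow(dels))
  for (i in seq_len(nrow(dels))) {
    s <- dels$start[i]; k <- dels$len[i]
    if (k >= ref$length) stop("malformed deletion: length ", k,
                              " >= reference length")
    if (dels$count[i] < th$min_alt_reads) next
    up <- normalize_position(ref, seq(s - th$flank_len, s - 1))
    dn <- normalize_position(ref, seq(s + k, s + k + th$flank_len - 1))
    flank_ok <- function(idx)
      stats::median(pileup$rd[idx]) >= th$min_rd &&
      stats::median(pileup$median_qs[idx]) >= th$min_qs
    rd <- pileup$rd[s]
    status <- if (rd < th$min_rd) "fail_rd"
              else if (!flank_ok(up) || !flank_ok(dn)) "fail_flank"
              else "PASS"
    if (status != "PASS" && !verbose) next
    del_seq <- paste(ref$chars[normalize_position(ref, seq(s, length.out = k))],
                     collapse = "")
    hf <- if (rd > 0) dels$count[i] / rd else NA_real_
    rows[[i]] <- new_calls(s, del_seq, "", "deletion", dels$count[i], rd, hf,
                           stats::median(pileup$median_qs[c(up, dn)]), status)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(new_calls())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call all variant types
#'
#' Convenience wrapper running [call_mismatches()], [call_insertions()] and
#' [call_deletions()] and binding the results.
#'
#' @inheritParams call_mismatches
#' @return Combined call table, ordered by position.
#' @export
call_variants <- function(pileup, ref, th = filter_thresholds(),
                          verbose = FALSE) {
  out <- rbind(call_mismatches(pileup, ref, th, verbose),
               call_insertions(pileup, ref, th, verbose),
               call_deletions(pileup, ref, th, verbose))
  out <- out[order(out$pos, out$vtype, out$alt_allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The eleven heteroplasmic-fraction classes
#'
#' Ordered labels of the eleven HF ranges used for cohort heteroplasmy
#' profiling, from low-level heteroplasmy through quasi-homoplasmy
#' (0.91-0.99) to homoplasmy (1.00).
#'
#' @return Character vector of 11 ordered labels.
#' @export
hf_class_labels <- function() {
  c("≤0.10", "0.11-0.20", "0.21-0.30", "0.31-0.40", "0.41-0.50",
    "0.51-0.60", "0.61-0.70", "0.71-0.80", "0.81-0.90", "0.91-0.99", "1.00")
}

#' Classify heteroplasmic fractions into the eleven HF classes
#'
#' The fraction is rounded to two decimals; a rounded value of 1.00 is
#' homoplasmic, 0.91-0.99 quasi-homoplasmic, and values at or below 0.10
#' fall in the low-level class.
#'
#' @param hf Numeric vector of heteroplasmic fractions in (0, 1], or a call
#'   table with an `hf` column.
#' @return Factor with the ordered levels of [hf_class_labels()].
#' @export
classify_hf <- function(hf) {
  if (is.data.frame(hf)) hf <- hf$hf
  if (any(is.na(hf)) || any(hf <= 0) || any(hf > 1 + 1e-12))
    stop("heteroplasmic fractions must lie in (0, 1]")
  labs <- hf_class_labels()
  cents <- as.integer(floor(hf * 100 + 0.5 + 1e-9))  # rounded to 2 decimals
  idx <- ifelse(cents <= 10L, 1L,
         ifelse(cents == 100L, 11L,
         ifelse(cents >= 91L, 10L, (cents - 11L) %/% 10L + 2L)))
  factor(labs[idx], levels = labs, ordered = TRUE)
}

#' Write PASS calls as VCF 4.2
#'
#' Indels are left-anchored in the usual VCF style: a deletion starting at
#' position s is reported at s-1 with the preceding base prefixed to REF;
#' an insertion anchored at position a is reported at a with
#' ALT = anchor base + inserted sequence. Per-sample fields carry genotype,
#' depths and the heteroplasmic fraction.
#'
#' @param calls Call table (non-PASS rows are dropped).
#' @param sample_id Sample name for the genotype column.
#' @param ref `circ_ref`.
#' @param path Optional output path.
#' @return Character vector of VCF lines (invisibly when `path` given).
#' @export
write_vcf <- function(calls, sample_id, ref, path = NULL) {
  calls <- calls[calls$filter_status == "PASS", , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", ref$name, ",length=", ref$length, ">"),
    "##FILTER=<ID=PASS,Description=\"QS>=25, rd>=5; deletions: flank median QS>=25 and rd>=5\">",
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant type: mismatch, insertion or deletion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (1 homoplasmic, 0/1 heteroplasmic)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth used as HF denominator\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Variant read depth\">",
    "##FORMAT=<ID=HF,Number=1,Type=Float,Description=\"Heteroplasmic fraction\">",
    "##FORMAT=<ID=QS,Number=1,Type=Float,Description=\"Median Phred quality of variant support\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  recs <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    if (v$vtype == "mismatch") {
      pos <- v$pos; REF <- v$ref_allele; ALT <- v$alt_allele
    } else if (v$vtype == "insertion") {
      pos <- v$pos; REF <- v$ref_allele; ALT <- v$alt_allele
    } else { # deletion: left-anchor at preceding base
      anchor <- normalize_position(ref, v$pos - 1)
      pos <- anchor
      REF <- paste0(ref$chars[anchor], v$ref_allele)
      ALT <- ref$chars[anchor]
    }
    gt <- if (v$zygosity == "homoplasmic") "1" else "0/1"
    recs[i] <- paste(ref$name, pos, ".", REF, ALT, ".", "PASS",
                     paste0("VT=", v$vtype), "GT:DP:AD:HF:QS",
                     paste(gt, v$total_depth, v$alt_depth,
                           sprintf("%.6g", v$hf),
                           sprintf("%.6g", v$median_qs), sep = ":"),
                     sep = "\t")
  }
  out <- c(hdr, recs)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Write PASS calls as BED
#'
#' Records use 0-based start and 1-based end coordinates: a mismatch at
#' position p spans (p-1, p); a deletion starting at s of length k spans
#' (s-1, s+k-1); an insertion anchored at a spans (a-1, a). The name field
#' encodes type, alleles and HF.
#'
#' @param calls Call table (non-PASS rows are dropped).
#' @param path Optional output path.
#' @param chrom Chromosome label (default `"chrM"`).
#' @return data.frame of BED fields (written as TSV when `path` given).
#' @export
write_bed <- function(calls, path = NULL, chrom = "chrM") {
  calls <- calls[calls$filter_status == "PASS", , drop = FALSE]
  start <- calls$pos - 1L
  end <- ifelse(calls$vtype == "deletion",
                calls$pos + nchar(calls$ref_allele) - 1L,
                calls$pos)
  name <- paste0(calls$vtype, "|",
                 ifelse(calls$vtype == "deletion",
                        paste0("del", calls$ref_allele),
                        paste0(calls$ref_allele, ">", calls$alt_allele)),
                 "|hf=", sprintf("%.4g", calls$hf))
  bed <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  bed
}

#' Write a call table as TSV
#'
#' @param calls Call table.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(calls)
}
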