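# Small builders used across test files.

sam_line <- function(qname, flag, pos, cigar, seq, qual = NULL, rname = "ref",
                     mapq = 60, rnext = "*", pnext = 0) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))        # Phred 40
  if (is.numeric(qual)) qual <- intToUtf8(qual + 33)
  paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, 0, seq, qual,
        sep = "\t")
}

sam_text <- function(..., ref_name = "ref", ref_len = 100) {
  c(paste0("@SQ\tSN:", ref_name, "\tLN:", ref_len), c(...))
}

# a pileup built directly from handcrafted reads over a given reference
pileup_from_lines <- function(lines, ref, mark = FALSE) {
  reads <- read_sam(sam_text(lines, ref_name = ref$name,
                             ref_len = ref$length), ref = ref)
  if (mark) reads <- mark_duplicates(reads)
  build_pileup(reads, ref)
}

# reads covering pos1..(pos1+len-1) as plain matches with uniform quality
match_reads <- function(n, pos, len, ref, qual = 35, prefix = "r") {
  vapply(seq_len(n), function(i)
    sam_line(paste0(prefix, i), 0, pos,
             paste0(len, "M"),
             substr(ref$sequence, pos, pos + len - 1),
             rep(qual, len), rname = ref$name),
    "")
}

expect_call <- function(calls, pos, vtype, alt = NULL) {
  hit <- calls$pos == pos & calls$vtype == vtype &
    calls$filter_status == "PASS"
  if (!is.null(alt)) hit <- hit & calls$alt_allele == alt
  testthat::expect_true(any(hit),
                        label = paste0("PASS ", vtype, " call at ", pos))
  calls[which(hit)[1], ]
}
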