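# reference of repeated ACGTT; mismatch fixtures are built by stacking
# plain-match reads with controlled alternate bases and qualities
mixed_reads <- function(ref, pos, n_ref, n_alt, alt, q_ref = 35, q_alt = 35,
                        len = 1) {
  c(vapply(seq_len(n_ref), function(i)
      sam_line(paste0("R", i), 0, pos, paste0(len, "M"),
               substr(ref$sequence, pos, pos + len - 1), rep(q_ref, len),
               rname = ref$name), ""),
    vapply(seq_len(n_alt), function(i)
      sam_line(paste0("A", i), 0, pos, paste0(len, "M"), alt,
               rep(q_alt, len), rname = ref$name), ""))
}

test_that("mismatch calls follow the HF formula and inclusive QS/rd thresholds", {
  ref <- circ_ref("ref", strrep("ACGTT", 10))
  # ref=A at pos 1: 15 ref reads + 5 G reads, median alt QS 30 -> hf 5/20
  pu <- pileup_from_lines(mixed_reads(ref, 1, 15, 5, "G", q_alt = 30), ref)
  calls <- call_mismatches(pu, ref)
  v <- expect_call(calls, 1, "mismatch", "G")
  expect_equal(v$hf, 0.25)
  expect_equal(v$alt_depth, 5L)
  expect_equal(v$total_depth, 20L)
  expect_equal(v$zygosity, "heteroplasmic")

  # rd boundary: rd=4 fails, rd=5 passes
  pu4 <- pileup_from_lines(mixed_reads(ref, 1, 2, 2, "G"), ref)
  expect_equal(nrow(call_mismatches(pu4, ref)), 0L)
  v4 <- call_mismatches(pu4, ref, verbose = TRUE)
  expect_equal(v4$filter_status, "fail_rd")
  pu5 <- pileup_from_lines(mixed_reads(ref, 1, 3, 2, "G"), ref)
  expect_equal(call_mismatches(pu5, ref)$filter_status, "PASS")

  # QS boundary: median 24 fails, 25 passes (inclusive)
  pu24 <- pileup_from_lines(mixed_reads(ref, 1, 10, 5, "G", q_alt = 24), ref)
  expect_equal(call_mismatches(pu24, ref, verbose = TRUE)$filter_status,
               "fail_qs")
  pu25 <- pileup_from_lines(mixed_reads(ref, 1, 10, 5, "G", q_alt = 25), ref)
  expect_equal(call_mismatches(pu25, ref)$filter_status, "PASS")

  # reference N positions are skipped
  refN <- circ_ref("ref", paste0("N", strrep("A", 9)))
  puN <- pileup_from_lines(mixed_reads(refN, 1, 10, 5, "G"), refN)
  expect_equal(nrow(call_mismatches(puN, refN)), 0L)
})

test_that("multi-allelic sites emit one call per alternate base", {
  ref <- circ_ref("ref", strrep("A", 20))
  lines <- c(mixed_reads(ref, 3, 10, 6, "G"),
             vapply(1:4, function(i)
               sam_line(paste0("T", i), 0, 3, "1M", "T", 35,
                        rname = ref$name), ""))
  calls <- call_mismatches(pileup_from_lines(lines, ref), ref)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$alt_allele, c("G", "T"))
  expect_equal(sum(calls$alt_depth), 10L)
  expect_equal(unique(calls$total_depth), 20L)
})

test_that("insertion calls use the 5' anchor depth as HF denominator", {
  ref <- circ_ref("ref", strrep("ACGTT", 20))
  ins_lines <- function(n_ins, n_plain, q_ins = 32, pos = 9) c(
    vapply(seq_len(n_ins), function(i)
      sam_line(paste0("i", i), 0, pos, "2M1I2M",
               paste0(substr(ref$sequence, pos, pos + 1), "A",
                      substr(ref$sequence, pos + 2, pos + 3)),
               c(35, 35, q_ins, 35, 35), rname = ref$name), ""),
    match_reads(n_plain, pos, 4, ref, prefix = "p"))

  pu <- pileup_from_lines(ins_lines(6, 54), ref)
  calls <- call_insertions(pu, ref)
  v <- expect_call(calls, 10, "insertion")
  expect_equal(v$hf, 0.10)            # 6 / 60 at the anchor
  expect_equal(v$total_depth, 60L)
  expect_equal(v$alt_allele, paste0(ref$chars[10], "A"))

  # anchor rd below 5 fails
  pu_lo <- pileup_from_lines(ins_lines(3, 1), ref)
  expect_equal(call_insertions(pu_lo, ref, verbose = TRUE)$filter_status,
               "fail_rd")
  # median insertion QS exactly 25 passes; 24 fails
  expect_equal(call_insertions(pileup_from_lines(ins_lines(6, 4, q_ins = 25),
                                                 ref), ref)$filter_status,
               "PASS")
  expect_equal(call_insertions(pileup_from_lines(ins_lines(6, 4, q_ins = 24),
                                                 ref), ref,
                               verbose = TRUE)$filter_status, "fail_qs")
})

test_that("deletion calls gate on both 5-bp flank medians and wrap circularly", {
  ref <- circ_ref("ref", strrep("ACGTT", 40))  # L = 200
  del_lines <- function(n_del, n_plain, q = 33, pos = 96, at = 100,
                        flank_q = 33) c(
    vapply(seq_len(n_del), function(i)
      sam_line(paste0("d", i), 0, pos, "4M2D4M",
               paste0(substr(ref$sequence, pos, pos + 3),
                      substr(ref$sequence, pos + 6, pos + 9)),
               rep(q, 8), rname = ref$name), ""),
    vapply(seq_len(n_plain), function(i)
      sam_line(paste0("p", i), 0, at - 10, "25M",
               substr(ref$sequence, at - 10, at + 14), rep(flank_q, 25),
               rname = ref$name), ""))

  # deletion at 100-101, 50 carriers, no other reads at start -> hf = 1
  pu <- pileup_from_lines(del_lines(50, 0), ref)
  calls <- call_deletions(pu, ref)
  v <- expect_call(calls, 100, "deletion")
  expect_equal(v$hf, 1.0)
  expect_equal(v$zygosity, "homoplasmic")
  expect_equal(nchar(v$ref_allele), 2L)

  # flank quality 24 -> fail_flank
  pu24 <- pileup_from_lines(del_lines(50, 0, q = 24), ref)
  expect_equal(call_deletions(pu24, ref, verbose = TRUE)$filter_status,
               "fail_flank")

  # deletion starting at pos 2: upstream flank wraps to L-3..L, 1
  wrap_lines <- c(
    vapply(1:10, function(i)
      sam_line(paste0("w", i), 0, 1, "1M1D20M",
               paste0(substr(ref$sequence, 1, 1),
                      substr(ref$sequence, 3, 22)), rep(33, 21),
               rname = ref$name), ""),
    vapply(1:10, function(i)
      sam_line(paste0("t", i), 0, 191, "10M",
               substr(ref$sequence, 191, 200), rep(33, 10),
               rname = ref$name), ""))
  puw <- pileup_from_lines(wrap_lines, ref)
  cw <- call_deletions(puw, ref)
  vw <- expect_call(cw, 2, "deletion")
  expect_equal(vw$hf, 1.0)
})

test_that("recomputing hf from the pileup reproduces stored values; thresholds are monotone", {
  ref <- simulate_reference(300, seed = 41)
  planted <- data.frame(
    pos = c(50, 120, 200, 260),
    vtype = c("mismatch", "mismatch", "deletion", "insertion"),
    alt_allele = c(vapply(c(50, 120), function(p)
      setdiff(c("A", "C", "G", "T"), ref$chars[p])[1], ""), "", "C"),
    del_len = c(NA, NA, 3L, NA), target_hf = c(0.3, 0.9, 0.6, 0.45))
  cfg <- simulation_config(planted = planted, read_length = 40,
                           fragment_mean = 100, fragment_sd = 10,
                           target_depth = 60, seed = 42)
  sim <- simulate_reads(ref, cfg)
  pu <- build_pileup(sim$reads, ref)
  calls <- call_variants(pu, ref)
  expect_true(all(calls$alt_depth <= calls$total_depth))
  expect_equal(calls$hf, calls$alt_depth / calls$total_depth)
  for (i in which(calls$vtype == "mismatch")) {
    b <- match(calls$alt_allele[i], c("A", "C", "G", "T"))
    expect_equal(calls$alt_depth[i], unname(pu$counts[calls$pos[i], b]))
    expect_equal(calls$total_depth[i], pu$rd[calls$pos[i]])
  }
  # raising thresholds never adds PASS calls
  base_keys <- call_keys(calls)
  for (th in list(filter_thresholds(min_qs = 30),
                  filter_thresholds(min_rd = 20),
                  filter_thresholds(min_qs = 34, min_rd = 40))) {
    stricter <- call_keys(call_variants(pu, ref, th))
    expect_true(all(stricter %in% base_keys))
  }
})

test_that("HF classes bin rounded fractions into the eleven ranges", {
  expect_equal(as.character(classify_hf(c(0.05, 0.10, 0.11, 0.25, 0.345,
                                          0.95, 0.99, 0.995, 1.0))),
               c("≤0.10", "≤0.10", "0.11-0.20", "0.21-0.30", "0.31-0.40",
                 "0.91-0.99", "0.91-0.99", "1.00", "1.00"))
  # rounding feeds zygosity the same way
  expect_equal(zygosity_of <- mitohet:::zygosity_of(c(0.994, 0.995)),
               c("heteroplasmic", "homoplasmic"))
  expect_error(classify_hf(0), "lie in")
  # every rounded value lands in exactly one class
  hf <- seq(0.01, 1, by = 0.01)
  expect_false(any(is.na(classify_hf(hf))))
  expect_equal(length(levels(classify_hf(hf))), 11L)
})

test_that("VCF writer left-anchors indels and round-trips through VariantAnnotation", {
  skip_if_not_installed("VariantAnnotation")
  ref <- circ_ref("chrM", strrep("ACGTT", 10))
  calls <- rbind(
    new_calls <- mitohet:::new_calls(7, "G", "A", "mismatch", 20, 20, 1.0,
                                     35, "PASS"),
    mitohet:::new_calls(10, "T", "", "deletion", 5, 10, 0.5, 33, "PASS"),
    mitohet:::new_calls(12, "C", "CAA", "insertion", 3, 12, 0.25, 30, "PASS"))
  tmp <- tempfile(fileext = ".vcf")
  write_vcf(calls, "S1", ref, tmp)
  vcf <- VariantAnnotation::readVcf(tmp)
  rr <- SummarizedExperiment::rowRanges(vcf)
  expect_equal(BiocGenerics::start(rr), c(7L, 9L, 12L))
  expect_equal(as.character(rr$REF), c("G", "TT", "C"))
  expect_equal(as.character(unlist(rr$ALT)), c("A", "T", "CAA"))
  hfs <- VariantAnnotation::geno(vcf)$HF
  expect_equal(as.numeric(hfs), c(1.0, 0.5, 0.25))
})

test_that("BED records use 0-based starts and 1-based ends", {
  calls <- rbind(
    mitohet:::new_calls(263, "A", "G", "mismatch", 10, 10, 1.0, 35, "PASS"),
    mitohet:::new_calls(301, "ACT", "", "deletion", 5, 10, 0.5, 33, "PASS"),
    mitohet:::new_calls(310, "C", "CC", "insertion", 3, 12, 0.25, 30, "PASS"))
  bed <- write_bed(calls)
  expect_equal(bed$start, c(262L, 300L, 309L))
  expect_equal(bed$end, c(263L, 303L, 310L))
  expect_match(bed$name[1], "mismatch\\|A>G")
  tmp <- tempfile(fileext = ".bed")
  write_bed(calls, tmp)
  back <- read.table(tmp, sep = "\t")
  expect_equal(back$V2, bed$start)
  expect_equal(back$V3, bed$end)
})
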