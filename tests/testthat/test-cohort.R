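mkcall <- function(pos, vtype = "mismatch", hf = 0.5, ref_allele = "A",
                   alt_allele = "G", sample = "S1") {
  df <- mitohet:::new_calls(pos, ref_allele, alt_allele, vtype,
                            round(hf * 100), 100L, hf, 35, "PASS")
  df$sample <- sample
  df
}

test_that("annotation adds loci, homopolymer/repeat flags and variability", {
  ref <- circ_ref("ref", "ATTTTACCCCGGAGGGTTAA")      # runs incl. wrap AA|A? no
  runs <- find_homopolymers(ref)
  loci <- data.frame(locus = c("geneA", "ctrl"), start = c(2L, 18L),
                     end = c(10L, 3L), klass = c("protein_coding", "control"))
  calls <- rbind(mkcall(5),                              # inside run TTTT? pos 2-5
                 mkcall(11, vtype = "insertion", alt_allele = "GG"),
                 mkcall(12),
                 mkcall(13, vtype = "deletion", alt_allele = "",
                        ref_allele = "AG"),
                 mkcall(2))
  vb <- data.frame(pos = c(5, 11, 12), value = c(0.19, 0.20, 0.5))
  ann <- annotate_calls(calls, loci = loci, homopolymers = runs,
                        repeat_intervals = data.frame(
                          locus = "rep1", start = 11L, end = 12L,
                          klass = "other"),
                        variability = vb, ref = ref)
  expect_equal(ann$locus[1], "geneA")
  expect_equal(ann$locus[5], "geneA,ctrl")   # overlapping loci both reported
  expect_equal(ann$locus[3], "intergenic")
  expect_true(ann$in_homopolymer[1])         # pos 5 in TTTT run (2..5)
  # insertion at anchor 11: anchor 11 not in a run, but 12 starts GG? check
  expect_equal(ann$in_homopolymer[2],
               any(c(11, 12) %in% unlist(lapply(seq_len(nrow(runs)),
                 function(i) homopolymer_positions(ref, runs[i, ])))))
  expect_true(ann$in_repeat[2])
  expect_false(ann$in_repeat[1])
  expect_equal(ann$variability, c(0.19, 0.20, 0.5, NA, NA))
  expect_equal(ann$low_variability, c(TRUE, FALSE, FALSE, NA, NA))
})

test_that("pathogenicity aggregation: inclusive 0.70 score, 'disease' classes, any/all", {
  preds <- data.frame(
    pos = 1:4, ref = "A", alt = "G",
    mutpred_score = c(0.70, 0.69, 0.9, NA),
    polyphen_class = c("neutral", "Disease", "disease", "disease"),
    snpsgo_class = c("neutral", "disease", "disease", NA))
  out <- aggregate_pathogenicity(preds)
  expect_equal(out$damaging_any, c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(out$damaging_all, c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(out$damaging_all <= out$damaging_any))
  expect_error(aggregate_pathogenicity(transform(preds,
                                                 mutpred_score = 1.2)),
               "outside")
})

test_that("sharedness counts carriers and populations; private variants flagged", {
  calls <- rbind(mkcall(100, sample = "S1"), mkcall(100, sample = "S2"),
                 mkcall(100, sample = "S3"), mkcall(200, sample = "S2"))
  pops <- data.frame(sample = c("S1", "S2", "S3"),
                     population = c("P1", "P1", "P2"))
  sh <- sharedness(calls, pops)
  expect_equal(sh$n_samples, c(3L, 1L))
  expect_equal(sh$n_populations, c(2L, 1L))
  expect_equal(sh$shared, c(TRUE, FALSE))
  expect_equal(nrow(sharedness(calls[0, ])), 0L)
})

test_that("locus normalization divides counts by wrap-aware lengths", {
  ref <- circ_ref("ref", strrep("A", 100))
  loci <- data.frame(locus = c("big", "wrap"), start = c(1L, 91L),
                     end = c(50L, 10L), klass = "other")
  calls <- rbind(
    do.call(rbind, lapply(1:10, function(i) mkcall(i, hf = 1))),
    mkcall(95, hf = 0.5))
  nb <- normalize_by_locus(calls, loci, ref)
  big_mm_hom <- nb[nb$locus == "big" & nb$vtype == "mismatch" &
                     nb$zygosity == "homoplasmic", ]
  expect_equal(big_mm_hom$count, 10L)
  expect_equal(big_mm_hom$rate, 10 / 50)
  wrap_row <- nb[nb$locus == "wrap" & nb$zygosity == "heteroplasmic" &
                   nb$vtype == "mismatch", ]
  expect_equal(wrap_row$length, 20L)        # 91..100 plus 1..10
  expect_equal(wrap_row$rate, 1 / 20)
  expect_true("intergenic" %in% nb$locus)
  inter <- nb[nb$locus == "intergenic", ]
  expect_equal(unique(inter$length), 40L)
  # pos 1..10 sit in both 'big' and the wrapped locus: counted in each
  expect_equal(sum(nb$count), 21L)
})

test_that("EBV-coverage classification partitions samples at 0 and >400", {
  ebv <- data.frame(sample = c("a", "b", "c", "d"),
                    ebv_coverage = c(0, 401, 400, 100))
  got <- classify_source(ebv)
  expect_equal(got$label, c("blood", "LCL", "unknown", "unknown"))
  expect_equal(sum(table(got$label)), 4L)  # exactly one label each
  expect_error(classify_source(data.frame(sample = "x", ebv_coverage = -1)),
               "negative")
})

test_that("HF matrix rows sum to per-sample PASS call counts", {
  calls <- rbind(mkcall(1, hf = 1, sample = "S1"),
                 mkcall(2, hf = 1, sample = "S1"),
                 mkcall(3, hf = 0.05, sample = "S1"),
                 mkcall(4, hf = 0.95, sample = "S2"))
  m <- build_hf_matrix(calls, samples = c("S1", "S2", "S3"))
  expect_equal(dim(m), c(3L, 11L))
  expect_equal(unname(m["S1", "1.00"]), 2L)
  expect_equal(unname(m["S1", "≤0.10"]), 1L)
  expect_equal(unname(m["S2", "0.91-0.99"]), 1L)
  expect_equal(unname(rowSums(m)), c(3L, 1L, 0L))
})

test_that("hierarchical clustering is Euclidean, deterministic and permutation-invariant", {
  m <- rbind(a = c(0, 0), b = c(3, 4), c = c(100, 100))
  hc <- hier_cluster(m)
  # first merge joins the two closest rows (distance 5)
  expect_equal(sort(hc$row_tree$merge[1, ]), c(-2, -1))
  expect_equal(hc$row_heights[1], 5)

  # identical rows merge at height 0
  m2 <- rbind(x = c(1, 2), y = c(1, 2), z = c(9, 9))
  expect_equal(hier_cluster(m2)$row_heights[1], 0)

  # permuting rows permutes labels, not topology
  perm <- c(3, 1, 2)
  hcp <- hier_cluster(m[perm, ])
  expect_equal(sort(hc$row_heights), sort(hcp$row_heights))

  expect_warning(one <- hier_cluster(m[1, , drop = FALSE]), "identity")
  expect_equal(one$row_order, 1L)

  skip_if_not_installed("ape")
  nwk <- cluster_newick(hc$row_tree)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("Fisher 2x2 equals hypergeometric enumeration; spec table reproduces", {
  m <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  got <- group_compare(m, mode = "fisher_2x2")
  expect_equal(got$p_value, 0.0028, tolerance = 0.02)
  expect_equal(got$p_value, oracle_fisher_2x2(m), tolerance = 1e-12)

  set.seed(61)
  for (i in 1:50) {
    N <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, N, prob = runif(4, 0.1, 1)))
    mm <- matrix(cells, 2)
    expect_equal(group_compare(mm, mode = "fisher_2x2")$p_value,
                 oracle_fisher_2x2(mm), tolerance = 1e-12,
                 info = paste(cells, collapse = ","))
  }
  expect_error(group_compare(matrix(c(-1, 1, 1, 1), 2), mode = "fisher_2x2"),
               "negative")
})

test_that("t-tests: identical groups give p=1; one-tailed is half of two-tailed in-direction", {
  x <- c(5, 6, 7, 8)
  same <- group_compare(x, x, mode = "t_two_tailed")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  y <- c(1, 2, 3, 4)
  two <- group_compare(x, y, mode = "t_two_tailed")
  one <- group_compare(x, y, mode = "t_one_tailed", alternative = "greater")
  expect_equal(one$p_value, two$p_value / 2)
  expect_error(group_compare(1, y, mode = "t_two_tailed"), "at least 2")

  # degenerate constant identical groups still defined
  cc <- group_compare(c(2, 2, 2), c(2, 2, 2), mode = "t_two_tailed")
  expect_equal(cc$p_value, 1)
})

test_that("Monte-Carlo Fisher is seeded-deterministic and reports replicates", {
  m <- matrix(c(5, 1, 2, 7, 3, 4), nrow = 2)
  a <- group_compare(m, mode = "fisher_rxc_montecarlo", B = 2000, seed = 99)
  b <- group_compare(m, mode = "fisher_rxc_montecarlo", B = 2000, seed = 99)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$B, 2000L)
  exact <- fisher.test(m)$p.value
  expect_equal(a$p_value, exact, tolerance = 0.1)
})
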