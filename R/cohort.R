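#' Annotate calls with loci, homopolymers, repeats and variability
#'
#' Adds to each call: the locus label(s) containing its position
#' (`"intergenic"` when none), whether it falls in a homopolymeric stretch
#' (for insertions, the anchor or the position just 3' of it — an inserted
#' base extending a run belongs to it), whether it overlaps a tandem-repeat
#' interval, and the per-position variability value with a low-variability
#' flag (< 0.20, strict; positions absent from the table get `NA`).
#'
#' @param calls Call table.
#' @param loci Locus table ([read_loci()]); optional.
#' @param homopolymers Run table ([find_homopolymers()]); optional.
#' @param repeat_intervals Optional data.frame with `start`/`end` (1-based
#'   inclusive, wrap allowed) of tandem-repeat regions, or a BED path.
#' @param variability Optional data.frame `pos`, `value` (values in [0,1]),
#'   or a TSV path with those columns.
#' @param ref `circ_ref` (needed for wrap arithmetic on runs/repeats).
#' @return The call table with columns `locus`, `in_homopolymer`,
#'   `in_repeat`, `variability`, `low_variability` added.
#' @export
annotate_calls <- function(calls, loci = NULL, homopolymers = NULL,
                           repeat_intervals = NULL, variability = NULL,
                           ref = NULL) {
  n <- nrow(calls)
  calls$locus <- rep("intergenic", n)
  if (!is.null(loci) && n > 0) {
    calls$locus <- vapply(calls$pos, function(p) {
      hits <- locus_of(loci, p)
      if (length(hits) == 0) "intergenic" else paste(hits, collapse = ",")
    }, "")
  }
  calls$in_homopolymer <- rep(FALSE, n)
  if (!is.null(homopolymers) && nrow(homopolymers) > 0 && n > 0) {
    stopifnot(!is.null(ref))
    run_pos <- unique(unlist(lapply(seq_len(nrow(homopolymers)), function(i)
      homopolymer_positions(ref, homopolymers[i, ]))))
    inrun <- function(p) normalize_position(ref, p) %in% run_pos
    calls$in_homopolymer <- vapply(seq_len(n), function(i) {
      p <- calls$pos[i]
      if (calls$vtype[i] == "insertion") inrun(p) || inrun(p + 1)
      else if (calls$vtype[i] == "deletion")
        any(vapply(seq(p, length.out = nchar(calls$ref_allele[i])), inrun, TRUE))
      else inrun(p)
    }, TRUE)
  }
  calls$in_repeat <- rep(FALSE, n)
  if (!is.null(repeat_intervals) && n > 0) {
    if (is.character(repeat_intervals))
      repeat_intervals <- read_loci(repeat_intervals, format = "bed")
    calls$in_repeat <- vapply(calls$pos, function(p)
      length(locus_of(repeat_intervals, p)) > 0, TRUE)
  }
  calls$variability <- rep(NA_real_, n)
  if (!is.null(variability) && n > 0) {
    if (is.character(variability)) variability <- read_variability(variability)
    calls$variability <- variability$value[match(calls$pos, variability$pos)]
  }
  calls$low_variability <- calls$variability < 0.20
  calls
}

#' Read a per-position variability table
#'
#' TSV with columns `pos` and `value`; values must lie in [0, 1]. Low
#' values suggest a position rarely varies across known genomes (candidate
#' novel haplogroup-defining variant or rare disease-linked mutation).
#'
#' @param path File path.
#' @return data.frame `pos`, `value`.
#' @export
read_variability <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  names(df) <- tolower(names(df))
  if (any(df$value < 0 | df$value > 1))
    stop("variability values must lie in [0, 1]")
  data.frame(pos = as.integer(df$pos), value = as.numeric(df$value))
}

#' Aggregate pathogenicity predictions across tools
#'
#' Combines precomputed pathogenicity outputs: a MutPred-style score in
#' [0, 1] (damaging at score >= 0.70, inclusive) and two categorical
#' classifiers (damaging when the class equals "disease",
#' case-insensitive). `damaging_any` is the OR over the tools present for
#' the row; `damaging_all` is the AND over all three and only TRUE when all
#' three are present and damaging.
#'
#' @param preds data.frame with columns `pos`, `ref`, `alt`,
#'   `mutpred_score`, `polyphen_class`, `snpsgo_class` (score/classes may
#'   be `NA` when a tool produced no output).
#' @return The input with logical columns `mutpred_damaging`,
#'   `polyphen_damaging`, `snpsgo_damaging`, `damaging_any`,
#'   `damaging_all` added. Rows with a score outside [0, 1] are an error.
#' @export
aggregate_pathogenicity <- function(preds) {
  sc <- preds$mutpred_score
  if (any(!is.na(sc) & (sc < 0 | sc > 1)))
    stop("MutPred score outside [0, 1]")
  mp <- !is.na(sc) & sc >= 0.70
  pp <- !is.na(preds$polyphen_class) &
        tolower(preds$polyphen_class) == "disease"
  sg <- !is.na(preds$snpsgo_class) &
        tolower(preds$snpsgo_class) == "disease"
  present <- cbind(!is.na(sc), !is.na(preds$polyphen_class),
                   !is.na(preds$snpsgo_class))
  if (any(rowSums(present) == 0))
    stop("row(s) with no tool output at all")
  dmg <- cbind(mp, pp, sg)
  preds$mutpred_damaging <- mp
  preds$polyphen_damaging <- pp
  preds$snpsgo_damaging <- sg
  preds$damaging_any <- rowSums(dmg & present) > 0
  preds$damaging_all <- rowSums(dmg) == 3L & rowSums(present) == 3L
  preds
}

#' Per-variant sharedness across a cohort
#'
#' Counts, for every distinct variant (position, alleles, type), how many
#' samples carry it and — when population metadata is given — how many
#' populations those carriers span. Variants seen in a single sample are
#' flagged non-shared (private).
#'
#' @param cohort_calls Call table with a `sample` column (PASS calls of all
#'   samples bound together).
#' @param populations Optional data.frame `sample`, `population`.
#' @return data.frame keyed by `pos`, `ref_allele`, `alt_allele`, `vtype`
#'   with `n_samples`, `n_populations` (NA without metadata) and `shared`.
#' @export
sharedness <- function(cohort_calls, populations = NULL) {
  if (nrow(cohort_calls) == 0)
    return(data.frame(pos = integer(), ref_allele = character(),
                      alt_allele = character(), vtype = character(),
                      n_samples = integer(), n_populations = integer(),
                      shared = logical(), stringsAsFactors = FALSE))
  key <- paste(cohort_calls$pos, cohort_calls$ref_allele,
               cohort_calls$alt_allele, cohort_calls$vtype, sep = "\r")
  grp <- split(seq_len(nrow(cohort_calls)), key)
  rows <- lapply(grp, function(idx) {
    first <- cohort_calls[idx[1], ]
    samples <- unique(cohort_calls$sample[idx])
    npop <- if (is.null(populations)) NA_integer_ else
      length(unique(populations$population[
        match(samples, populations$sample)]))
    data.frame(pos = first$pos, ref_allele = first$ref_allele,
               alt_allele = first$alt_allele, vtype = first$vtype,
               n_samples = length(samples), n_populations = npop,
               shared = length(samples) > 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$vtype, out$alt_allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locus-length-normalized variant rates
#'
#' For every locus (plus an intergenic bucket) and every zygosity x
#' variant-type category: the raw call count and the count divided by the
#' locus length in bp (wrap-around loci use their true wrapped length).
#' Length normalization removes the trivial dependence of counts on locus
#' size when comparing mutational burden across loci.
#'
#' @param calls Call table (annotate first, or pass `loci` to annotate here).
#' @param loci Locus table.
#' @param ref `circ_ref` (for wrapped lengths and intergenic size).
#' @return data.frame `locus`, `klass`, `length`, `zygosity`, `vtype`,
#'   `count`, `rate`.
#' @export
normalize_by_locus <- function(calls, loci, ref) {
  L <- ref$length
  len <- locus_length(loci, L)
  if (any(len <= 0)) stop("zero-length locus")
  covered <- unique(unlist(lapply(seq_len(nrow(loci)), function(i) {
    if (loci$start[i] <= loci$end[i]) loci$start[i]:loci$end[i]
    else c(loci$start[i]:L, 1:loci$end[i])
  })))
  inter_len <- L - length(covered)
  tab <- data.frame(locus = c(loci$locus, "intergenic"),
                    klass = c(loci$klass, "intergenic"),
                    length = c(len, inter_len), stringsAsFactors = FALSE)
  cats <- expand.grid(zygosity = c("homoplasmic", "heteroplasmic"),
                      vtype = c("mismatch", "insertion", "deletion"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    inside <- if (tab$locus[i] == "intergenic") {
      vapply(calls$pos, function(p) length(locus_of(loci, p)) == 0, TRUE)
    } else {
      li <- loci[loci$locus == tab$locus[i], , drop = FALSE]
      vapply(calls$pos, function(p) length(locus_of(li, p)) > 0, TRUE)
    }
    if (nrow(calls) == 0) inside <- logical(0)
    cbind(tab[i, , drop = FALSE][rep(1, nrow(cats)), ], cats,
          count = vapply(seq_len(nrow(cats)), function(k)
            sum(inside & calls$zygosity == cats$zygosity[k] &
                  calls$vtype == cats$vtype[k]), 0L))
  })
  out <- do.call(rbind, rows)
  out$rate <- out$count / out$length
  rownames(out) <- NULL
  out
}

#' Classify DNA source from EBV coverage
#'
#' Lymphoblastoid cell lines are EBV-transformed, so reads mapping to the
#' EBV genome betray LCL-derived DNA: coverage 0 is labeled blood, coverage
#' above 400 (strict) LCL, anything between is left unknown.
#'
#' @param ebv data.frame with `sample` and `ebv_coverage` columns (or a TSV
#'   path).
#' @return data.frame `sample`, `ebv_coverage`, `label`.
#' @export
classify_source <- function(ebv) {
  if (is.character(ebv))
    ebv <- utils::read.table(ebv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (any(ebv$ebv_coverage < 0)) stop("negative EBV coverage")
  label <- ifelse(ebv$ebv_coverage == 0, "blood",
                  ifelse(ebv$ebv_coverage > 400, "LCL", "unknown"))
  data.frame(sample = ebv$sample, ebv_coverage = ebv$ebv_coverage,
             label = label, stringsAsFactors = FALSE)
}

#' Sample-by-HF-class count matrix
#'
#' Counts each sample's PASS calls in the eleven heteroplasmic-fraction
#' classes. Row sums equal per-sample call counts; samples named in
#' `samples` but absent from the calls get zero rows.
#'
#' @param cohort_calls Call table with a `sample` column.
#' @param samples Optional character vector fixing the row set/order.
#' @return Integer matrix, rows samples, columns [hf_class_labels()].
#' @export
build_hf_matrix <- function(cohort_calls, samples = NULL) {
  labs <- hf_class_labels()
  if (is.null(samples)) samples <- sort(unique(cohort_calls$sample))
  m <- matrix(0L, nrow = length(samples), ncol = length(labs),
              dimnames = list(samples, labs))
  keep <- cohort_calls$filter_status == "PASS" &
          cohort_calls$sample %in% samples
  cc <- cohort_calls[keep, , drop = FALSE]
  if (nrow(cc) > 0) {
    cls <- classify_hf(cc$hf)
    tb <- table(factor(cc$sample, levels = samples), cls)
    m[rownames(tb), colnames(tb)] <- m[rownames(tb), colnames(tb)] +
      unclass(tb)
  }
  m
}

#' Hierarchical clustering of the HF-class matrix
#'
#' Agglomerative clustering with Euclidean distance (complete linkage by
#' default, the convention of the base heatmap stack) on both rows
#' (samples) and columns (HF classes). Output is deterministic; a
#' single-row matrix yields the identity ordering with a warning.
#'
#' @param m Numeric matrix (samples x HF classes).
#' @param method Linkage: `"complete"` (default), `"average"` or
#'   `"single"`.
#' @return List with `row_order`, `col_order`, `row_tree`, `col_tree`
#'   (`hclust` objects or NULL), `row_heights`, `col_heights`.
#' @export
hier_cluster <- function(m, method = c("complete", "average", "single")) {
  method <- match.arg(method)
  cl1 <- function(x) {
    if (nrow(x) < 2) {
      warning("fewer than 2 rows: identity ordering")
      return(NULL)
    }
    stats::hclust(stats::dist(x, method = "euclidean"), method = method)
  }
  rt <- cl1(m)
  ct <- cl1(t(m))
  list(row_order = if (is.null(rt)) seq_len(nrow(m)) else rt$order,
       col_order = if (is.null(ct)) seq_len(ncol(m)) else ct$order,
       row_tree = rt, col_tree = ct,
       row_heights = if (is.null(rt)) numeric(0) else rt$height,
       col_heights = if (is.null(ct)) numeric(0) else ct$height)
}

#' Export a cluster tree as Newick text
#'
#' @param tree An `hclust` object (from [hier_cluster()]).
#' @return Newick string with merge heights as branch lengths.
#' @export
cluster_newick <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  ape::write.tree(ape::as.phylo(tree))
}

#' Group comparison statistics
#'
#' Blood/LCL-style comparisons: Welch t-tests (one- or two-tailed) on
#' per-sample variant counts, an exact Fisher test for 2x2 tables, and a
#' seeded Monte-Carlo Fisher test for r x c tables.
#'
#' @param x For t modes, numeric vector of group A counts; for Fisher
#'   modes, the contingency matrix.
#' @param y Group B counts (t modes only).
#' @param mode One of `"t_two_tailed"`, `"t_one_tailed"`, `"fisher_2x2"`,
#'   `"fisher_rxc_montecarlo"`.
#' @param alternative Direction for the one-tailed t-test (`"greater"`:
#'   mean of `x` exceeds mean of `y`).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param B Monte-Carlo replicates for the r x c Fisher (default 10000).
#' @param seed Seed for the Monte-Carlo Fisher (required for
#'   reproducibility there, ignored otherwise).
#' @return List with `statistic`, `p_value`, `method` and (Monte-Carlo
#'   mode) `B`.
#' @export
group_compare <- function(x, y = NULL,
                          mode = c("t_two_tailed", "t_one_tailed",
                                   "fisher_2x2", "fisher_rxc_montecarlo"),
                          alternative = c("greater", "less"),
                          var_equal = FALSE, B = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("t_two_tailed", "t_one_tailed")) {
    if (length(x) < 2 || length(y) < 2)
      stop("t-test requires at least 2 observations per group")
    alt <- if (mode == "t_two_tailed") "two.sided" else match.arg(alternative)
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      # degenerate identical groups: no variance, no difference
      return(list(statistic = 0,
                  p_value = if (alt == "two.sided") 1 else 0.5,
                  method = paste0(if (var_equal) "pooled" else "Welch",
                                  " t-test (", alt, ")")))
    }
    tt <- stats::t.test(x, y, alternative = alt, var.equal = var_equal)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         method = paste0(if (var_equal) "pooled" else "Welch",
                         " t-test (", alt, ")"))
  } else if (mode == "fisher_2x2") {
    if (!is.matrix(x) || any(dim(x) != 2)) stop("fisher_2x2 needs a 2x2 matrix")
    if (any(x < 0)) stop("negative cell in contingency table")
    ft <- stats::fisher.test(x)
    list(statistic = unname(ft$estimate), p_value = ft$p.value,
         method = "Fisher exact test (2x2, two-sided)")
  } else {
    if (!is.matrix(x)) stop("fisher_rxc_montecarlo needs a matrix")
    if (any(x < 0)) stop("negative cell in contingency table")
    if (!is.null(seed)) set.seed(seed)
    ft <- stats::fisher.test(x, simulate.p.value = TRUE, B = B)
    list(statistic = NA_real_, p_value = ft$p.value,
         method = "Fisher test (r x c, Monte-Carlo)", B = as.integer(B))
  }
}
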