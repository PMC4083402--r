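#' Simulate a circular reference sequence
#'
#' Seeded pseudo-random nucleotide sequence with a requested GC fraction;
#' the default mirrors the base composition of the human mitochondrial
#' genome (about 44% GC).
#'
#' @param length Sequence length (>= 100).
#' @param seed Integer seed.
#' @param gc_fraction Fraction of G+C bases (default 0.44).
#' @return A `circ_ref`.
#' @export
simulate_reference <- function(length, seed = 1L, gc_fraction = 0.44) {
  if (length < 100) stop("reference length must be >= 100")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  circ_ref("sim_mt", paste(sample(names(p), length, replace = TRUE, prob = p),
                           collapse = ""))
}

#' Simulation configuration
#'
#' Bundles the read-simulation parameters: planted variants with their
#' target heteroplasmic fractions (each fragment carries each variant
#' independently with probability `target_hf` — a haplotype mixture at the
#' fragment level, so both mates agree), read and fragment geometry,
#' target depth, a Gaussian Phred-quality model, a per-base sequencing
#' error rate, and a PCR duplicate rate (that fraction of fragments is
#' emitted twice with duplicate-eligible coordinates).
#'
#' @param planted data.frame with columns `pos` (1-based), `vtype`
#'   (`mismatch`/`insertion`/`deletion`), `alt_allele` (mismatch: the
#'   alternate base; insertion: the inserted sequence, anchor excluded;
#'   deletion: ignored), `del_len` (deletions only) and `target_hf` in
#'   (0, 1]. Planted indels must not overlap each other.
#' @param read_length Read length in bp (default 100).
#' @param fragment_mean,fragment_sd Fragment length distribution (default
#'   250 +/- 30; fragments are clamped to hold a full read after any
#'   planted deletion).
#' @param target_depth Expected mean per-base depth (default 100).
#' @param qs_mean,qs_sd,qs_floor Phred quality model (default 33 +/- 3,
#'   floor 2, cap 40).
#' @param duplicate_rate Fraction of fragments emitted twice (default 0).
#' @param error_rate Per-base substitution error rate (default 0); errors
#'   lower the base's Phred score, never raise it.
#' @param seed Integer seed.
#' @return List of class `mt_simconfig`.
#' @export
simulation_config <- function(planted = NULL, read_length = 100L,
                              fragment_mean = 250, fragment_sd = 30,
                              target_depth = 100, qs_mean = 33, qs_sd = 3,
                              qs_floor = 2L, duplicate_rate = 0,
                              error_rate = 0, seed = 1L) {
  if (is.null(planted))
    planted <- data.frame(pos = integer(), vtype = character(),
                          alt_allele = character(), del_len = integer(),
                          target_hf = numeric(), stringsAsFactors = FALSE)
  if (!"del_len" %in% names(planted)) planted$del_len <- NA_integer_
  stopifnot(read_length <= fragment_mean,
            duplicate_rate >= 0, duplicate_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            all(planted$target_hf > 0), all(planted$target_hf <= 1))
  # non-overlap of planted indels
  iv <- planted[planted$vtype != "mismatch", , drop = FALSE]
  if (nrow(iv) > 1) {
    span <- lapply(seq_len(nrow(iv)), function(i)
      if (iv$vtype[i] == "deletion") iv$pos[i]:(iv$pos[i] + iv$del_len[i] - 1L)
      else iv$pos[i])
    if (any(duplicated(unlist(span))))
      stop("planted indels overlap")
  }
  structure(list(planted = planted, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 target_depth = target_depth, qs_mean = qs_mean,
                 qs_sd = qs_sd, qs_floor = as.integer(qs_floor),
                 duplicate_rate = duplicate_rate, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "mt_simconfig")
}

# Build haplotype char/ref-pos vectors for one fragment and cut read
# windows out of it; returns per-read pos/cigar/seq plus realized-variant
# bookkeeping. edits rows are the carried variants, fully inside the
# fragment.
.frag_with_indels <- function(ref, start, flen, edits, rl) {
  chars <- ref$chars[start:(start + flen - 1L)]
  refpos <- start:(start + flen - 1L)
  # apply 3' to 5' so earlier coordinates stay valid
  edits <- edits[order(-edits$pos), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    k <- e$pos - start + 1L
    if (e$vtype == "mismatch") {
      chars[k] <- e$alt_allele
    } else if (e$vtype == "deletion") {
      drop <- k:(k + e$del_len - 1L)
      chars <- chars[-drop]; refpos <- refpos[-drop]
    } else { # insertion after anchor pos
      ins <- strsplit(e$alt_allele, "", fixed = TRUE)[[1]]
      chars <- append(chars, ins, after = k)
      refpos <- append(refpos, rep(NA_integer_, length(ins)), after = k)
    }
  }
  H <- length(chars)
  windows <- list(1:rl, (H - rl + 1L):H)
  out <- vector("list", 2)
  for (w in 1:2) {
    idx <- windows[[w]]
    wch <- chars[idx]; wrp <- refpos[idx]
    pos <- wrp[which(!is.na(wrp))[1]]
    # CIGAR from the ref-pos structure: NA -> I, gaps between consecutive
    # mapped positions -> D, mapped -> M
    ops <- character(0); lens <- integer(0)
    push <- function(op, len) {
      if (length(ops) > 0 && ops[length(ops)] == op) {
        lens[length(lens)] <<- lens[length(lens)] + len
      } else {
        ops <<- c(ops, op); lens <<- c(lens, len)
      }
    }
    prev_rp <- NA_integer_
    for (j in seq_along(wrp)) {
      if (is.na(wrp[j])) push("I", 1L)
      else {
        if (!is.na(prev_rp) && wrp[j] - prev_rp > 1L)
          push("D", wrp[j] - prev_rp - 1L)
        push("M", 1L)
        prev_rp <- wrp[j]
      }
    }
    out[[w]] <- list(pos = pos, cigar = paste0(lens, ops, collapse = ""),
                     seq = paste(wch, collapse = ""),
                     fp_end = max(wrp, na.rm = TRUE),
                     del_spans = {
                       mapped <- wrp[!is.na(wrp)]
                       d <- diff(mapped); s <- which(d > 1)
                       if (length(s) == 0) NULL
                       else cbind(mapped[s] + 1L, mapped[s + 1L] - 1L)
                     },
                     ins_anchors = {
                       ia <- which(is.na(wrp))
                       # anchor = previous mapped position
                       if (length(ia) == 0) integer(0)
                       else unique(vapply(ia, function(j) {
                         prev <- wrp[seq_len(j - 1L)]
                         prev <- prev[!is.na(prev)]
                         if (length(prev) == 0) NA_integer_
                         else prev[length(prev)]
                       }, 0L))
                     })
  }
  out
}

#' Simulate paired-end reads from a heteroplasmic mixture
#'
#' Fragments are placed uniformly on the circle (origin-spanning fragments
#' are resampled to keep standard linear SAM records); each fragment
#' independently carries each planted variant with probability
#' `target_hf`; paired 100%-overlap-free mates are cut from the fragment
#' ends with correct flags, positions and CIGAR strings (insertions and
#' deletions become I/D operations). Phred qualities follow the Gaussian
#' model; sequencing errors substitute a random other base and lower the
#' Phred score. The duplicate fraction of fragments is emitted twice. The
#' truth table reports, per planted variant, the carrier-fragment count
#' and the realized supporting/covering read counts over distinct
#' fragments (duplicate copies excluded), whose ratio is the realized
#' heteroplasmic fraction.
#'
#' @param ref `circ_ref`.
#' @param config `mt_simconfig` from [simulation_config()].
#' @return List with `reads` (`mt_reads` table), `sam` (SAM text lines)
#'   and `truth` (data.frame `pos`, `vtype`, `ref_allele`, `alt_allele`,
#'   `target_hf`, `n_carrier_fragments`, `support`, `cover`,
#'   `realized_hf`).
#' @export
simulate_reads <- function(ref, config) {
  cf <- config
  set.seed(cf$seed)
  L <- ref$length; rl <- cf$read_length
  if (cf$target_depth <= 0) stop("target depth must be positive")
  pv <- cf$planted
  nv <- nrow(pv)
  if (nv > 0 && any(pv$pos < 1 | pv$pos > L))
    stop("planted variant position outside reference")
  # derive reference alleles
  if (nv > 0) {
    pv$ref_allele <- vapply(seq_len(nv), function(i) {
      if (pv$vtype[i] == "deletion")
        paste(ref$chars[normalize_position(ref, seq(pv$pos[i],
              length.out = pv$del_len[i]))], collapse = "")
      else ref$chars[pv$pos[i]]
    }, "")
  }
  maxdel <- if (nv > 0 && any(pv$vtype == "deletion"))
    max(pv$del_len[pv$vtype == "deletion"]) else 0L
  n_frag <- max(1L, as.integer(round(L * cf$target_depth / (2 * rl))))
  flen <- as.integer(round(stats::rnorm(n_frag, cf$fragment_mean,
                                        cf$fragment_sd)))
  flen <- pmin(pmax(flen, rl + maxdel), L - 1L)
  start <- as.integer(floor(stats::runif(n_frag) * (L - flen + 1))) + 1L
  end <- start + flen - 1L

  carried <- matrix(FALSE, nrow = n_frag, ncol = max(nv, 1L))
  if (nv > 0) {
    for (v in seq_len(nv)) {
      carrier <- stats::runif(n_frag) < pv$target_hf[v]
      contain <- switch(pv$vtype[v],
        mismatch  = start <= pv$pos[v] & end >= pv$pos[v],
        insertion = start <= pv$pos[v] & end > pv$pos[v],
        deletion  = start <= pv$pos[v] &
                    end >= pv$pos[v] + pv$del_len[v] - 1L)
      carried[, v] <- carrier & contain
    }
  }
  indel_v <- if (nv > 0) which(pv$vtype != "mismatch") else integer(0)
  has_indel <- if (length(indel_v) > 0)
    rowSums(carried[, indel_v, drop = FALSE]) > 0 else rep(FALSE, n_frag)

  # per-read columns, reads 2*f-1 / 2*f are the mates of fragment f
  n_reads <- 2L * n_frag
  rpos <- integer(n_reads); rcigar <- character(n_reads)
  rseq <- character(n_reads); fp_end <- integer(n_reads)
  frag_of <- rep(seq_len(n_frag), each = 2L)
  # realized indel events per read (lists indexed by variant)
  ins_reads <- vector("list", max(nv, 1L))
  del_reads <- vector("list", max(nv, 1L))

  simple <- which(!has_indel)
  if (length(simple) > 0) {
    i1 <- 2L * simple - 1L; i2 <- 2L * simple
    rpos[i1] <- start[simple]
    rpos[i2] <- end[simple] - rl + 1L
    rcigar[c(i1, i2)] <- paste0(rl, "M")
    rseq[i1] <- substring(ref$sequence, start[simple],
                          start[simple] + rl - 1L)
    rseq[i2] <- substring(ref$sequence, end[simple] - rl + 1L, end[simple])
    fp_end[i1] <- start[simple] + rl - 1L
    fp_end[i2] <- end[simple]
    # apply carried mismatches inside the read windows
    if (nv > 0) for (v in which(pv$vtype == "mismatch")) {
      fc <- simple[carried[simple, v]]
      if (length(fc) == 0) next
      for (rgroup in list(2L * fc - 1L, 2L * fc)) {
        off <- pv$pos[v] - rpos[rgroup] + 1L
        hit <- off >= 1L & off <= rl
        if (any(hit)) {
          idx <- rgroup[hit]
          substring(rseq[idx], off[hit], off[hit]) <- pv$alt_allele[v]
        }
      }
    }
  }
  for (f in which(has_indel)) {
    edits <- pv[carried[f, ], , drop = FALSE]
    rr <- .frag_with_indels(ref, start[f], flen[f], edits, rl)
    for (w in 1:2) {
      ri <- 2L * f - 2L + w
      rpos[ri] <- rr[[w]]$pos
      rcigar[ri] <- rr[[w]]$cigar
      rseq[ri] <- rr[[w]]$seq
      fp_end[ri] <- rr[[w]]$fp_end
      # which planted indels were realized in this read
      if (!is.null(rr[[w]]$del_spans)) for (v in indel_v) {
        if (pv$vtype[v] == "deletion" &&
            any(rr[[w]]$del_spans[, 1] == pv$pos[v] &
                rr[[w]]$del_spans[, 2] == pv$pos[v] + pv$del_len[v] - 1L))
          del_reads[[v]] <- c(del_reads[[v]], ri)
      }
      if (length(rr[[w]]$ins_anchors) > 0) for (v in indel_v) {
        if (pv$vtype[v] == "insertion" &&
            pv$pos[v] %in% rr[[w]]$ins_anchors)
          ins_reads[[v]] <- c(ins_reads[[v]], ri)
      }
    }
  }

  # duplicates: re-emit a fraction of fragments (same coordinates/alleles,
  # fresh qualities and errors)
  n_dup <- as.integer(round(cf$duplicate_rate * n_frag))
  dup_frags <- if (n_dup > 0) sort(sample.int(n_frag, n_dup)) else integer(0)
  dup_reads <- as.vector(rbind(2L * dup_frags - 1L, 2L * dup_frags))
  all_idx <- c(seq_len(n_reads), dup_reads)
  is_dup_copy <- c(rep(FALSE, n_reads), rep(TRUE, length(dup_reads)))
  nr_tot <- length(all_idx)

  # qualities and sequencing errors over the emitted reads
  q <- as.integer(round(stats::rnorm(nr_tot * rl, cf$qs_mean, cf$qs_sd)))
  q <- pmin(pmax(q, cf$qs_floor), 40L)
  seqs <- rseq[all_idx]
  if (cf$error_rate > 0) {
    chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
    err <- which(stats::runif(length(chars)) < cf$error_rate)
    if (length(err) > 0) {
      BASES <- c("A", "C", "G", "T")
      for (k in err) {
        chars[k] <- sample(setdiff(BASES, chars[k]), 1)
      }
      q[err] <- pmax(q[err] - 20L, cf$qs_floor)
      seqs <- vapply(split(chars, rep(seq_len(nr_tot), each = rl)),
                     paste, "", collapse = "")
      seqs <- unname(seqs[order(as.integer(names(seqs)))])
    }
  }
  quals <- vapply(seq_len(nr_tot), function(i)
    intToUtf8(q[((i - 1L) * rl + 1L):(i * rl)] + 33L), "")

  mate1 <- all_idx %% 2L == 1L
  flag <- ifelse(mate1,
                 FLAG_PAIRED + FLAG_PROPER + FLAG_MREVERSE + FLAG_READ1,
                 FLAG_PAIRED + FLAG_PROPER + FLAG_REVERSE + FLAG_READ2)
  frag_id <- frag_of[all_idx]
  qname <- sprintf("frag%06d%s", frag_id, ifelse(is_dup_copy, "_dup", ""))
  mate_idx <- ifelse(mate1, all_idx + 1L, all_idx - 1L)
  reads <- data.frame(qname = qname, flag = as.integer(flag),
                      rname = ref$name, pos = rpos[all_idx],
                      mapq = 60L, cigar = rcigar[all_idx],
                      rnext = "=", pnext = rpos[mate_idx],
                      seq = seqs, qual = quals, stringsAsFactors = FALSE)
  reads$paired <- TRUE
  reads$reverse <- !mate1
  reads$duplicate <- FALSE
  class(reads) <- c("mt_reads", "data.frame")

  # truth table over distinct fragments (original copies only)
  truth <- if (nv == 0) {
    data.frame(pos = integer(), vtype = character(),
               ref_allele = character(), alt_allele = character(),
               target_hf = numeric(), n_carrier_fragments = integer(),
               support = integer(), cover = integer(),
               realized_hf = numeric(), stringsAsFactors = FALSE)
  } else {
    rows <- lapply(seq_len(nv), function(v) {
      site <- pv$pos[v]
      covering <- which(rpos <= site & fp_end >= site)
      support <- switch(pv$vtype[v],
        mismatch = sum(carried[frag_of[covering], v]),
        deletion = length(del_reads[[v]]),
        insertion = length(ins_reads[[v]]))
      data.frame(pos = site, vtype = pv$vtype[v],
                 ref_allele = pv$ref_allele[v],
                 alt_allele = if (pv$vtype[v] == "deletion") ""
                              else pv$alt_allele[v],
                 target_hf = pv$target_hf[v],
                 n_carrier_fragments = sum(carried[, v]),
                 support = as.integer(support),
                 cover = length(covering),
                 realized_hf = if (length(covering) > 0)
                   support / length(covering) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  list(reads = reads, sam = write_sam(reads, ref), truth = truth)
}

#' Simulate a cohort of samples drawn from synthetic haplogroups
#'
#' Generates (or accepts) a haplogroup definitions table, assigns each
#' sample a haplogroup, plants its defining sites as homoplasmic
#' mismatches plus optional private heteroplasmies at unused positions,
#' simulates reads per sample, and emits population/gender/EBV-coverage
#' metadata so cohort analytics can be exercised end to end.
#'
#' @param n_samples Number of samples (default 20).
#' @param ref Optional `circ_ref` (default: simulated, 1000 bp).
#' @param haplogroup_defs Optional definitions table
#'   ([read_haplogroup_defs()] layout); generated when NULL.
#' @param n_haplogroups,sites_per_hg Synthetic tree size when generating
#'   definitions (defaults 5 and 10).
#' @param n_private Private heteroplasmic mismatches per sample (default 2).
#' @param depth,read_length Simulation geometry per sample.
#' @param seed Integer seed.
#' @param dir Optional directory: per-sample SAM files plus `metadata.tsv`,
#'   `truth.tsv` and `haplogroup_defs.tsv` are written there.
#' @return List with `ref`, `definitions`, `samples` (per-sample list of
#'   `reads`/`sam`/`truth`/`haplogroup`), and `metadata` data.frame
#'   (`sample`, `haplogroup`, `population`, `gender`, `ebv_coverage`).
#' @export
make_fixture_cohort <- function(n_samples = 20L, ref = NULL,
                                haplogroup_defs = NULL, n_haplogroups = 5L,
                                sites_per_hg = 10L, n_private = 2L,
                                depth = 50, read_length = 60L, seed = 1L,
                                dir = NULL) {
  set.seed(seed)
  if (is.null(ref)) ref <- simulate_reference(1000L, seed = seed + 7L)
  L <- ref$length
  # keep planted sites clear of the genome edges: origin-spanning
  # fragments are rejected, so coverage ramps up over about two read
  # lengths at either end
  margin <- min(2L * read_length + 10L, L %/% 4L)
  if (is.null(haplogroup_defs)) {
    need <- n_haplogroups * sites_per_hg
    sites <- sample((margin + 1L):(L - margin), need)
    haplogroup_defs <- do.call(rbind, lapply(seq_len(n_haplogroups),
      function(h) {
        p <- sites[((h - 1L) * sites_per_hg + 1L):(h * sites_per_hg)]
        data.frame(haplogroup = paste0("HG", h), position = p,
                   derived_allele = vapply(p, function(pp)
                     sample(setdiff(c("A", "C", "G", "T"),
                                    ref$chars[pp]), 1), ""),
                   stringsAsFactors = FALSE)
      }))
  }
  used <- unique(haplogroup_defs$position)
  hgs <- unique(haplogroup_defs$haplogroup)
  samples <- vector("list", n_samples)
  meta <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    hg <- hgs[(s - 1L) %% length(hgs) + 1L]
    d <- haplogroup_defs[haplogroup_defs$haplogroup == hg, , drop = FALSE]
    planted <- data.frame(pos = d$position, vtype = "mismatch",
                          alt_allele = d$derived_allele,
                          del_len = NA_integer_, target_hf = 1,
                          stringsAsFactors = FALSE)
    if (n_private > 0) {
      free <- setdiff(seq(margin + 1L, L - margin), used)
      pp <- sample(free, n_private)
      planted <- rbind(planted, data.frame(
        pos = pp, vtype = "mismatch",
        alt_allele = vapply(pp, function(x)
          sample(setdiff(c("A", "C", "G", "T"), ref$chars[x]), 1), ""),
        del_len = NA_integer_,
        target_hf = stats::runif(n_private, 0.05, 0.6),
        stringsAsFactors = FALSE))
    }
    cfg <- simulation_config(planted = planted, read_length = read_length,
                             fragment_mean = max(2 * read_length, 150),
                             fragment_sd = 20, target_depth = depth,
                             seed = seed + 1000L + s)
    sim <- simulate_reads(ref, cfg)
    sim$haplogroup <- hg
    samples[[s]] <- sim
    meta[[s]] <- data.frame(
      sample = sprintf("S%03d", s), haplogroup = hg,
      population = paste0("POP_", hg),
      gender = sample(c("female", "male"), 1),
      ebv_coverage = if (s %% 2 == 0) 0 else round(stats::runif(1, 401, 1200)),
      stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta)
  names(samples) <- metadata$sample
  out <- list(ref = ref, definitions = haplogroup_defs, samples = samples,
              metadata = metadata)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(samples))
      writeLines(samples[[s]]$sam, file.path(dir, paste0(s, ".sam")))
    utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(haplogroup_defs,
                       file.path(dir, "haplogroup_defs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth_all <- do.call(rbind, lapply(names(samples), function(s)
      cbind(sample = s, samples[[s]]$truth)))
    utils::write.table(truth_all, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
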