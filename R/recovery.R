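#' Heteroplasmic-fraction recovery study
#'
#' Runs the full estimator path — simulate reads at a planted heteroplasmic
#' fraction, build the pileup, call mismatches — over a grid of planted
#' fractions and replicate seeds, and reports each run's estimated HF, the
#' site depth, and whether the estimate falls within
#' `3 * sqrt(h * (1 - h) / depth)` of truth (the binomial sampling bound at
#' that depth). Sequencing errors are off so the study isolates allele
#' sampling; duplicates are off so the nominal depth is realized (see the
#' methods vignette). A run with no PASS call scores an estimate of 0.
#'
#' Geometry note: fragments are fixed at twice the read length, so every
#' fragment covers the mid-genome study site with exactly one mate and the
#' depth at the site equals the fragment count — the `depth` argument is
#' therefore realized exactly at the measured position.
#'
#' @param hf_grid Planted fractions (default the seven-point grid 0.05,
#'   0.10, 0.25, 0.50, 0.75, 0.90, 1.00).
#' @param n_seeds Replicates per fraction (default 500).
#' @param depth Depth at the study site (default 200).
#' @param ref_length,read_length Simulation geometry (defaults 200 / 60).
#' @param seed Base seed; replicate r of fraction i uses
#'   `seed + 10000 * i + r`.
#' @return data.frame with one row per run: `target_hf`, `seed`,
#'   `estimated_hf`, `depth`, `within_3sigma`, `rounded_homoplasmic`.
#' @export
hf_recovery_study <- function(hf_grid = c(0.05, 0.10, 0.25, 0.50, 0.75,
                                          0.90, 1.00),
                              n_seeds = 500L, depth = 200,
                              ref_length = 200L, read_length = 60L,
                              seed = 1L) {
  ref <- simulate_reference(ref_length, seed = seed)
  pos <- ref_length %/% 2L
  alt <- setdiff(c("A", "C", "G", "T"), ref$chars[pos])[1]
  out <- vector("list", length(hf_grid) * n_seeds)
  k <- 0L
  for (i in seq_along(hf_grid)) {
    h <- hf_grid[i]
    planted <- data.frame(pos = pos, vtype = "mismatch", alt_allele = alt,
                          del_len = NA_integer_, target_hf = h,
                          stringsAsFactors = FALSE)
    for (r in seq_len(n_seeds)) {
      cfg <- simulation_config(planted = planted,
                               read_length = read_length,
                               fragment_mean = 2 * read_length,
                               fragment_sd = 0,
                               target_depth = depth * 2 * read_length /
                                 ref_length,
                               error_rate = 0, duplicate_rate = 0,
                               seed = seed + 10000L * i + r)
      sim <- simulate_reads(ref, cfg)
      pu <- build_pileup(sim$reads, ref)
      calls <- call_mismatches(pu, ref)
      hit <- calls$pos == pos & calls$alt_allele == alt &
        calls$filter_status == "PASS"
      est <- if (any(hit)) calls$hf[which(hit)[1]] else 0
      d <- pu$rd[pos]
      tol <- 3 * sqrt(h * (1 - h) / d)
      k <- k + 1L
      out[[k]] <- data.frame(target_hf = h, seed = cfg$seed,
                             estimated_hf = est, depth = d,
                             within_3sigma = abs(est - h) <= tol,
                             rounded_homoplasmic = floor(est * 100 + 0.5 +
                                                           1e-9) == 100,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
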