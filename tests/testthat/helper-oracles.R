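# Independent brute-force oracles. These deliberately re-derive results
# with naive loops and their own small lookup tables so they share no code
# path with the package internals they check.

# --- naive per-read pileup scan ---------------------------------------
oracle_pileup <- function(reads, ref, use_duplicates = FALSE) {
  L <- ref$length
  norm <- function(p) ((p - 1) %% L) + 1
  counts <- matrix(0L, nrow = L, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  quals <- vector("list", L * 4)
  del_cov <- integer(L)
  dels <- list(); inss <- list()
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (bitwAnd(r$flag, 0x4) != 0 || bitwAnd(r$flag, 0x100) != 0) next
    if (!use_duplicates && bitwAnd(r$flag, 0x400) != 0) next
    toks <- regmatches(r$cigar, gregexpr("[0-9]+.", r$cigar))[[1]]
    ops <- substr(toks, nchar(toks), nchar(toks))
    lens <- as.integer(substr(toks, 1, nchar(toks) - 1))
    qi <- 1; rp <- r$pos
    q <- utf8ToInt(r$qual) - 33L
    s <- strsplit(r$seq, "")[[1]]
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "=", "X")) {
        for (j in 0:(lens[k] - 1)) {
          p <- norm(rp + j); b <- match(s[qi + j], c("A", "C", "G", "T"))
          if (!is.na(b)) {
            counts[p, b] <- counts[p, b] + 1L
            key <- (p - 1) * 4 + b
            quals[[key]] <- c(quals[[key]], q[qi + j])
          }
        }
        qi <- qi + lens[k]; rp <- rp + lens[k]
      } else if (ops[k] == "I") {
        inss[[length(inss) + 1]] <- list(
          anchor = norm(rp - 1),
          seq = paste(s[qi:(qi + lens[k] - 1)], collapse = ""),
          quals = q[qi:(qi + lens[k] - 1)])
        qi <- qi + lens[k]
      } else if (ops[k] == "D") {
        dels[[length(dels) + 1]] <- c(norm(rp), lens[k])
        for (j in 0:(lens[k] - 1))
          del_cov[norm(rp + j)] <- del_cov[norm(rp + j)] + 1L
        rp <- rp + lens[k]
      } else if (ops[k] == "N") {
        rp <- rp + lens[k]
      } else if (ops[k] == "S") {
        qi <- qi + lens[k]
      }
    }
  }
  rd <- as.integer(rowSums(counts) + del_cov)
  list(counts = counts, quals = quals, del_cov = del_cov, rd = rd,
       dels = dels, inss = inss)
}

# --- literal reimplementation of the calling filters ------------------
oracle_calls <- function(op, ref, min_qs = 25, min_rd = 5, flank = 5,
                         min_alt = 1) {
  L <- ref$length
  norm <- function(p) ((p - 1) %% L) + 1
  BASES <- c("A", "C", "G", "T")
  out <- list()
  # mismatches
  for (p in 1:L) {
    rb <- substr(ref$sequence, p, p)
    if (!rb %in% BASES) next
    if (op$rd[p] < min_rd) next
    for (b in 1:4) {
      if (BASES[b] == rb) next
      cnt <- op$counts[p, b]
      if (cnt < min_alt) next
      if (median(op$quals[[(p - 1) * 4 + b]]) < min_qs) next
      out[[length(out) + 1]] <- sprintf("mismatch:%d:%s>%s:%d/%d", p, rb,
                                        BASES[b], cnt, op$rd[p])
    }
  }
  # insertions (merged by anchor+seq)
  if (length(op$inss) > 0) {
    keys <- sapply(op$inss, function(x) paste(x$anchor, x$seq))
    for (k in unique(keys)) {
      grp <- op$inss[keys == k]
      anchor <- grp[[1]]$anchor
      support <- length(grp)
      if (support < min_alt) next
      if (op$rd[anchor] < min_rd) next
      if (median(unlist(lapply(grp, `[[`, "quals"))) < min_qs) next
      out[[length(out) + 1]] <- sprintf("insertion:%d:%s:%d/%d", anchor,
                                        grp[[1]]$seq, support, op$rd[anchor])
    }
  }
  # deletions
  if (length(op$dels) > 0) {
    keys <- sapply(op$dels, paste, collapse = ":")
    for (k in unique(keys)) {
      cnt <- sum(keys == k)
      if (cnt < min_alt) next
      sd_ <- as.integer(strsplit(k, ":")[[1]])
      s <- sd_[1]; len <- sd_[2]
      if (op$rd[s] < min_rd) next
      up <- sapply((s - flank):(s - 1), norm)
      dn <- sapply((s + len):(s + len + flank - 1), norm)
      pos_med_qs <- function(p) {
        v <- unlist(op$quals[((p - 1) * 4 + 1):((p - 1) * 4 + 4)])
        if (length(v) == 0) 0 else median(v)
      }
      ok <- median(op$rd[up]) >= min_rd &&
            median(sapply(up, pos_med_qs)) >= min_qs &&
            median(op$rd[dn]) >= min_rd &&
            median(sapply(dn, pos_med_qs)) >= min_qs
      if (!ok) next
      out[[length(out) + 1]] <- sprintf("deletion:%d:%d:%d/%d", s, len,
                                        cnt, op$rd[s])
    }
  }
  out <- unlist(out)
  if (is.null(out)) character(0) else sort(out)
}

# canonical key set from a package call table, comparable to oracle_calls
call_keys <- function(calls) {
  calls <- calls[calls$filter_status == "PASS", , drop = FALSE]
  keys <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    keys[i] <- switch(v$vtype,
      mismatch = sprintf("mismatch:%d:%s>%s:%d/%d", v$pos, v$ref_allele,
                         v$alt_allele, v$alt_depth, v$total_depth),
      insertion = sprintf("insertion:%d:%s:%d/%d", v$pos,
                          substring(v$alt_allele, 2), v$alt_depth,
                          v$total_depth),
      deletion = sprintf("deletion:%d:%d:%d/%d", v$pos,
                         nchar(v$ref_allele), v$alt_depth, v$total_depth))
  }
  sort(keys)
}

# --- hypergeometric enumeration for the two-sided Fisher 2x2 ----------
oracle_fisher_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  rs <- a + b; k <- a + c; N <- a + b + c + d
  lo <- max(0, k - (N - rs)); hi <- min(rs, k)
  logp <- function(x) lchoose(rs, x) + lchoose(N - rs, k - x) - lchoose(N, k)
  lp_obs <- logp(a)
  xs <- lo:hi
  lp <- sapply(xs, logp)
  # two-sided: sum of all tables at most as probable as the observed one
  # (relative guard for floating-point ties)
  sum(exp(lp[lp <= lp_obs + log(1 + 1e-7)]))
}

# --- independent IUPAC expansion table --------------------------------
iupac_table <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG")
iupac_contains <- function(code, base) {
  s <- iupac_table[[code]]
  !is.null(s) && grepl(base, s, fixed = TRUE)
}

# --- homopolymer scan of the doubled string ---------------------------
oracle_homopolymers <- function(seqstr) {
  L <- nchar(seqstr)
  ch <- strsplit(paste0(seqstr, seqstr), "")[[1]]
  runs <- list()
  i <- 1
  while (i <= 2 * L) {
    j <- i
    while (j < 2 * L && ch[j + 1] == ch[i]) j <- j + 1
    len <- j - i + 1
    # keep maximal runs starting in the first copy, truncated to < L
    if (i <= L && len >= 2 && ch[i] != "N" && len < 2 * L) {
      prev <- if (i == 1) ch[2 * L] else ch[i - 1]
      if (prev != ch[i] && len <= L)
        runs[[length(runs) + 1]] <- list(start = i, base = ch[i],
                                         run_length = min(len, L))
    }
    i <- j + 1
  }
  if (length(runs) == 0)
    return(data.frame(start = integer(), base = character(),
                      run_length = integer()))
  df <- do.call(rbind, lapply(runs, as.data.frame))
  df[order(df$start), , drop = FALSE]
}
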