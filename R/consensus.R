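# IUPAC ambiguity handling. The code table comes from Biostrings; N is
# treated as "no information" for haplogroup matching (never matches).
iupac_for_set <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  code <- names(map)[match(key, vapply(map, function(s)
    paste(sort(strsplit(s, "")[[1]]), collapse = ""), ""))]
  if (is.na(code) || length(code) == 0)
    stop("no IUPAC code for base set {", key, "}")
  code
}

iupac_set <- function(code) {
  if (code == "N") return(character(0))  # gap: matches nothing
  s <- Biostrings::IUPAC_CODE_MAP[[code]]
  if (is.null(s)) return(character(0))
  strsplit(s, "")[[1]]
}

#' Build a per-sample consensus genome with IUPAC ambiguity coding
#'
#' Length-preserving consensus over the reference: positions with depth
#' below `min_rd` become `N` (gaps); a PASS mismatch with heteroplasmic
#' fraction at or above the consensus threshold (default 0.75) substitutes
#' the alternate base; PASS mismatches below the threshold yield the IUPAC
#' code covering the reference base plus all PASS alternate bases (so
#' downstream haplogroup matching can still see sub-threshold variants);
#' all other positions keep the reference base. Indels are not applied, so
#' the consensus length always equals the reference length.
#'
#' @param calls Call table; only PASS mismatches are used.
#' @param pileup `mt_pileup` (for the gap rule).
#' @param ref `circ_ref`.
#' @param th `mt_thresholds`.
#' @return Object of class `mt_consensus`: list with `sequence` (string of
#'   length L), `gap_count` (number of N characters) and `length`.
#' @export
build_consensus <- function(calls, pileup, ref, th = filter_thresholds()) {
  chars <- ref$chars
  chars[pileup$rd < th$min_rd] <- "N"
  mm <- calls[calls$vtype == "mismatch" & calls$filter_status == "PASS", ,
              drop = FALSE]
  if (nrow(mm) > 0) {
    for (p in unique(mm$pos)) {
      if (chars[p] == "N") next
      rows <- mm[mm$pos == p, , drop = FALSE]
      hi <- rows$hf >= th$consensus_hf
      if (sum(hi) > 1)
        stop("two alternate alleles at position ", p,
             " each with HF >= ", th$consensus_hf,
             " (fractions cannot sum above 1)")
      if (any(hi)) {
        chars[p] <- rows$alt_allele[hi]
      } else {
        chars[p] <- iupac_for_set(c(ref$chars[p], rows$alt_allele))
      }
    }
  }
  seq <- paste(chars, collapse = "")
  structure(list(sequence = seq, length = nchar(seq),
                 gap_count = sum(chars == "N")),
            class = "mt_consensus")
}

#' @export
print.mt_consensus <- function(x, ...) {
  cat("Consensus genome: ", x$length, " bp, ", x$gap_count, " gap(s)\n",
      sep = "")
  invisible(x)
}

#' Write a consensus genome as FASTA
#'
#' @param consensus `mt_consensus`.
#' @param name Sequence name.
#' @param path Output path.
#' @export
write_consensus_fasta <- function(consensus, name, path) {
  x <- Biostrings::BStringSet(consensus$sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a consensus genome back from FASTA
#'
#' Accepts the full IUPAC alphabet (unlike [load_reference()], which only
#' admits A/C/G/T/N reference bases).
#'
#' @param path FASTA file with a single record.
#' @return An `mt_consensus`.
#' @export
read_consensus_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1)
    stop("consensus FASTA must hold exactly one record")
  seq <- toupper(as.character(set[[1]]))
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", seq)
  if (nchar(bad) > 0)
    stop("non-IUPAC character(s) in consensus: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  structure(list(sequence = seq, length = nchar(seq),
                 gap_count = lengths(regmatches(seq, gregexpr("N", seq)))),
            class = "mt_consensus")
}

#' Read a haplogroup definitions table
#'
#' TSV with header `haplogroup, position, derived_allele`: each row is one
#' defining site of one haplogroup, in the same coordinate system as the
#' consensus sequences to be scored (the table, not the package, fixes the
#' reference the positions refer to).
#'
#' @param path File path.
#' @return data.frame with columns `haplogroup`, `position`,
#'   `derived_allele`.
#' @export
read_haplogroup_defs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  data.frame(haplogroup = as.character(df$haplogroup),
             position = as.integer(df$position),
             derived_allele = toupper(df$derived_allele),
             stringsAsFactors = FALSE)
}

#' Assign a haplogroup with a reliability score
#'
#' For each haplogroup the score counts defining sites whose consensus
#' character carries the derived allele (a plain match, or an IUPAC
#' ambiguity code whose base set contains it; `N` never matches) and
#' divides by the number of expected defining sites: `p_hg = Nph /
#' N_ph_exp`. The best haplogroup is the one with the highest `p_hg`, ties
#' broken toward the larger defining set and then lexicographically. An
#' assignment is flagged reliable only when `p_hg` exceeds 0.90 (strict).
#'
#' @param consensus `mt_consensus` (or a plain sequence string).
#' @param definitions Definitions table from [read_haplogroup_defs()].
#' @param uncovered One of `"count"` (default: sites the consensus shows as
#'   `N` stay in the denominator) or `"exclude"` (drop them from both
#'   numerator and denominator).
#' @return List of class `mt_haplogroup`: `name`, `n_ph`, `n_ph_exp`,
#'   `p_hg`, `reliable`, and `ranking` (the full per-haplogroup table).
#' @export
assign_haplogroup <- function(consensus, definitions,
                              uncovered = c("count", "exclude")) {
  uncovered <- match.arg(uncovered)
  seq <- if (inherits(consensus, "mt_consensus")) consensus$sequence
         else as.character(consensus)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (nrow(definitions) == 0) stop("empty haplogroup definitions table")
  bad <- definitions$position < 1 | definitions$position > L
  if (any(bad))
    stop("haplogroup definition position(s) outside 1..", L, ": ",
         paste(utils::head(definitions$position[bad], 5), collapse = ","))
  hgs <- sort(unique(definitions$haplogroup))
  rows <- lapply(hgs, function(h) {
    d <- definitions[definitions$haplogroup == h, , drop = FALSE]
    cons <- chars[d$position]
    matched <- mapply(function(cc, allele) allele %in% iupac_set(cc),
                      cons, d$derived_allele)
    n_exp <- nrow(d)
    if (uncovered == "exclude") n_exp <- n_exp - sum(cons == "N")
    n_ph <- sum(matched)
    data.frame(haplogroup = h, n_ph = n_ph, n_ph_exp = n_exp,
               p_hg = if (n_exp > 0) n_ph / n_exp else 0,
               stringsAsFactors = FALSE)
  })
  rank <- do.call(rbind, rows)
  rank <- rank[order(-rank$p_hg, -rank$n_ph_exp, rank$haplogroup), ,
               drop = FALSE]
  rownames(rank) <- NULL
  best <- rank[1, ]
  structure(list(name = best$haplogroup, n_ph = best$n_ph,
                 n_ph_exp = best$n_ph_exp, p_hg = best$p_hg,
                 reliable = best$p_hg > 0.90, ranking = rank),
            class = "mt_haplogroup")
}

#' @export
print.mt_haplogroup <- function(x, ...) {
  cat("Haplogroup ", x$name, ": P_Hg = ", format(x$p_hg, digits = 4),
      " (", x$n_ph, "/", x$n_ph_exp, " defining sites",
      if (x$reliable) ", reliable)" else ", not reliable)", "\n", sep = "")
  invisible(x)
}
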