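#' Load a circular mitochondrial reference from FASTA
#'
#' Reads a single-record FASTA file (or literal FASTA text) and returns a
#' circular reference object. mtDNA is a circular molecule, so all position
#' arithmetic downstream (flanking windows, wrap-around loci, origin-spanning
#' homopolymer runs) treats position `L + 1` as position 1.
#'
#' @param input Path to a FASTA file, or a character vector of FASTA lines
#'   (anything containing a newline or starting with `>` is treated as text).
#' @return An object of class `circ_ref` with elements `name`, `sequence`
#'   (uppercase string over A/C/G/T/N) and `length`.
#' @examples
#' ref <- load_reference(">chrM\nACGTACGT")
#' ref$length
#' @export
load_reference <- function(input) {
  is_text <- length(input) > 1 || grepl("[>\n]", input[1])
  if (is_text) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(unlist(strsplit(paste(input, collapse = "\n"), "\n")), tmp)
    path <- tmp
  } else {
    path <- input
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error: ", conditionMessage(e)))
  if (length(set) == 0) stop("FASTA format error: empty stream, no record found")
  if (length(set) > 1) stop("FASTA format error: multiple records (", length(set), ") in input")
  seq <- toupper(as.character(set[[1]]))
  if (nchar(seq) == 0) stop("FASTA format error: record has empty sequence")
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0) {
    stop("FASTA format error: illegal character(s) '",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""), "' in sequence")
  }
  circ_ref(names(set)[1], seq)
}

#' Construct a circular reference from a sequence string
#'
#' @param name Label for the sequence.
#' @param sequence Uppercase-able string over A/C/G/T/N.
#' @return A `circ_ref` object.
#' @export
circ_ref <- function(name, sequence) {
  sequence <- toupper(sequence)
  structure(
    list(name = as.character(name)[1],
         sequence = sequence,
         length = nchar(sequence),
         chars = strsplit(sequence, "", fixed = TRUE)[[1]]),
    class = "circ_ref"
  )
}

#' @export
print.circ_ref <- function(x, ...) {
  cat("Circular reference '", x$name, "': ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Normalize a position onto the circular coordinate system
#'
#' Maps any integer offset onto 1..L: `((p - 1) mod L) + 1`. Position 0 maps
#' to L, position L + 1 maps to 1. Vectorized.
#'
#' @param ref A `circ_ref` (or its length as a single integer).
#' @param p Integer vector of positions/offsets.
#' @return Integer vector of 1-based positions in 1..L.
#' @export
normalize_position <- function(ref, p) {
  L <- if (inherits(ref, "circ_ref")) ref$length else as.integer(ref)
  as.integer(((as.numeric(p) - 1) %% L) + 1)
}

#' Extract reference bases at (circularly normalized) positions
#'
#' @param ref A `circ_ref`.
#' @param p Integer vector of positions (any offsets; normalized).
#' @return Character vector of single bases.
#' @export
ref_base <- function(ref, p) {
  ref$chars[normalize_position(ref, p)]
}

#' Find homopolymer runs on a circular reference
#'
#' A homopolymer is a maximal run of at least two identical adjacent
#' nucleotides; such stretches are the hotspots where most mitochondrial
#' indels (length heteroplasmy) arise. Runs crossing the origin are reported
#' once, starting at their true start near the end of the sequence and
#' wrapping onto the beginning. `N` bases never participate in a run.
#'
#' @param ref A `circ_ref`.
#' @param min_len Minimum run length (default 2).
#' @return data.frame with columns `start` (1-based), `base`, `run_length`,
#'   sorted by `start`.
#' @export
find_homopolymers <- function(ref, min_len = 2L) {
  ch <- ref$chars
  L <- ref$length
  r <- rle(ch)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  runs <- data.frame(start = start, base = r$values, run_length = r$lengths,
                     stringsAsFactors = FALSE)
  # wrap: merge a run ending at L with a run starting at 1 of the same base
  n <- nrow(runs)
  if (n > 1 && runs$base[n] == runs$base[1] && runs$base[n] != "N") {
    runs$run_length[n] <- runs$run_length[n] + runs$run_length[1]
    runs <- runs[-1, , drop = FALSE]
  }
  runs <- runs[runs$run_length >= min_len & runs$base != "N", , drop = FALSE]
  runs <- runs[order(runs$start), , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Positions covered by a homopolymer run (circular)
#'
#' @param ref A `circ_ref`.
#' @param run One row of the [find_homopolymers()] table (list/df-row with
#'   `start` and `run_length`).
#' @return Integer vector of normalized positions.
#' @export
homopolymer_positions <- function(ref, run) {
  normalize_position(ref, seq(run$start, length.out = run$run_length))
}

#' Read a locus annotation table
#'
#' Accepts either a BED file (0-based half-open; converted to 1-based
#' inclusive on load) or a TSV with header `locus, start, end, class`
#' already in 1-based inclusive coordinates. A locus whose `start > end`
#' wraps around the origin (the mtDNA control region does).
#'
#' @param path File path.
#' @param format `"auto"` (default: BED if no header and >=3 columns with
#'   numeric cols 2-3), `"bed"` or `"tsv"`.
#' @return data.frame with columns `locus`, `start`, `end`, `klass`.
#' @export
read_loci <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  first <- readLines(path, n = 1)
  if (format == "auto") {
    format <- if (grepl("^locus\t", first)) "tsv" else "bed"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    out <- data.frame(locus = as.character(df$locus),
                      start = as.integer(df$start),
                      end = as.integer(df$end),
                      klass = if ("class" %in% names(df)) df$class else "other",
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (any(df[[2]] == df[[3]])) stop("zero-length locus in BED annotation")
    lab <- if (ncol(df) >= 4) as.character(df[[4]]) else
      paste0("locus_", df[[2]] + 1L, "_", df[[3]])
    out <- data.frame(locus = lab,
                      start = as.integer(df[[2]]) + 1L,  # BED 0-based start
                      end = as.integer(df[[3]]),          # BED 1-based end
                      klass = if (ncol(df) >= 5) df[[5]] else "other",
                      stringsAsFactors = FALSE)
  }
  if (any(out$start <= out$end & out$end - out$start + 1L <= 0L))
    stop("zero-length locus in annotation table")
  out
}

#' Length of a locus, honoring wrap-around
#'
#' @param loci Locus table (`locus`, `start`, `end`).
#' @param L Reference length.
#' @return Integer vector of locus lengths.
#' @export
locus_length <- function(loci, L) {
  ifelse(loci$start <= loci$end,
         loci$end - loci$start + 1L,
         L - loci$start + 1L + loci$end)
}

#' Loci containing a position
#'
#' Returns all locus labels whose interval (wrap-aware) contains the
#' normalized position `p`; overlapping annotations are all reported. An
#' empty result means the position is intergenic.
#'
#' @param loci Locus table as from [read_loci()].
#' @param p A single position (normalized by the caller or any offset if
#'   `ref` given).
#' @param ref Optional `circ_ref` used to normalize `p`.
#' @return Character vector of locus labels (possibly empty).
#' @export
locus_of <- function(loci, p, ref = NULL) {
  if (!is.null(ref)) p <- normalize_position(ref, p)
  hit <- ifelse(loci$start <= loci$end,
                p >= loci$start & p <= loci$end,
                p >= loci$start | p <= loci$end)
  loci$locus[hit]
}
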