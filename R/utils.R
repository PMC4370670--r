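# Internal coordinate convention: 0-based, half-open [start, end), strand "+"/"-".
# GFF3 I/O converts to/from 1-based inclusive; BED output stays 0-based half-open.

#' Create a genomic interval
#'
#' Intervals are 0-based half-open; used for every genomic coordinate in the
#' package.
#'
#' @param chrom Sequence name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand "+" or "-".
#' @return A list of class `interval`.
#' @export
interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: require 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand), class = "interval")
}

interval_width <- function(x) x$end - x$start

contains <- function(outer, inner) {
  outer$chrom == inner$chrom && outer$start <= inner$start && inner$end <= outer$end
}

overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# -- sequence helpers ---------------------------------------------------------

revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

dna_to_rna <- function(s) chartr("Tt", "Uu", toupper(s))
rna_to_dna <- function(s) chartr("Uu", "Tt", toupper(s))

# reverse complement of an RNA string, returned as RNA
revcomp_rna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(toupper(s))))
}

# length of the maximal terminal run of 'base' at the 3' end of a string
terminal_run <- function(s, base = "A") {
  n <- nchar(s)
  if (n == 0L) return(0L)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  k <- 0L
  for (i in seq(n, 1L)) {
    if (ch[i] == base) k <- k + 1L else break
  }
  k
}

# length of the maximal run of 'base' anywhere in a string
max_run <- function(s, base = "A") {
  if (nchar(s) == 0L) return(0L)
  runs <- rle(strsplit(s, "", fixed = TRUE)[[1L]] == base)
  m <- runs$lengths[runs$values]
  if (length(m) == 0L) 0L else max(m)
}

count_base <- function(s, base = "A") {
  lengths(regmatches(s, gregexpr(base, s, fixed = TRUE)))
}

# Fetch genomic subsequence [start, end) on a chromosome (DNA, + strand).
genome_fetch <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  start <- max(0L, as.integer(start)); end <- min(len, as.integer(end))
  if (start >= end) return("")
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

# n genomic bases immediately downstream (transcription order) of a cleavage
# position, returned in sense orientation. Cleavage convention: on "+" the
# 0-based index just after the last templated base; on "-" the index just
# 5'-genomic of the last templated base.
genome_downstream <- function(genome, chrom, cleavage_pos, strand, n) {
  if (strand == "+") {
    genome_fetch(genome, chrom, cleavage_pos, cleavage_pos + n)
  } else {
    s <- genome_fetch(genome, chrom, cleavage_pos - n + 1L, cleavage_pos + 1L)
    if (nchar(s) == 0L) "" else revcomp_dna(s)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of data.frames, dropping NULLs; NULL when nothing remains
rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
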