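# Poly(A)-site discovery from untemplated 3' tail evidence.
#
# Cleavage-position convention (0-based): on "+" the index immediately after
# the last templated base; on "-" the index immediately 5'-genomic of it, so
# the UTR offset of a cleavage equals the retained isoform length on both
# strands.

# Internal-priming check: the window of genomic sequence immediately
# downstream (sense) of the cleavage must not be A-rich, otherwise the tail
# can come from oligo-dT annealing to genomic adenines.
internal_priming_ok <- function(genome, chrom, cleavage_pos, strand,
                                window = 20L, max_a_count = 11L, max_a_run = 5L) {
  down <- genome_downstream(genome, chrom, cleavage_pos, strand, window)
  down <- dna_to_rna(down)  # normalize; counts work on A either way
  count_base(down, "A") <= max_a_count && max_run(down, "A") <= max_a_run
}

# Genomic A-run length starting at the cleavage position (sense orientation);
# tail adenines explained by these bases are templated.
templated_a_run <- function(genome, chrom, cleavage_pos, strand, max_len) {
  down <- genome_downstream(genome, chrom, cleavage_pos, strand, max_len)
  if (nchar(down) == 0L) return(0L)
  ch <- strsplit(toupper(down), "", fixed = TRUE)[[1L]]
  k <- 0L
  for (b in ch) { if (b == "A") k <- k + 1L else break }
  k
}

#' Detect an EST-style poly(A) tail on one read placement
#'
#' A placement yields cleavage evidence iff (i) the terminal A-run of its 3'
#' soft-clip is longer than `min_tail - 1` nucleotides (default: more than 10,
#' i.e. at least 11), (ii) the run is untemplated (the corresponding
#' downstream genomic bases are not themselves an A-run of that length), and
#' (iii) the internal-priming filter passes: the `prime_window` genomic
#' nucleotides downstream of the cleavage contain fewer than
#' `prime_max_a + 1` adenines and no A-run of `prime_max_run + 1` or more.
#'
#' @param placement One row of a placement data.frame.
#' @param genome A [Biostrings::DNAStringSet].
#' @param min_tail Minimum untemplated tail length (default 11).
#' @param prime_window,prime_max_a,prime_max_run Internal-priming parameters.
#' @return A one-row data.frame of tail evidence, or `NULL`.
#' @export
detect_est_tail <- function(placement, genome, min_tail = 11L,
                            prime_window = 20L, prime_max_a = 11L,
                            prime_max_run = 5L) {
  clip <- placement$clipped_tail_3p
  if (is.null(clip) || is.na(clip) || clip == "") return(NULL)
  run <- terminal_run(dna_to_rna(clip), "A")
  if (run < min_tail) return(NULL)
  cleavage <- if (placement$strand == "+") placement$end else placement$start - 1L
  tmpl <- templated_a_run(genome, placement$chrom, cleavage, placement$strand, run)
  if (tmpl >= run) return(NULL)  # fully explainable by genome: templated
  if (!internal_priming_ok(genome, placement$chrom, cleavage, placement$strand,
                           prime_window, prime_max_a, prime_max_run))
    return(NULL)
  data.frame(chrom = placement$chrom, pos = cleavage, strand = placement$strand,
             tail_len = run, source = "EST", read_id = placement$read_id,
             aligned_length = placement$aligned_length, stringsAsFactors = FALSE)
}

#' Assess RNA-Seq tail support at one candidate cleavage position
#'
#' A position is supported iff at least two reads each carry at least
#' `min_tail` untemplated terminal adenines (untemplated count = terminal
#' A-run minus the genomic A-run at the cleavage) and at least two of the
#' supporting reads differ in aligned length.
#'
#' @param placements data.frame of placements sharing one cleavage position.
#' @param genome A [Biostrings::DNAStringSet].
#' @param min_tail Minimum untemplated terminal A count per read (default 2).
#' @return A list with `supported` (flag) and `evidence` (data.frame of
#'   supporting reads; empty when unsupported).
#' @export
detect_rnaseq_tail <- function(placements, genome, min_tail = 2L) {
  if (nrow(placements) == 0L)
    return(list(supported = FALSE, evidence = NULL))
  cleavage <- ifelse(placements$strand == "+", placements$end, placements$start - 1L)
  if (length(unique(cleavage)) != 1L)
    stop("placements must share one cleavage position")
  runs <- vapply(placements$clipped_tail_3p,
                 function(s) terminal_run(dna_to_rna(s), "A"), integer(1))
  tmpl <- templated_a_run(genome, placements$chrom[1L], cleavage[1L],
                          placements$strand[1L], max(runs))
  untempl <- pmax(0L, runs - tmpl)
  ok <- untempl >= min_tail
  supported <- sum(ok) >= 2L &&
    length(unique(placements$aligned_length[ok])) >= 2L
  if (!supported) return(list(supported = FALSE, evidence = NULL))
  ev <- data.frame(chrom = placements$chrom[ok], pos = cleavage[ok],
                   strand = placements$strand[ok], tail_len = untempl[ok],
                   source = "RNASEQ", read_id = placements$read_id[ok],
                   aligned_length = placements$aligned_length[ok],
                   stringsAsFactors = FALSE)
  list(supported = TRUE, evidence = ev)
}

#' Scan placements for RNA-Seq cleavage support, grouped by position
#'
#' Convenience wrapper grouping placements by (chrom, strand, cleavage
#' position) and applying [detect_rnaseq_tail()] to every group.
#'
#' @inheritParams detect_rnaseq_tail
#' @return data.frame of supporting evidence rows (possibly empty).
#' @export
scan_rnaseq_tails <- function(placements, genome, min_tail = 2L) {
  if (nrow(placements) == 0L) return(NULL)
  cleavage <- ifelse(placements$strand == "+", placements$end, placements$start - 1L)
  key <- paste(placements$chrom, placements$strand, cleavage)
  out <- lapply(split(seq_len(nrow(placements)), key), function(idx) {
    detect_rnaseq_tail(placements[idx, , drop = FALSE], genome, min_tail)$evidence
  })
  rbind_all(out)
}

#' Single-linkage clustering of cleavage positions
#'
#' Positions (one gene, one strand) within `max_gap` nucleotides of each
#' other are subsumed into one site. The cluster representative is the member
#' position with maximal total support; ties go to the most proximal member
#' (closest to the CDS: smallest genomic position on "+", largest on "-").
#'
#' @param evidence data.frame with columns `pos` and `source` (one row per
#'   evidence item; repeated positions accumulate support).
#' @param strand Strand of the gene.
#' @param max_gap Link distance (default 40 nt).
#' @return data.frame with one row per site: position, support per source,
#'   support_total, n_members, members (comma-joined positions).
#' @export
cluster_apa_sites <- function(evidence, strand = "+", max_gap = 40L) {
  if (is.null(evidence) || nrow(evidence) == 0L)
    return(data.frame(position = integer(0), support_EST = integer(0),
                      support_RNASEQ = integer(0), support_EXTERNAL = integer(0),
                      support_total = integer(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  tab <- table(factor(evidence$source, levels = c("EST", "RNASEQ", "EXTERNAL")),
               evidence$pos)
  pos <- sort(as.integer(colnames(tab)))
  tab <- tab[, as.character(pos), drop = FALSE]
  cl <- cumsum(c(0L, diff(pos) > max_gap))
  out <- lapply(split(seq_along(pos), cl), function(idx) {
    per_pos <- colSums(tab[, idx, drop = FALSE])
    tot <- sum(per_pos)
    best <- which(per_pos == max(per_pos))
    rep_idx <- if (strand == "+") best[1L] else best[length(best)]
    data.frame(position = pos[idx][rep_idx],
               support_EST = sum(tab["EST", idx]),
               support_RNASEQ = sum(tab["RNASEQ", idx]),
               support_EXTERNAL = sum(tab["EXTERNAL", idx]),
               support_total = tot, n_members = length(idx),
               members = paste(pos[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  rbind_all(out)
}

#' Read an external poly(A)-site list (BED6)
#'
#' Each BED row marks one cleavage position as a 1-nt interval
#' `[pos, pos + 1)`; strand is taken from column 6.
#'
#' @param path BED6 file.
#' @return Evidence data.frame (source "EXTERNAL").
#' @export
read_external_sites <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = BiocGenerics::start(gr) - 1L,
             strand = as.character(BiocGenerics::strand(gr)),
             tail_len = NA_integer_, source = "EXTERNAL",
             read_id = NA_character_, aligned_length = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Build the per-gene poly(A)-site catalog
#'
#' Takes the union of EST, RNA-Seq and external cleavage evidence, assigns
#' each item to the gene whose longest transcript contains it (matching chrom
#' and strand), clusters jointly per gene with [cluster_apa_sites()], and
#' discards everything outside the longest transcript. Site UTR offsets are
#' computed in transcription order from the UTR start.
#'
#' @param evidence data.frame of tail evidence (columns chrom, pos, strand,
#'   source), e.g. rbind of [detect_est_tail()] / [scan_rnaseq_tails()]
#'   output and [read_external_sites()].
#' @param bundle An `apa_bundle`.
#' @param max_gap Cluster link distance (default 40 nt).
#' @return An `apa_catalog`: list with `sites` (named list of per-gene
#'   data.frames sorted proximal to distal) and `n_sites` (named vector).
#' @export
build_catalog <- function(evidence, bundle, max_gap = 40L) {
  genes <- bundle$genes
  sites <- list()
  known_chroms <- names(bundle$genome)
  if (!is.null(evidence) && nrow(evidence)) {
    bad <- !evidence$chrom %in% known_chroms
    if (any(bad)) {
      warning("skipping ", sum(bad), " evidence item(s) on unknown chromosome(s): ",
              paste(unique(evidence$chrom[bad]), collapse = ", "))
      evidence <- evidence[!bad, , drop = FALSE]
    }
  }
  for (g in genes) {
    tx <- g$transcripts[[g$longest_transcript_id]]
    if (is.null(evidence) || nrow(evidence) == 0L) next
    # cleavage positions are boundaries: a site at the annotated transcript
    # end lies at span[2] on "+" and span[1]-1 on "-", both inside the
    # transcript under the boundary convention
    sel <- evidence$chrom == tx$chrom & evidence$strand == tx$strand &
      evidence$pos >= tx$span[1L] - 1L & evidence$pos <= tx$span[2L]
    if (!any(sel)) next
    cl <- cluster_apa_sites(evidence[sel, , drop = FALSE], tx$strand, max_gap)
    utr <- extract_utr_sequence(g, bundle$genome)
    cl$utr_offset <- if (is.null(utr)) NA_integer_
                     else vapply(cl$position, function(p) utr_offset_of(utr, p),
                                 integer(1))
    # proximal -> distal in transcription order
    ord <- if (tx$strand == "+") order(cl$position) else order(-cl$position)
    cl <- cl[ord, , drop = FALSE]
    cl$site_id <- paste0(g$gene_id, ":", seq_len(nrow(cl)))
    cl$gene_id <- g$gene_id
    rownames(cl) <- NULL
    sites[[g$gene_id]] <- cl
  }
  structure(list(sites = sites,
                 n_sites = vapply(sites, nrow, integer(1))),
            class = "apa_catalog")
}

#' @export
print.apa_catalog <- function(x, ...) {
  cat("Poly(A)-site catalog:", sum(x$n_sites), "sites in", length(x$sites),
      "genes\n")
  invisible(x)
}

#' Write a catalog to BED6
#'
#' One row per site: chrom, position, position + 1, gene_id:site_id,
#' total support, strand.
#'
#' @param catalog An `apa_catalog`.
#' @param bundle The `apa_bundle` the catalog was built from.
#' @param path Output BED path.
#' @export
write_catalog_bed <- function(catalog, bundle, path) {
  rows <- character(0)
  for (gid in names(catalog$sites)) {
    g <- bundle$genes[[gid]]
    s <- catalog$sites[[gid]]
    rows <- c(rows, paste(g$chrom, s$position, s$position + 1L, s$site_id,
                          s$support_total, g$strand, sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
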