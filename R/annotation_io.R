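#' Load a genome + gene + miRNA annotation bundle
#'
#' Reads gene models (GFF3), miRNA loci (GFF3), mature-arm sequences (TSV:
#' `mirna_gene_id`, `arm_name`, `mature_seq`) and a genome (FASTA) into an
#' in-memory bundle. All coordinates are converted from GFF3 1-based inclusive
#' to internal 0-based half-open. Each gene resolves a
#' `longest_transcript_id`: the transcript of maximal genomic span, ties
#' broken by lexicographically smallest id.
#'
#' @param gene_gff3 Path to gene models (features `gene`, `mRNA`, `exon`,
#'   `CDS`, `three_prime_UTR`).
#' @param mirna_gff3 Path to miRNA loci (features `miRNA_primary_transcript`
#'   or `miRNA`).
#' @param mature_tsv Path to mature-arm TSV.
#' @param genome_fasta Path to genome FASTA.
#' @return A list of class `apa_bundle` with elements `genes` (named list of
#'   gene models), `mirnas` (named list of miRNA records) and `genome`
#'   (a [Biostrings::DNAStringSet]).
#' @export
load_annotation_bundle <- function(gene_gff3, mirna_gff3, mature_tsv, genome_fasta) {
  for (f in c(gene_gff3, mirna_gff3, mature_tsv, genome_fasta))
    if (!file.exists(f)) stop("input file not found: ", f)
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- read_gene_gff3(gene_gff3)
  mirnas <- read_mirna_gff3(mirna_gff3, mature_tsv)
  structure(list(genes = genes, mirnas = mirnas, genome = genome),
            class = "apa_bundle")
}

#' @export
print.apa_bundle <- function(x, ...) {
  cat("Annotation bundle:", length(x$genes), "genes,", length(x$mirnas),
      "miRNA genes,", length(x$genome), "sequences\n")
  invisible(x)
}

# Cheap structural validation before handing the file to rtracklayer, so
# malformed rows are reported with their line number.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("GFF3 parse error at line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e) || e < s)
      stop("GFF3 parse error at line ", i, ": invalid coordinates ", f[4L], "-", f[5L])
  }
  invisible(TRUE)
}

read_gene_gff3 <- function(path) {
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(gr$Parent, function(p) if (length(p)) as.character(p[1L]) else NA_character_,
                    character(1))

  tx_rows <- which(typ %in% c("mRNA", "transcript"))
  gene_rows <- which(typ == "gene")
  if (length(tx_rows) == 0L) stop("no mRNA/transcript features in ", path)

  # transcript -> gene
  tx_gene <- parents[tx_rows]
  names(tx_gene) <- ids[tx_rows]
  if (anyNA(names(tx_gene)) || anyNA(tx_gene))
    stop("GFF3 parse error: mRNA feature missing ID or Parent attribute")

  genes <- list()
  for (g in unique(tx_gene)) {
    tx_ids <- sort(names(tx_gene)[tx_gene == g])
    transcripts <- list()
    for (tid in tx_ids) {
      child <- which(parents == tid)
      ex <- child[typ[child] == "exon"]
      cds <- child[typ[child] == "CDS"]
      utr <- child[typ[child] == "three_prime_UTR"]
      if (length(ex) == 0L) stop("transcript ", tid, " has no exons")
      strand <- as.character(BiocGenerics::strand(gr[ex[1L]]))
      chrom <- as.character(GenomicRanges::seqnames(gr[ex[1L]]))
      exdf <- data.frame(start = BiocGenerics::start(gr[ex]) - 1L,
                         end = BiocGenerics::end(gr[ex]))
      exdf <- exdf[order(exdf$start), , drop = FALSE]
      rownames(exdf) <- NULL
      if (nrow(exdf) > 1L && any(exdf$start[-1L] < exdf$end[-nrow(exdf)]))
        stop("transcript ", tid, " has overlapping exons")
      cds_end <- NA_integer_
      if (length(cds)) {
        # last CDS base in transcription order, 0-based
        cds_end <- if (strand == "+") max(BiocGenerics::end(gr[cds])) - 1L
                   else min(BiocGenerics::start(gr[cds])) - 1L
      }
      utr3 <- NULL
      if (length(utr)) {
        utr3 <- interval(chrom, min(BiocGenerics::start(gr[utr])) - 1L,
                         max(BiocGenerics::end(gr[utr])), strand)
      }
      transcripts[[tid]] <- list(
        transcript_id = tid, chrom = chrom, strand = strand,
        exons = exdf, cds_end_genomic = cds_end, utr3 = utr3,
        span = c(min(exdf$start), max(exdf$end)))
    }
    spans <- vapply(transcripts, function(t) diff(t$span), numeric(1))
    longest <- names(transcripts)[order(-spans, names(transcripts))][1L]
    genes[[g]] <- structure(list(gene_id = g, chrom = transcripts[[1L]]$chrom,
                                 strand = transcripts[[1L]]$strand,
                                 transcripts = transcripts,
                                 longest_transcript_id = longest),
                            class = "gene_model")
  }
  genes[order(names(genes))]
}

read_mirna_gff3 <- function(path, mature_tsv) {
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("miRNA_primary_transcript", "miRNA", "gene")
  gr <- gr[keep]
  ids <- as.character(gr$ID)
  if (anyNA(ids)) stop("GFF3 parse error: miRNA feature missing ID attribute")

  mat <- utils::read.delim(mature_tsv, stringsAsFactors = FALSE)
  need <- c("mirna_gene_id", "arm_name", "mature_seq")
  if (!all(need %in% names(mat)))
    stop("mature TSV must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(mat$mirna_gene_id, ids)
  if (length(unknown))
    stop("mature arms reference unknown miRNA gene(s): ",
         paste(unknown, collapse = ", "))
  missing_arms <- setdiff(ids, mat$mirna_gene_id)
  if (length(missing_arms))
    stop("miRNA gene(s) without mature arms: ", paste(missing_arms, collapse = ", "))

  mirnas <- list()
  for (i in seq_along(gr)) {
    id <- ids[i]
    rows <- mat[mat$mirna_gene_id == id, , drop = FALSE]
    seqs <- dna_to_rna(rows$mature_seq)
    if (any(nchar(seqs) < 8L))
      stop("mature sequence shorter than 8 nt for ", id)
    arms <- data.frame(arm_name = rows$arm_name, mature_seq = seqs,
                       seed_2_8 = substr(seqs, 2L, 8L),
                       stringsAsFactors = FALSE)
    mirnas[[id]] <- structure(list(
      mirna_gene_id = id,
      locus = interval(as.character(GenomicRanges::seqnames(gr[i])),
                       BiocGenerics::start(gr[i]) - 1L, BiocGenerics::end(gr[i]),
                       as.character(BiocGenerics::strand(gr[i]))),
      arms = arms), class = "mirna_record")
  }
  mirnas[order(names(mirnas))]
}

#' Write gene models back to GFF3
#'
#' Inverse of the gene-model loader; used for round-trip checks and export.
#'
#' @param genes Named list of gene models.
#' @param path Output path.
#' @export
write_gene_gff3 <- function(genes, path) {
  rows <- list()
  add <- function(chrom, src, type, start0, end, strand, attrs) {
    rows[[length(rows) + 1L]] <<- paste(chrom, src, type, start0 + 1L, end, ".",
                                        strand, ".", attrs, sep = "\t")
  }
  for (g in genes) {
    span <- range(unlist(lapply(g$transcripts, function(t) t$span)))
    add(g$chrom, "apafeedback", "gene", span[1L], span[2L], g$strand,
        paste0("ID=", g$gene_id))
    for (t in g$transcripts) {
      add(t$chrom, "apafeedback", "mRNA", t$span[1L], t$span[2L], t$strand,
          paste0("ID=", t$transcript_id, ";Parent=", g$gene_id))
      for (j in seq_len(nrow(t$exons)))
        add(t$chrom, "apafeedback", "exon", t$exons$start[j], t$exons$end[j],
            t$strand, paste0("Parent=", t$transcript_id))
      if (!is.na(t$cds_end_genomic)) {
        # emit a single CDS row ending (in transcription order) at cds_end
        cs <- if (t$strand == "+") t$span[1L] else t$cds_end_genomic
        ce <- if (t$strand == "+") t$cds_end_genomic + 1L else t$span[2L]
        if (!is.null(t$utr3)) {
          if (t$strand == "+") ce <- min(ce, t$utr3$start)
          else cs <- max(cs, t$utr3$end - 1L)
        }
        add(t$chrom, "apafeedback", "CDS", cs, ce, t$strand,
            paste0("Parent=", t$transcript_id))
      }
      if (!is.null(t$utr3))
        add(t$chrom, "apafeedback", "three_prime_UTR", t$utr3$start, t$utr3$end,
            t$strand, paste0("Parent=", t$transcript_id))
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Extract the 3'UTR sequence of a gene's longest transcript
#'
#' Returns the UTR in mRNA sense orientation (reverse-complemented for minus
#' strand genes) over the RNA alphabet (T converted to U).
#'
#' @param gene A gene model.
#' @param genome A [Biostrings::DNAStringSet] genome.
#' @return A `utr_sequence` (fields `gene_id`, `seq`, `length`, `genomic`),
#'   or `NULL` when the longest transcript has no annotated 3'UTR.
#' @export
extract_utr_sequence <- function(gene, genome) {
  tx <- gene$transcripts[[gene$longest_transcript_id]]
  if (is.null(tx$utr3)) return(NULL)
  s <- genome_fetch(genome, tx$utr3$chrom, tx$utr3$start, tx$utr3$end)
  if (tx$strand == "-") s <- revcomp_dna(s)
  structure(list(gene_id = gene$gene_id, seq = dna_to_rna(s),
                 length = nchar(s), genomic = tx$utr3),
            class = "utr_sequence")
}

#' Map a genomic position to a transcription-order 3'UTR offset
#'
#' The offset is the number of UTR nucleotides retained by an isoform cleaved
#' at `pos` (cleavage-position convention: on "+" the 0-based index after the
#' last templated base; on "-" the index just 5'-genomic of it).
#'
#' @param utr A `utr_sequence`.
#' @param pos Genomic cleavage position.
#' @return Integer offset; 0 at the UTR start, `utr$length` at its distal end.
#' @export
utr_offset_of <- function(utr, pos) {
  if (utr$genomic$strand == "+") as.integer(pos) - utr$genomic$start
  else utr$genomic$end - 1L - as.integer(pos)
}

# inverse: genomic cleavage position of a UTR offset
genomic_pos_of_offset <- function(utr, offset) {
  if (utr$genomic$strand == "+") utr$genomic$start + as.integer(offset)
  else utr$genomic$end - 1L - as.integer(offset)
}

#' Load read placements from SAM or the packaged TSV dialect
#'
#' Applies the alignment-quality filter: placements with mapping quality below
#' `min_mapq` (default 20, the conventional unique-alignment cutoff) are
#' dropped, as are non-unique placements when `require_unique` is set. The 3'
#' soft-clipped bases of each alignment are captured in read orientation in
#' `clipped_tail_3p`.
#'
#' TSV dialect (tab-separated, header): read_id, chrom, start, end, strand,
#' mapq, unique, clipped_tail_3p; coordinates 0-based half-open, empty clip
#' written as ".".
#'
#' @param path SAM (`.sam`) or TSV file.
#' @param min_mapq Minimum mapping quality (inclusive).
#' @param require_unique Keep only uniquely mapping reads.
#' @return data.frame with columns read_id, chrom, start, end, strand, mapq,
#'   unique, clipped_tail_3p, aligned_length.
#' @export
load_read_placements <- function(path, min_mapq = 20L, require_unique = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  df <- if (grepl("\\.sam$", path, ignore.case = TRUE) || startsWith(first, "@")) {
    read_sam_placements(path)
  } else if (startsWith(first, "read_id")) {
    read_tsv_placements(path)
  } else stop("unknown read-placement format: ", path)
  df <- df[df$mapq >= min_mapq & (!require_unique | df$unique), , drop = FALSE]
  rownames(df) <- NULL
  df
}

read_tsv_placements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(clipped_tail_3p = "character"))
  need <- c("read_id", "chrom", "start", "end", "strand", "mapq", "unique",
            "clipped_tail_3p")
  if (!all(need %in% names(df)))
    stop("placement TSV must have columns: ", paste(need, collapse = ", "))
  df$clipped_tail_3p[df$clipped_tail_3p == "."] <- ""
  df$unique <- df$unique %in% c(TRUE, 1L, "1", "TRUE", "true")
  df$aligned_length <- df$end - df$start
  df[c(need, "aligned_length")]
}

read_sam_placements <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "strand",
                                        "pos", "mapq", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(x$pos)
  n <- sum(keep)
  out <- data.frame(read_id = x$qname[keep], chrom = as.character(x$rname)[keep],
                    start = x$pos[keep] - 1L, end = integer(n),
                    strand = as.character(x$strand)[keep],
                    mapq = as.integer(x$mapq)[keep], unique = logical(n),
                    clipped_tail_3p = character(n), stringsAsFactors = FALSE)
  cig <- x$cigar[keep]; seqs <- as.character(x$seq)[keep]; flags <- x$flag[keep]
  for (i in seq_len(n)) {
    ops <- cigar_ops(cig[i])
    ref_len <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
    out$end[i] <- out$start[i] + ref_len
    # 3' soft clip: trailing S for +, leading S for - (SEQ stored in reference
    # orientation), returned in read orientation
    if (out$strand[i] == "-") {
      if (ops$op[1L] == "S") {
        k <- ops$len[1L]
        out$clipped_tail_3p[i] <- revcomp_dna(substr(seqs[i], 1L, k))
      }
    } else {
      last <- nrow(ops)
      if (ops$op[last] == "S") {
        k <- ops$len[last]
        out$clipped_tail_3p[i] <- substr(seqs[i], nchar(seqs[i]) - k + 1L, nchar(seqs[i]))
      }
    }
    out$unique[i] <- bitwAnd(flags[i], 0x100L) == 0L && bitwAnd(flags[i], 0x800L) == 0L
  }
  out$aligned_length <- out$end - out$start
  out
}

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(data.frame(len = integer(), op = character()))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}
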