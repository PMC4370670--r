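# Differential 3'UTR usage between a study and a control condition:
# partition UTRs into poly(A) regions, count 3'-anchored reads per region,
# binomial-test each region against the library-size ratio, and call per-gene
# shortening/lengthening by the median-index rule.

#' Partition a 3'UTR into poly(A) regions
#'
#' With K sites at increasing UTR offsets s_1 < ... < s_K, region k spans
#' (s_{k-1}, s_k] with region 1 anchored at the UTR start. Offsets are on the
#' isoform-length scale (a site at offset s ends an isoform of s UTR nt).
#' Sites outside (0, UTR length] are ignored; with no usable site the gene
#' yields zero regions and is excluded from shift analysis.
#'
#' @param utr A `utr_sequence`.
#' @param sites Per-gene site data.frame from an `apa_catalog` (needs
#'   `utr_offset`).
#' @return data.frame: gene_id, index (1-based, proximal to distal),
#'   start_off (exclusive), end_off (inclusive).
#' @export
partition_polya_regions <- function(utr, sites) {
  offs <- sort(unique(sites$utr_offset))
  offs <- offs[!is.na(offs) & offs > 0L & offs <= utr$length]
  if (length(offs) == 0L)
    return(data.frame(gene_id = character(0), index = integer(0),
                      start_off = integer(0), end_off = integer(0)))
  data.frame(gene_id = utr$gene_id, index = seq_along(offs),
             start_off = c(0L, offs[-length(offs)]), end_off = offs,
             stringsAsFactors = FALSE)
}

# transcription-order UTR offset of a read's 3'-most aligned base, on the
# isoform-length scale used by partition_polya_regions
read_end_offset <- function(placements, utr) {
  pos <- ifelse(placements$strand == "+", placements$end, placements$start - 1L)
  vapply(pos, function(p) utr_offset_of(utr, p), integer(1))
}

#' Count reads per poly(A) region
#'
#' A read is assigned to the region containing its 3'-most aligned base
#' (transcription order); region spans are right-closed, so a read ending
#' exactly at a site belongs to the region that site terminates. Reads
#' outside all regions (or on the wrong strand/chromosome) are ignored.
#'
#' @param placements Placement data.frame (one condition).
#' @param regions Output of [partition_polya_regions()].
#' @param utr The `utr_sequence` the regions belong to.
#' @return Integer vector of counts, one per region row.
#' @export
count_reads_by_region <- function(placements, regions, utr) {
  if (nrow(regions) == 0L) return(integer(0))
  counts <- integer(nrow(regions))
  if (nrow(placements) == 0L) return(counts)
  sel <- placements$chrom == utr$genomic$chrom &
    placements$strand == utr$genomic$strand
  if (!any(sel)) return(counts)
  e <- read_end_offset(placements[sel, , drop = FALSE], utr)
  for (k in seq_len(nrow(regions)))
    counts[k] <- sum(e > regions$start_off[k] & e <= regions$end_off[k])
  counts
}

#' Test per-region read-count changes between conditions
#'
#' Each region with study count x and control count (n - x) is tested with a
#' two-sided binomial test of x out of n against p0 = lib_study /
#' (lib_study + lib_control), i.e. the study fraction expected from library
#' sizes alone. q-values are Benjamini-Hochberg over all tested regions in
#' the call (genome-wide family). Direction is "up" when the study fraction
#' exceeds p0 at q < alpha, "down" when below, else "none".
#'
#' @param regions data.frame with columns gene_id, index, count_study,
#'   count_control.
#' @param lib_study,lib_control Total mapped reads per condition (> 0).
#' @param alpha Significance level on q (default 0.05).
#' @return `regions` with p_value, q_value and direction appended.
#' @export
test_regions <- function(regions, lib_study, lib_control, alpha = 0.05) {
  if (lib_study <= 0 || lib_control <= 0) stop("library sizes must be positive")
  p0 <- lib_study / (lib_study + lib_control)
  n <- regions$count_study + regions$count_control
  regions$p_value <- mapply(function(x, nn) {
    if (nn == 0L) 1 else binomial_two_sided(x, nn, p0)$p_value
  }, regions$count_study, n)
  regions$q_value <- if (nrow(regions)) bh_adjust(regions$p_value) else numeric(0)
  frac <- ifelse(n > 0, regions$count_study / n, p0)
  regions$direction <- ifelse(regions$q_value < alpha & frac > p0, "up",
                              ifelse(regions$q_value < alpha & frac < p0,
                                     "down", "none"))
  regions
}

#' Call per-gene 3'UTR shortening or lengthening
#'
#' A gene is called only when it has at least one significantly up- and one
#' significantly downregulated region. Its UTR is "longer" in the study
#' condition when the median region index of the upregulated regions exceeds
#' the median index of the downregulated ones, and "shorter" otherwise (ties
#' call "shorter" and are flagged).
#'
#' @param tests Output of [test_regions()].
#' @return data.frame: gene_id, call ("shorter"/"longer"/"not_called"),
#'   median_up_index, median_down_index, tie.
#' @export
call_utr_shift <- function(tests) {
  out <- lapply(split(tests, tests$gene_id), function(tg) {
    up <- tg$index[tg$direction == "up"]
    down <- tg$index[tg$direction == "down"]
    if (length(up) == 0L || length(down) == 0L)
      return(data.frame(gene_id = tg$gene_id[1L], call = "not_called",
                        median_up_index = NA_real_, median_down_index = NA_real_,
                        tie = FALSE, stringsAsFactors = FALSE))
    mu <- stats::median(up); md <- stats::median(down)
    data.frame(gene_id = tg$gene_id[1L],
               call = if (mu > md) "longer" else "shorter",
               median_up_index = mu, median_down_index = md,
               tie = mu == md, stringsAsFactors = FALSE)
  })
  res <- rbind_all(out)
  res[order(res$gene_id), , drop = FALSE]
}

#' Filter genes by sequencing depth
#'
#' @param regions data.frame with gene_id, count_study, count_control.
#' @param min_total Minimum summed study + control reads per gene
#'   (inclusive; default 20).
#' @return Character vector of retained gene ids.
#' @export
filter_genes_for_depth <- function(regions, min_total = 20L) {
  tot <- tapply(regions$count_study + regions$count_control, regions$gene_id, sum)
  names(tot)[tot >= min_total]
}

#' Summarize shift calls by gene class
#'
#' @param calls Output of [call_utr_shift()].
#' @param class_labels Named character vector mapping gene_id to a class
#'   label (e.g. "HT-host", "NT-host", "other").
#' @return data.frame per class: n_called, n_shorter, n_longer,
#'   fraction_shorter.
#' @export
summarize_shift_by_class <- function(calls, class_labels) {
  called <- calls[calls$call != "not_called", , drop = FALSE]
  cls <- class_labels[called$gene_id]
  cls[is.na(cls)] <- "other"
  out <- lapply(split(called, cls), function(x) {
    data.frame(n_called = nrow(x), n_shorter = sum(x$call == "shorter"),
               n_longer = sum(x$call == "longer"),
               fraction_shorter = if (nrow(x)) sum(x$call == "shorter") / nrow(x)
                                  else NA_real_)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(class = character(0), n_called = integer(0),
                      n_shorter = integer(0), n_longer = integer(0),
                      fraction_shorter = numeric(0)))
  res <- cbind(class = rownames(res), res)
  rownames(res) <- NULL
  res
}

#' Run the full shift analysis for one annotation bundle
#'
#' Convenience wrapper: partitions every gene with catalogued sites, counts
#' study and control reads per region, applies the depth filter, tests all
#' retained regions in one genome-wide family, and calls per-gene shifts.
#'
#' @param bundle An `apa_bundle`.
#' @param catalog An `apa_catalog`.
#' @param study,control Placement data.frames (pre-filtered).
#' @param lib_study,lib_control Library sizes (total mapped reads).
#' @param alpha Significance level (default 0.05).
#' @param min_total Depth filter (default 20 reads/gene).
#' @return A list of class `utr_shift` with `tests` (per-region) and `calls`
#'   (per-gene) plus the thresholds used.
#' @export
analyze_utr_shifts <- function(bundle, catalog, study, control,
                               lib_study, lib_control,
                               alpha = 0.05, min_total = 20L) {
  reg_list <- list()
  for (gid in names(catalog$sites)) {
    utr <- extract_utr_sequence(bundle$genes[[gid]], bundle$genome)
    if (is.null(utr)) next
    reg <- partition_polya_regions(utr, catalog$sites[[gid]])
    if (nrow(reg) == 0L) next
    reg$count_study <- count_reads_by_region(study, reg, utr)
    reg$count_control <- count_reads_by_region(control, reg, utr)
    reg_list[[gid]] <- reg
  }
  regions <- rbind_all(reg_list)
  if (is.null(regions))
    regions <- data.frame(gene_id = character(0), index = integer(0),
                          start_off = integer(0), end_off = integer(0),
                          count_study = integer(0), count_control = integer(0))
  keep <- filter_genes_for_depth(regions, min_total)
  tested <- test_regions(regions[regions$gene_id %in% keep, , drop = FALSE],
                         lib_study, lib_control, alpha)
  calls <- if (nrow(tested)) call_utr_shift(tested) else
    data.frame(gene_id = character(0), call = character(0),
               median_up_index = numeric(0), median_down_index = numeric(0),
               tie = logical(0))
  structure(list(tests = tested, calls = calls, alpha = alpha,
                 min_total = min_total, lib_study = lib_study,
                 lib_control = lib_control,
                 n_genes_with_regions = length(unique(regions$gene_id)),
                 n_genes_tested = length(keep)),
            class = "utr_shift")
}

#' @export
print.utr_shift <- function(x, ...) {
  cat("Differential 3'UTR usage\n")
  cat(sprintf("  %d genes with poly(A) regions, %d pass depth filter (>= %d reads)\n",
              x$n_genes_with_regions, x$n_genes_tested, x$min_total))
  cat(sprintf("  %d regions tested, alpha = %g (BH, genome-wide family)\n",
              nrow(x$tests), x$alpha))
  tab <- table(factor(x$calls$call, levels = c("shorter", "longer", "not_called")))
  cat(sprintf("  calls: %d shorter, %d longer, %d not called\n",
              tab[["shorter"]], tab[["longer"]], tab[["not_called"]]))
  invisible(x)
}

#' Export sequences upstream of poly(A) sites as FASTA
#'
#' Writes, for every catalogued site, the `window` nucleotides immediately 5'
#' of the cleavage position in transcription order (sense strand); motif
#' discovery tools consume this file. Sites closer than `window` to the UTR
#' start yield truncated records with a warning.
#'
#' @param catalog An `apa_catalog`.
#' @param bundle The matching `apa_bundle`.
#' @param path Output FASTA path.
#' @param window Upstream window size (default 40 nt).
#' @export
export_upstream_sequences <- function(catalog, bundle, path, window = 40L) {
  seqs <- character(0)
  for (gid in names(catalog$sites)) {
    g <- bundle$genes[[gid]]
    s <- catalog$sites[[gid]]
    for (i in seq_len(nrow(s))) {
      w <- window
      if (!is.na(s$utr_offset[i]) && s$utr_offset[i] < window) {
        w <- max(0L, s$utr_offset[i])
        warning("site ", s$site_id[i], " is ", s$utr_offset[i],
                " nt from the UTR start; record truncated to ", w, " nt")
      }
      pos <- s$position[i]
      seq <- if (g$strand == "+") {
        genome_fetch(bundle$genome, g$chrom, pos - w, pos)
      } else {
        sub <- genome_fetch(bundle$genome, g$chrom, pos + 1L, pos + 1L + w)
        if (nchar(sub)) revcomp_dna(sub) else sub
      }
      seqs[s$site_id[i]] <- seq
    }
  }
  xs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}
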