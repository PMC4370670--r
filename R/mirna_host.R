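#' Classify a miRNA locus by genomic context
#'
#' A miRNA is intronic when its locus is fully contained in an intron of some
#' transcript, exonic when it is contained in a transcript but overlaps an
#' exon, and intergenic when no transcript contains it. When several genes
#' contain the locus, a same-strand host is preferred, then intronic over
#' exonic containment, then the smallest containing intron, then the
#' lexicographically smallest gene id (alternates are recorded).
#'
#' @param mirna A miRNA record.
#' @param genes Named list of gene models.
#' @return A list with `mirna_gene_id`, `category` ("intronic", "exonic" or
#'   "intergenic"), `host_gene_id`, `intron_index` (1-based, transcription
#'   order), `distance_to_upstream_exon` (nt from the transcription-upstream
#'   exon boundary to the miRNA 5' end) and `alternates`.
#' @export
classify_mirna_location <- function(mirna, genes) {
  loc <- mirna$locus
  cands <- list()
  for (g in genes) {
    for (tx in g$transcripts) {
      span <- interval(tx$chrom, tx$span[1L], tx$span[2L], tx$strand)
      if (!contains(span, loc)) next
      ex_overlap <- any(loc$start < tx$exons$end & tx$exons$start < loc$end)
      if (ex_overlap) {
        cands[[length(cands) + 1L]] <- list(gene = g, tx = tx, category = "exonic",
                                            intron_index = NA_integer_,
                                            intron_len = Inf, dist = NA_integer_)
        next
      }
      ne <- nrow(tx$exons)
      if (ne < 2L) next
      for (k in seq_len(ne - 1L)) {
        istart <- tx$exons$end[k]; iend <- tx$exons$start[k + 1L]
        if (loc$start >= istart && loc$end <= iend) {
          idx <- if (tx$strand == "+") k else ne - k
          dist <- if (tx$strand == "+") loc$start - istart else iend - loc$end
          cands[[length(cands) + 1L]] <- list(gene = g, tx = tx,
                                              category = "intronic",
                                              intron_index = idx,
                                              intron_len = iend - istart,
                                              dist = dist)
        }
      }
    }
  }
  if (length(cands) == 0L)
    return(list(mirna_gene_id = mirna$mirna_gene_id, category = "intergenic",
                host_gene_id = NA_character_, intron_index = NA_integer_,
                distance_to_upstream_exon = NA_integer_,
                alternates = character(0)))
  same_strand <- vapply(cands, function(cc) cc$tx$strand == loc$strand, logical(1))
  intronic <- vapply(cands, function(cc) cc$category == "intronic", logical(1))
  ilen <- vapply(cands, function(cc) cc$intron_len, numeric(1))
  gid <- vapply(cands, function(cc) cc$gene$gene_id, character(1))
  ord <- order(!same_strand, !intronic, ilen, gid)
  best <- cands[[ord[1L]]]
  list(mirna_gene_id = mirna$mirna_gene_id, category = best$category,
       host_gene_id = best$gene$gene_id, intron_index = best$intron_index,
       distance_to_upstream_exon = best$dist,
       alternates = setdiff(unique(gid), best$gene$gene_id))
}

#' Find miRNA seed matches in a 3'UTR
#'
#' Reports every UTR position whose 7-mer equals the reverse complement of
#' mature-sequence nucleotides 2-8 (site type 7mer-m8), or the reverse
#' complement of nucleotides 2-7 followed by an A on the UTR (7mer-A1).
#' Overlapping and duplicate positions are all reported; a position
#' satisfying both definitions is reported once, as 7mer-m8.
#'
#' @param utr A `utr_sequence`.
#' @param mature_seq Mature miRNA sequence (RNA or DNA letters, length >= 8).
#' @param mirna_gene_id,arm_name Optional identifiers carried into the output.
#' @return data.frame with columns mirna_gene_id, arm_name, gene_id,
#'   utr_offset (0-based), site_type, site_seq.
#' @export
find_seed_matches <- function(utr, mature_seq, mirna_gene_id = NA_character_,
                              arm_name = NA_character_) {
  mature_seq <- dna_to_rna(mature_seq)
  if (nchar(mature_seq) < 8L) stop("mature sequence must be at least 8 nt")
  empty <- data.frame(mirna_gene_id = character(0), arm_name = character(0),
                      gene_id = character(0), utr_offset = integer(0),
                      site_type = character(0), site_seq = character(0),
                      stringsAsFactors = FALSE)
  L <- utr$length
  if (L < 7L) return(empty)
  site_m8 <- revcomp_rna(substr(mature_seq, 2L, 8L))
  site_a1 <- paste0(revcomp_rna(substr(mature_seq, 2L, 7L)), "A")
  kmers <- substring(utr$seq, seq_len(L - 6L), seq(7L, L))
  type <- ifelse(kmers == site_m8, "7mer-m8",
                 ifelse(kmers == site_a1, "7mer-A1", NA_character_))
  hit <- which(!is.na(type))
  if (length(hit) == 0L) return(empty)
  data.frame(mirna_gene_id = mirna_gene_id, arm_name = arm_name,
             gene_id = utr$gene_id, utr_offset = hit - 1L,
             site_type = type[hit], site_seq = kmers[hit],
             stringsAsFactors = FALSE)
}

#' Call host-targeting (HT) vs non-host-targeting (NT) miRNA arms
#'
#' Every arm of every miRNA with a host gene (intronic or exonic context) is
#' scanned against the host's 3'UTR; an arm is HT iff it has at least one
#' seed match there. Intergenic miRNAs are excluded. Hosts without an
#' annotated 3'UTR yield NT calls with a warning.
#'
#' @param assignments List of host assignments
#'   (from [classify_mirna_location()]), one per miRNA.
#' @param mirnas Named list of miRNA records.
#' @param utrs Named list of `utr_sequence` keyed by gene id (may omit genes
#'   without UTRs).
#' @return data.frame with one row per (miRNA gene, arm): mirna_gene_id,
#'   arm_name, category, host_gene_id, is_HT, n_matches.
#' @export
classify_host_targeting <- function(assignments, mirnas, utrs) {
  rows <- list()
  for (a in assignments) {
    if (a$category == "intergenic") next
    mir <- mirnas[[a$mirna_gene_id]]
    utr <- utrs[[a$host_gene_id]]
    for (j in seq_len(nrow(mir$arms))) {
      if (is.null(utr)) {
        warning("host ", a$host_gene_id, " has no annotated 3'UTR; arm ",
                mir$arms$arm_name[j], " of ", a$mirna_gene_id, " called NT")
        n <- 0L
      } else {
        n <- nrow(find_seed_matches(utr, mir$arms$mature_seq[j]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_gene_id = a$mirna_gene_id, arm_name = mir$arms$arm_name[j],
        category = a$category, host_gene_id = a$host_gene_id,
        is_HT = n >= 1L, n_matches = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna_gene_id = character(0), arm_name = character(0),
                      category = character(0), host_gene_id = character(0),
                      is_HT = logical(0), n_matches = integer(0))
  out <- out[order(out$mirna_gene_id, out$arm_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare HT-host and NT-host gene cohorts
#'
#' Splits host genes into the HT set (hosting at least one HT arm) and the NT
#' set (hosting arms, none HT) and compares 3'UTR lengths and poly(A)-site
#' counts between the two sets with two-sided Mann-Whitney U tests.
#'
#' @param calls Output of [classify_host_targeting()].
#' @param utrs Named list of `utr_sequence` keyed by gene id.
#' @param catalog Optional `apa_catalog`; genes absent from it count 0 sites.
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(calls, utrs, catalog = NULL) {
  ht_hosts <- unique(calls$host_gene_id[calls$is_HT])
  nt_hosts <- setdiff(unique(calls$host_gene_id), ht_hosts)
  utr_len <- function(gs) vapply(gs, function(g) {
    u <- utrs[[g]]; if (is.null(u)) NA_integer_ else u$length
  }, integer(1))
  site_n <- function(gs) {
    if (is.null(catalog)) return(rep(NA_integer_, length(gs)))
    vapply(gs, function(g) {
      s <- catalog$sites[[g]]; if (is.null(s)) 0L else nrow(s)
    }, integer(1))
  }
  len_ht <- stats::na.omit(utr_len(ht_hosts)); len_nt <- stats::na.omit(utr_len(nt_hosts))
  p_len <- if (length(len_ht) && length(len_nt))
    mann_whitney_u(len_ht, len_nt)$p_value else NA_real_
  s_ht <- site_n(ht_hosts); s_nt <- site_n(nt_hosts)
  p_sites <- if (!is.null(catalog) && length(s_ht) && length(s_nt))
    mann_whitney_u(s_ht, s_nt)$p_value else NA_real_
  structure(list(
    n_ht_arms = sum(calls$is_HT), n_nt_arms = sum(!calls$is_HT),
    n_ht_hosts = length(ht_hosts), n_nt_hosts = length(nt_hosts),
    total_seed_matches_ht = sum(calls$n_matches[calls$is_HT]),
    median_utr_ht = stats::median(len_ht), median_utr_nt = stats::median(len_nt),
    p_utr_length = p_len,
    median_sites_ht = stats::median(s_ht), median_sites_nt = stats::median(s_nt),
    p_site_count = p_sites,
    ht_hosts = ht_hosts, nt_hosts = nt_hosts), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Host-targeting cohort summary\n")
  cat(sprintf("  HT arms: %d in %d host genes (%d seed matches); NT arms: %d in %d host genes\n",
              x$n_ht_arms, x$n_ht_hosts, x$total_seed_matches_ht,
              x$n_nt_arms, x$n_nt_hosts))
  cat(sprintf("  3'UTR length median HT %.0f vs NT %.0f (MWU p = %.3g)\n",
              x$median_utr_ht, x$median_utr_nt, x$p_utr_length))
  if (!is.na(x$p_site_count))
    cat(sprintf("  poly(A) sites/gene median HT %.1f vs NT %.1f (MWU p = %.3g)\n",
                x$median_sites_ht, x$median_sites_nt, x$p_site_count))
  invisible(x)
}
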