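CANONICAL_SIGNALS <- c("AAUAAA", "AUUAAA")

#' Scan a 3'UTR for canonical polyadenylation signals
#'
#' Reports every occurrence (overlaps included) of the canonical hexamers
#' AAUAAA and AUUAAA. `utr_offset` is 0-based; human-facing tables use
#' 1-based positions (`utr_offset + 1`), matching the convention of reported
#' signal positions.
#'
#' @param utr A `utr_sequence`.
#' @return data.frame: gene_id, motif, utr_offset (0-based),
#'   relative_position (`(utr_offset + 1) / UTR length`).
#' @export
scan_polya_signals <- function(utr) {
  L <- utr$length
  hits <- list()
  if (L >= 6L) {
    kmers <- substring(utr$seq, seq_len(L - 5L), seq(6L, L))
    for (motif in CANONICAL_SIGNALS) {
      at <- which(kmers == motif)
      if (length(at))
        hits[[motif]] <- data.frame(gene_id = utr$gene_id, motif = motif,
                                    utr_offset = at - 1L,
                                    stringsAsFactors = FALSE)
    }
  }
  out <- rbind_all(hits)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), motif = character(0),
                      utr_offset = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$utr_offset), , drop = FALSE]
  out$relative_position <- (out$utr_offset + 1L) / L
  rownames(out) <- NULL
  out
}

#' Relative positions of signal hits within a UTR
#'
#' @param hits data.frame from [scan_polya_signals()] (needs `utr_offset`).
#' @param utr_len UTR length in nucleotides (>= 1).
#' @return Numeric vector in (0, 1]: 1-based hit position / UTR length.
#' @export
relative_positions <- function(hits, utr_len) {
  if (utr_len < 1L) stop("utr_len must be >= 1")
  (hits$utr_offset + 1L) / utr_len
}

#' Compare signal-position distributions between two cohorts
#'
#' Two-sided Mann-Whitney U comparison of relative signal positions of
#' host-targeting vs non-host-targeting host-gene UTRs.
#'
#' @param ht_rel,nt_rel Numeric vectors of relative positions (non-empty).
#' @return list(median_HT, median_NT, p_value, statistic).
#' @export
compare_signal_position_distributions <- function(ht_rel, nt_rel) {
  if (length(ht_rel) == 0L || length(nt_rel) == 0L)
    stop("both cohorts must be non-empty")
  mwu <- mann_whitney_u(ht_rel, nt_rel)
  list(median_HT = stats::median(ht_rel), median_NT = stats::median(nt_rel),
       p_value = mwu$p_value, statistic = mwu$statistic)
}

#' Annotate seed matches with APA influence and canonical-signal precedence
#'
#' A match is `apa_influenced` when at least one catalogued poly(A) site of
#' the same gene has a UTR offset strictly between 0 and the match start, so
#' the isoform cleaved there lacks the site. It is `preceded_by_canonical`
#' when at least one canonical signal ends at or before the match start
#' (i.e. lies wholly 5' of the match; an abutting signal counts). The
#' stricter `"site_linked"` precedence mode additionally requires the
#' signal to sit 10-40 nt upstream of some upstream poly(A) site, i.e. to
#' plausibly direct a cleavage that drops the match.
#'
#' @param matches data.frame from [find_seed_matches()].
#' @param catalog An `apa_catalog`.
#' @param signals data.frame of signal hits ([scan_polya_signals()] output,
#'   possibly row-bound across genes).
#' @param precedence "any_upstream" (default) or "site_linked".
#' @return `matches` with logical columns `apa_influenced` and
#'   `preceded_by_canonical` appended.
#' @export
annotate_seed_match_apa <- function(matches, catalog, signals,
                                    precedence = c("any_upstream",
                                                   "site_linked")) {
  precedence <- match.arg(precedence)
  n <- nrow(matches)
  matches$apa_influenced <- logical(n)
  matches$preceded_by_canonical <- logical(n)
  for (i in seq_len(n)) {
    gid <- matches$gene_id[i]
    m <- matches$utr_offset[i]
    s <- catalog$sites[[gid]]
    up_sites <- integer(0)
    if (!is.null(s) && nrow(s)) {
      up_sites <- s$utr_offset[!is.na(s$utr_offset) & s$utr_offset > 0L &
                                 s$utr_offset < m]
      matches$apa_influenced[i] <- length(up_sites) > 0L
    }
    sg <- signals[signals$gene_id == gid, , drop = FALSE]
    if (nrow(sg)) {
      upstream <- sg$utr_offset[sg$utr_offset + 6L <= m]
      matches$preceded_by_canonical[i] <- if (precedence == "any_upstream") {
        length(upstream) > 0L
      } else {
        # signal hexamer must end 10-40 nt before an upstream cleavage site
        any(vapply(upstream, function(o)
          any(up_sites - (o + 6L) >= 10L & up_sites - (o + 6L) <= 40L),
          logical(1)))
      }
    }
  }
  matches
}
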