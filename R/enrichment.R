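# Enrichment of APA-machinery genes among host-targeting miRNA targets:
# per gene, a 2x2 Fisher test of "arms with >= 1 seed match" between two
# miRNA cohorts, BH-adjusted within the declared test family.

#' Count cohort arms targeting one 3'UTR
#'
#' @param apa_gene_utr A `utr_sequence`.
#' @param mature_seqs Character vector of mature arm sequences (the cohort);
#'   an arm matching several times counts once.
#' @return Number of arms with at least one seed match.
#' @export
count_targeting_arms <- function(apa_gene_utr, mature_seqs) {
  if (length(mature_seqs) == 0L) return(0L)
  sum(vapply(mature_seqs, function(m)
    nrow(find_seed_matches(apa_gene_utr, m)) >= 1L, logical(1)))
}

#' Fisher enrichment from pre-tabulated targeting counts
#'
#' Each row contributes the 2x2 table `[[targeting_A, n_A - targeting_A],
#' [targeting_B, n_B - targeting_B]]`, tested two-sided with Fisher's exact
#' test; q-values are BH over the rows supplied (one family per call).
#'
#' @param counts data.frame with columns gene, targeting_A, n_A,
#'   targeting_B, n_B.
#' @return data.frame of class `enrichment_result` adding pct_A, pct_B,
#'   odds_ratio, p_value, q_value.
#' @export
enrichment_from_counts <- function(counts) {
  need <- c("gene", "targeting_A", "n_A", "targeting_B", "n_B")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  if (any(counts$targeting_A > counts$n_A | counts$targeting_B > counts$n_B))
    stop("targeting counts cannot exceed cohort sizes")
  res <- counts
  ft <- mapply(function(a, na, b, nb) {
    if (na == 0L || nb == 0L) return(c(NA_real_, NA_real_))
    f <- fisher_exact_two_sided(a, na - a, b, nb - b)
    c(f$statistic, f$p_value)
  }, counts$targeting_A, counts$n_A, counts$targeting_B, counts$n_B)
  res$pct_A <- 100 * res$targeting_A / res$n_A
  res$pct_B <- 100 * res$targeting_B / res$n_B
  res$odds_ratio <- ft[1L, ]
  res$p_value <- ft[2L, ]
  res$q_value <- NA_real_
  ok <- !is.na(res$p_value)
  if (any(ok)) res$q_value[ok] <- bh_adjust(res$p_value[ok])
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Build per-gene targeting enrichment tables for two cohorts
#'
#' Counts, for every APA-machinery gene UTR, the arms of cohort A and cohort
#' B with at least one seed match, and tests each gene's 2x2 table. The BH
#' family is the set of genes in one call; to use a joint family across two
#' comparisons (e.g. HT vs NT and HT vs intergenic), row-bind the counts and
#' call [enrichment_from_counts()] once.
#'
#' @param apa_gene_utrs Named list of `utr_sequence` (the APA-machinery
#'   genes).
#' @param cohort_A,cohort_B Character vectors of mature arm sequences
#'   (disjoint cohorts).
#' @return An `enrichment_result` data.frame.
#' @export
enrichment_table <- function(apa_gene_utrs, cohort_A, cohort_B) {
  counts <- do.call(rbind, lapply(names(apa_gene_utrs), function(g) {
    data.frame(gene = g,
               targeting_A = count_targeting_arms(apa_gene_utrs[[g]], cohort_A),
               n_A = length(cohort_A),
               targeting_B = count_targeting_arms(apa_gene_utrs[[g]], cohort_B),
               n_B = length(cohort_B), stringsAsFactors = FALSE)
  }))
  enrichment_from_counts(counts)
}

#' Packaged APA-machinery targeting counts fixture
#'
#' Loads the packaged per-gene targeting counts of the 11 poly(A)-signal
#' recognition genes (HT cohort of 203 arms vs NT cohort of 601 arms).
#' The intergenic cohort size is not recorded (only percentages are known),
#' so only the HT-vs-NT comparison is testable from this fixture.
#'
#' @return data.frame: gene, targeting_A (HT), n_A, targeting_B (NT), n_B.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_counts.tsv", package = "apafeedback",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged host-gene shift-call fixture
#'
#' Loads the packaged per-arm table of host-targeting miRNA host genes with
#' significant 3'UTR changes after CPSF2 silencing (host gene, miRNA arm,
#' HT flag, direction of the UTR change).
#'
#' @return data.frame: host_gene, mirna, is_HT, utr_change.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_calls.tsv", package = "apafeedback",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
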