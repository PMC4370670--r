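# End-to-end orchestration: load -> classify miRNAs -> detect APA sites ->
# scan signals -> shift calling -> enrichment, rendering the report tables.

#' Pipeline configuration
#'
#' @param genes,mirnas,mature,genome Annotation input paths.
#' @param est_reads EST-style tail-evidence placements (SAM or TSV), or NULL.
#' @param rnaseq_reads RNA-Seq tail-evidence placements (SAM or TSV), or
#'   NULL; sites need two tailed reads of different aligned length.
#' @param external_sites BED6 of external poly(A) sites, or NULL.
#' @param study_reads,control_reads Condition placements (SAM/TSV), or NULL
#'   to skip the shift stage.
#' @param lib_study,lib_control Library sizes; default: the respective file's
#'   filtered read count.
#' @param alpha Significance level (default 0.05).
#' @param min_mapq Alignment-quality filter (default 20).
#' @param min_total Depth filter, reads per gene (default 20).
#' @param cluster_gap Site clustering distance (default 40 nt).
#' @param min_tail Minimum untemplated EST tail length (default 11).
#' @param out_dir Report directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genes, mirnas, mature, genome,
                            est_reads = NULL, rnaseq_reads = NULL,
                            external_sites = NULL,
                            study_reads = NULL, control_reads = NULL,
                            lib_study = NULL, lib_control = NULL,
                            alpha = 0.05, min_mapq = 20L, min_total = 20L,
                            cluster_gap = 40L, min_tail = 11L,
                            out_dir = tempfile("apareport")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' errors.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

write_report_tsv <- function(df, path, thresholds) {
  hdr <- paste0("# ", names(thresholds), " = ",
                vapply(thresholds, as.character, character(1)))
  con <- file(path, "w")
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: annotation loading, miRNA classification and HT/NT calling,
#' poly(A)-site discovery, signal scanning and seed-match annotation,
#' differential 3'UTR shift calling, and the class-level shift summary.
#' Writes `mirna_calls.tsv`, `apa_sites.bed`, `signal_hits.tsv`,
#' `seed_match_flags.tsv`, `shift_calls.tsv`, `class_summary.tsv` and
#' `cohort_summary.tsv` under `config$out_dir`, each with a provenance
#' header echoing the thresholds. Repeated runs on identical inputs
#' produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `apa_report` with all stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  thresholds <- config[c("alpha", "min_mapq", "min_total", "cluster_gap",
                         "min_tail")]
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  bundle <- load_annotation_bundle(config$genes, config$mirnas, config$mature,
                                   config$genome)
  note("load: ", length(bundle$genes), " genes, ", length(bundle$mirnas),
       " miRNA genes")
  utrs <- lapply(bundle$genes, extract_utr_sequence, genome = bundle$genome)
  utrs <- utrs[!vapply(utrs, is.null, logical(1))]

  assignments <- lapply(bundle$mirnas, classify_mirna_location,
                        genes = bundle$genes)
  calls <- classify_host_targeting(assignments, bundle$mirnas, utrs)
  note("classify-mirnas: ", nrow(calls), " arm calls, ", sum(calls$is_HT),
       " HT")

  evidence <- NULL
  if (!is.null(config$est_reads)) {
    pl <- load_read_placements(config$est_reads, config$min_mapq)
    ev <- lapply(seq_len(nrow(pl)), function(i)
      detect_est_tail(pl[i, , drop = FALSE], bundle$genome,
                      min_tail = config$min_tail))
    evidence <- rbind_all(ev)
  }
  if (!is.null(config$rnaseq_reads)) {
    pl <- load_read_placements(config$rnaseq_reads, config$min_mapq)
    rs <- scan_rnaseq_tails(pl, bundle$genome)
    if (!is.null(rs)) evidence <- rbind(evidence, rs)
  }
  if (!is.null(config$external_sites))
    evidence <- rbind(evidence, read_external_sites(config$external_sites))
  catalog <- build_catalog(evidence, bundle, max_gap = config$cluster_gap)
  note("detect-apa: ", sum(catalog$n_sites), " sites in ",
       length(catalog$sites), " genes")

  signals <- rbind_all(lapply(utrs, scan_polya_signals))
  matches <- rbind_all(lapply(seq_len(nrow(calls)), function(i) {
    utr <- utrs[[calls$host_gene_id[i]]]
    if (is.null(utr)) return(NULL)
    m <- bundle$mirnas[[calls$mirna_gene_id[i]]]
    arm <- m$arms[m$arms$arm_name == calls$arm_name[i], , drop = FALSE]
    find_seed_matches(utr, arm$mature_seq[1L], calls$mirna_gene_id[i],
                      calls$arm_name[i])
  }))
  if (!is.null(matches) && nrow(matches))
    matches <- annotate_seed_match_apa(matches, catalog, signals)
  note("scan-signals: ", if (is.null(signals)) 0L else nrow(signals),
       " signal hits, ", if (is.null(matches)) 0L else nrow(matches),
       " seed matches")

  summary_tbl <- cohort_summary(calls, utrs, catalog)

  shift <- NULL; class_summary <- NULL
  if (!is.null(config$study_reads) && !is.null(config$control_reads)) {
    study <- load_read_placements(config$study_reads, config$min_mapq)
    control <- load_read_placements(config$control_reads, config$min_mapq)
    lib_s <- config$lib_study %||% nrow(study)
    lib_c <- config$lib_control %||% nrow(control)
    shift <- analyze_utr_shifts(bundle, catalog, study, control, lib_s, lib_c,
                                alpha = config$alpha,
                                min_total = config$min_total)
    labels <- rep("other", length(bundle$genes))
    names(labels) <- names(bundle$genes)
    labels[summary_tbl$nt_hosts] <- "NT-host"
    labels[summary_tbl$ht_hosts] <- "HT-host"
    class_summary <- summarize_shift_by_class(shift$calls, labels)
    note("shift-call: ", sum(shift$calls$call != "not_called"),
         " of ", nrow(shift$calls), " genes called")
  }

  write_report_tsv(calls, file.path(config$out_dir, "mirna_calls.tsv"),
                   thresholds)
  write_catalog_bed(catalog, bundle, file.path(config$out_dir, "apa_sites.bed"))
  write_report_tsv(signals %||% data.frame(),
                   file.path(config$out_dir, "signal_hits.tsv"), thresholds)
  write_report_tsv(matches %||% data.frame(),
                   file.path(config$out_dir, "seed_match_flags.tsv"), thresholds)
  cohort_df <- data.frame(
    metric = c("n_ht_arms", "n_nt_arms", "n_ht_hosts", "n_nt_hosts",
               "total_seed_matches_ht", "median_utr_ht", "median_utr_nt",
               "p_utr_length", "median_sites_ht", "median_sites_nt",
               "p_site_count"),
    value = c(summary_tbl$n_ht_arms, summary_tbl$n_nt_arms,
              summary_tbl$n_ht_hosts, summary_tbl$n_nt_hosts,
              summary_tbl$total_seed_matches_ht, summary_tbl$median_utr_ht,
              summary_tbl$median_utr_nt, summary_tbl$p_utr_length,
              summary_tbl$median_sites_ht, summary_tbl$median_sites_nt,
              summary_tbl$p_site_count))
  write_report_tsv(cohort_df, file.path(config$out_dir, "cohort_summary.tsv"),
                   thresholds)
  if (!is.null(shift)) {
    write_report_tsv(shift$calls, file.path(config$out_dir, "shift_calls.tsv"),
                     thresholds)
    write_report_tsv(class_summary,
                     file.path(config$out_dir, "class_summary.tsv"), thresholds)
  }

  structure(list(bundle = bundle, utrs = utrs, calls = calls,
                 catalog = catalog, signals = signals, matches = matches,
                 cohort = summary_tbl, shift = shift,
                 class_summary = class_summary, log = log,
                 thresholds = thresholds, out_dir = config$out_dir),
            class = "apa_report")
}

#' @export
print.apa_report <- function(x, ...) {
  cat("APA feedback pipeline report (", x$out_dir, ")\n", sep = "")
  for (l in x$log) cat("  ", l, "\n", sep = "")
  invisible(x)
}
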