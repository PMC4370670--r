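# Ground-truthed synthetic inputs exercising every pipeline stage: a toy
# genome with host genes and planted intronic miRNAs, UTRs with planted seed
# matches, canonical signals and cleavage sites, tail reads with
# internal-priming decoys, and two-condition region counts with planted
# 3'UTR shifts. Everything is deterministic given the config seed.

SAFE_DOWNSTREAM <- "CGTCGATCGGATCCGATGCG"          # passes the priming filter
DECOY_DOWNSTREAM <- "GAAAAAAAAAAAAGCGCGCG"         # A-rich: must fail it

#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions: a 2:1 control:study
#' library ratio (mirroring the ~100M control vs ~50M study read depth of
#' the silencing experiment, scaled down), an effect size of 0.3 (fraction
#' of distal read mass moved across the UTR for a planted shift), 500 reads
#' per gene, 5 tail reads per cleavage site, and 2-4 sites per UTR spaced
#' at least ~150 nt apart.
#'
#' @param rng_seed Integer seed; all outputs are byte-identical given it.
#' @param n_genes Number of protein-coding genes.
#' @param n_intronic_mirnas Number of genes hosting one intronic miRNA each.
#' @param arms_per_mirna Mature arms per miRNA gene.
#' @param fraction_HT Fraction of arms given a planted host seed match.
#' @param utr_length_range,utr_length_range_ht 3'UTR length range (nt) for
#'   NT/other genes and for HT host genes.
#' @param sites_per_utr_range,sites_per_utr_range_ht Cleavage sites per UTR.
#' @param signals_per_utr Canonical signals planted per UTR.
#' @param signal_placement "distal_biased" (HT hosts uniform, others in the
#'   distal 20%) or "uniform".
#' @param shift_fractions Named fractions of genes planted "shorter" and
#'   "longer" (the rest are null).
#' @param effect_size Fraction of distal mass moved for planted shifts.
#' @param depth_per_gene Control reads per gene for region counts.
#' @param lib_sizes Named totals `c(study=, control=)`.
#' @param tail_depth_per_site Tail reads per true cleavage site.
#' @param n_priming_decoys Internal-priming decoy loci (with tail reads).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_genes = 20L, n_intronic_mirnas = 10L,
                       arms_per_mirna = 1L, fraction_HT = 0.5,
                       utr_length_range = c(600L, 2000L),
                       utr_length_range_ht = utr_length_range,
                       sites_per_utr_range = c(2L, 4L),
                       sites_per_utr_range_ht = sites_per_utr_range,
                       signals_per_utr = 3L,
                       signal_placement = c("distal_biased", "uniform"),
                       shift_fractions = c(shorter = 0.2, longer = 0.2),
                       effect_size = 0.3, depth_per_gene = 500L,
                       lib_sizes = c(study = 50000L, control = 100000L),
                       tail_depth_per_site = 5L, n_priming_decoys = 20L) {
  signal_placement <- match.arg(signal_placement)
  if (fraction_HT < 0 || fraction_HT > 1) stop("fraction_HT must be in [0, 1]")
  if (n_intronic_mirnas > n_genes)
    stop("n_intronic_mirnas cannot exceed n_genes")
  if (min(utr_length_range) < 200L)
    stop("UTRs shorter than 200 nt cannot accommodate the planted features")
  structure(as.list(environment()), class = "sim_config")
}

# -- internal helpers ---------------------------------------------------------

# occupied-interval tracker: pick a free sense position for a feature of
# length len within [lo, hi] (0-based start range), avoiding booked spans
pick_free <- function(lo, hi, len, occupied, tries = 500L) {
  for (i in seq_len(tries)) {
    p <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    clash <- any(p < occupied$end & occupied$start < p + len)
    if (!clash) return(p)
  }
  stop("infeasible configuration: no free position for a ", len,
       "-nt feature in [", lo, ", ", hi, "]")
}

book <- function(occupied, start, len) {
  rbind(occupied, data.frame(start = start, end = start + len))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_mature <- function(len = 21L) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

comp_map <- c(A = "T", C = "G", G = "C", T = "A")

# write a sense-orientation DNA string into the chromosome character vector
# at gene sense offset `off` (gene occupies [g0, g0+glen) genomically)
plant_sense <- function(chrom, g0, glen, strand, off, seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (strand == "+") {
    chrom[(g0 + off + 1L):(g0 + off + n)] <- ch
  } else {
    idx <- (g0 + glen - off):(g0 + glen - off - n + 1L)
    chrom[idx] <- unname(comp_map[ch])
  }
  chrom
}

sense_to_genomic <- function(g0, glen, strand, off) {
  if (strand == "+") g0 + off else g0 + glen - 1L - off
}

make_gene_model <- function(gene_id, chrom_name, strand, g0, exon_lens,
                            intron_lens, utr_len) {
  glen <- sum(exon_lens) + sum(intron_lens)
  # sense-coordinate exon spans
  sense_ex <- matrix(0L, nrow = length(exon_lens), ncol = 2L)
  off <- 0L
  for (k in seq_along(exon_lens)) {
    sense_ex[k, ] <- c(off, off + exon_lens[k])
    off <- off + exon_lens[k] + if (k < length(exon_lens)) intron_lens[k] else 0L
  }
  # genomic exons
  ex <- t(apply(sense_ex, 1L, function(s) {
    if (strand == "+") g0 + s else c(g0 + glen - s[2L], g0 + glen - s[1L])
  }))
  exdf <- data.frame(start = ex[, 1L], end = ex[, 2L])
  exdf <- exdf[order(exdf$start), , drop = FALSE]
  rownames(exdf) <- NULL
  utr_sense_start <- glen - utr_len
  utr_g <- if (strand == "+") c(g0 + utr_sense_start, g0 + glen)
           else c(g0, g0 + utr_len)
  cds_end <- sense_to_genomic(g0, glen, strand, utr_sense_start - 1L)
  tid <- paste0(gene_id, ".t1")
  tx <- list(transcript_id = tid, chrom = chrom_name, strand = strand,
             exons = exdf, cds_end_genomic = cds_end,
             utr3 = interval(chrom_name, utr_g[1L], utr_g[2L], strand),
             span = c(g0, g0 + glen))
  structure(list(gene_id = gene_id, chrom = chrom_name, strand = strand,
                 transcripts = stats::setNames(list(tx), tid),
                 longest_transcript_id = tid),
            class = "gene_model")
}

write_mirna_gff3 <- function(mirnas, path) {
  rows <- vapply(mirnas, function(m) {
    paste(m$locus$chrom, "apafeedback", "miRNA_primary_transcript",
          m$locus$start + 1L, m$locus$end, ".", m$locus$strand, ".",
          paste0("ID=", m$mirna_gene_id), sep = "\t")
  }, character(1))
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Write placements in the packaged TSV dialect
#'
#' @param df Placement data.frame.
#' @param path Output path.
#' @export
write_placements_tsv <- function(df, path) {
  out <- df[c("read_id", "chrom", "start", "end", "strand", "mapq", "unique",
              "clipped_tail_3p")]
  out$unique <- as.integer(out$unique)
  out$clipped_tail_3p[out$clipped_tail_3p == ""] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- generator ---------------------------------------------------------------

#' Generate a ground-truthed synthetic cohort
#'
#' Emits genome FASTA, gene and miRNA GFF3, mature-arm TSV and a ground-truth
#' object. HT arms get one planted exact 7mer-m8 site in their host UTR; NT
#' arms are rejection-sampled to have zero matches. Canonical signals are
#' planted uniformly in HT host UTRs and in the distal 20% elsewhere (in
#' `distal_biased` mode). Cleavage sites are evenly spaced (>= ~150 nt
#' apart), each followed by an A-poor downstream window so genuine sites
#' pass the internal-priming filter; decoy loci carry an A-rich window that
#' must fail it.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created); default a fresh tempdir.
#' @return list with `dir`, file `paths`, the `truth` tables and `config`.
#' @export
generate_cohort <- function(config, out_dir = tempfile("simcohort")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n <- config$n_genes
  n_arms_total <- config$n_intronic_mirnas * config$arms_per_mirna
  n_ht <- round(config$fraction_HT * n_arms_total)

  # per-arm HT flags in arm enumeration order
  arm_is_ht <- rep(FALSE, n_arms_total)
  if (n_ht > 0L) arm_is_ht[seq_len(n_ht)] <- TRUE

  # shift labels by gene index
  n_short <- round(config$shift_fractions[["shorter"]] * n)
  n_long <- round(config$shift_fractions[["longer"]] * n)
  shift_label <- rep("none", n)
  if (n_short > 0L) shift_label[seq_len(n_short)] <- "shorter"
  if (n_long > 0L) shift_label[n_short + seq_len(n_long)] <- "longer"

  exon1 <- 200L; intron1 <- 400L; cds2 <- 100L; gap <- 250L
  gene_ids <- sprintf("G%03d", seq_len(n))
  hosts_mirna <- seq_len(config$n_intronic_mirnas)

  # decide per-gene HT-host status first (drives UTR length / site count)
  arm_host <- rep(hosts_mirna, each = config$arms_per_mirna)
  gene_has_ht <- vapply(seq_len(n), function(i)
    any(arm_is_ht[arm_host == i]), logical(1))

  utr_len <- integer(n); n_sites <- integer(n); strand <- character(n)
  for (i in seq_len(n)) {
    lr <- if (gene_has_ht[i]) config$utr_length_range_ht else config$utr_length_range
    sr <- if (gene_has_ht[i]) config$sites_per_utr_range_ht else config$sites_per_utr_range
    utr_len[i] <- if (lr[1L] == lr[2L]) lr[1L] else sample(lr[1L]:lr[2L], 1L)
    n_sites[i] <- if (sr[1L] == sr[2L]) sr[1L] else sample(sr[1L]:sr[2L], 1L)
    strand[i] <- if (i %% 2L == 0L) "-" else "+"
  }
  glen <- exon1 + intron1 + cds2 + utr_len
  g0 <- cumsum(c(gap, (glen + gap)[-n]))
  chrom_len <- g0[n] + glen[n] + gap
  chrom_name <- "chrS"
  chrom <- strsplit(random_dna(chrom_len), "", fixed = TRUE)[[1L]]

  genes <- list(); mirnas <- list(); mature_rows <- list()
  truth_sites <- list(); truth_signals <- list(); truth_arms <- list()
  truth_decoys <- list()
  decoy_gene <- rep(seq_len(n), length.out = config$n_priming_decoys)
  arm_counter <- 0L

  for (i in seq_len(n)) {
    gid <- gene_ids[i]
    L <- utr_len[i]
    gm <- make_gene_model(gid, chrom_name, strand[i], g0[i],
                          c(exon1, cds2 + L), intron1, L)
    genes[[gid]] <- gm
    utr_sense_start <- glen[i] - L
    occupied <- data.frame(start = integer(0), end = integer(0))  # UTR coords

    # cleavage sites: evenly spaced, most distal at the UTR end
    K <- n_sites[i]
    site_off <- unique(as.integer(round(L * seq_len(K) / K)))
    for (s in site_off) {
      chrom <- plant_sense(chrom, g0[i], glen[i], strand[i],
                           utr_sense_start + s, SAFE_DOWNSTREAM)
      occupied <- book(occupied, s, nchar(SAFE_DOWNSTREAM))
      g_last <- sense_to_genomic(g0[i], glen[i], strand[i],
                                 utr_sense_start + s - 1L)
      cpos <- if (strand[i] == "+") g_last + 1L else g_last - 1L
      truth_sites[[length(truth_sites) + 1L]] <- data.frame(
        gene_id = gid, utr_offset = s, genomic_pos = cpos,
        chrom = chrom_name, strand = strand[i], stringsAsFactors = FALSE)
    }

    # internal-priming decoys assigned to this gene
    for (d in which(decoy_gene == i)) {
      dpos <- pick_free(30L, L - 60L, nchar(DECOY_DOWNSTREAM) + 1L, occupied)
      # keep decoys clear of true sites so nothing hinges on clustering
      chrom <- plant_sense(chrom, g0[i], glen[i], strand[i],
                           utr_sense_start + dpos, DECOY_DOWNSTREAM)
      occupied <- book(occupied, dpos, nchar(DECOY_DOWNSTREAM))
      g_last <- sense_to_genomic(g0[i], glen[i], strand[i],
                                 utr_sense_start + dpos - 1L)
      cpos <- if (strand[i] == "+") g_last + 1L else g_last - 1L
      truth_decoys[[length(truth_decoys) + 1L]] <- data.frame(
        gene_id = gid, utr_offset = dpos, genomic_pos = cpos,
        chrom = chrom_name, strand = strand[i], stringsAsFactors = FALSE)
    }

    # canonical signals
    distal <- config$signal_placement == "distal_biased" && !gene_has_ht[i]
    lo <- if (distal) as.integer(ceiling(0.8 * L)) else 0L
    for (k in seq_len(config$signals_per_utr)) {
      spos <- pick_free(lo, L - 7L, 6L, occupied)
      motif <- if (k %% 2L == 0L) "AUUAAA" else "AAUAAA"
      chrom <- plant_sense(chrom, g0[i], glen[i], strand[i],
                           utr_sense_start + spos, rna_to_dna(motif))
      occupied <- book(occupied, spos, 6L)
      truth_signals[[length(truth_signals) + 1L]] <- data.frame(
        gene_id = gid, utr_offset = spos, motif = motif,
        stringsAsFactors = FALSE)
    }

    # intronic miRNA + arms
    if (i %in% hosts_mirna) {
      mir_id <- sprintf("sim-mir-%03d", i)
      mir_sense <- c(exon1 + 160L, exon1 + 240L)  # inside the intron
      mg <- sort(c(sense_to_genomic(g0[i], glen[i], strand[i], mir_sense[1L]),
                   sense_to_genomic(g0[i], glen[i], strand[i], mir_sense[2L] - 1L)))
      arms <- list()
      for (a in seq_len(config$arms_per_mirna)) {
        arm_counter <- arm_counter + 1L
        arm_name <- if (a == 1L) "-5p" else "-3p"
        if (arm_is_ht[arm_counter]) {
          mature <- random_mature()
          site <- rna_to_dna(revcomp_rna(substr(mature, 2L, 8L)))
          mpos <- pick_free(30L, L - 40L, 7L, occupied)
          chrom <- plant_sense(chrom, g0[i], glen[i], strand[i],
                               utr_sense_start + mpos, site)
          occupied <- book(occupied, mpos, 7L)
          planted <- mpos
        } else {
          planted <- NA_integer_
          mature <- random_mature()  # validated against the final UTR below
        }
        arms[[a]] <- list(arm_name = arm_name, mature_seq = mature,
                          planted_offset = planted,
                          is_ht = arm_is_ht[arm_counter])
      }
      mirnas[[mir_id]] <- list(gene_idx = i, mir_id = mir_id,
                               locus = interval(chrom_name, mg[1L], mg[2L] + 1L,
                                                strand[i]),
                               arms = arms)
    }
  }

  genome <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
  names(genome) <- chrom_name

  # final UTR sequences (for NT rejection sampling and truth flags)
  utrs <- lapply(genes, extract_utr_sequence, genome = genome)

  for (mid in names(mirnas)) {
    m <- mirnas[[mid]]
    host <- gene_ids[m$gene_idx]
    for (a in seq_along(m$arms)) {
      arm <- m$arms[[a]]
      if (!arm$is_ht) {
        tries <- 0L
        while (nrow(find_seed_matches(utrs[[host]], arm$mature_seq)) > 0L) {
          arm$mature_seq <- random_mature()
          tries <- tries + 1L
          if (tries > 200L) stop("could not sample a non-targeting arm for ", host)
        }
        mirnas[[mid]]$arms[[a]] <- arm
      }
      mature_rows[[length(mature_rows) + 1L]] <- data.frame(
        mirna_gene_id = mid, arm_name = arm$arm_name,
        mature_seq = arm$mature_seq, stringsAsFactors = FALSE)
      truth_arms[[length(truth_arms) + 1L]] <- data.frame(
        mirna_gene_id = mid, arm_name = arm$arm_name, host_gene_id = host,
        is_HT = arm$is_ht, planted_offset = arm$planted_offset,
        stringsAsFactors = FALSE)
    }
  }

  truth <- list(
    arms = rbind_all(truth_arms),
    sites = rbind_all(truth_sites),
    signals = rbind_all(truth_signals),
    decoys = rbind_all(truth_decoys),
    shift = data.frame(gene_id = gene_ids, label = shift_label,
                       n_sites = vapply(gene_ids, function(g)
                         sum(vapply(truth_sites, function(s)
                           s$gene_id == g, logical(1))), integer(1)),
                       stringsAsFactors = FALSE),
    utr_len = stats::setNames(utr_len, gene_ids),
    gene_has_ht = stats::setNames(gene_has_ht, gene_ids))

  # expected per-match flags (for HT planted matches)
  ta <- truth$arms
  if (is.null(ta))
    ta <- data.frame(mirna_gene_id = character(0), arm_name = character(0),
                     host_gene_id = character(0), is_HT = logical(0),
                     planted_offset = integer(0), stringsAsFactors = FALSE)
  ta$apa_influenced <- logical(nrow(ta))
  ta$preceded_by_canonical <- logical(nrow(ta))
  for (j in seq_len(nrow(ta))) {
    if (is.na(ta$planted_offset[j])) next
    g <- ta$host_gene_id[j]; mpos <- ta$planted_offset[j]
    s <- truth$sites[truth$sites$gene_id == g, "utr_offset"]
    sg <- truth$signals[truth$signals$gene_id == g, "utr_offset"]
    ta$apa_influenced[j] <- any(s > 0L & s < mpos)
    ta$preceded_by_canonical[j] <- any(sg + 6L <= mpos)
  }
  truth$arms <- ta

  paths <- list(genome = file.path(out_dir, "genome.fa"),
                genes = file.path(out_dir, "genes.gff3"),
                mirnas = file.path(out_dir, "mirnas.gff3"),
                mature = file.path(out_dir, "mature.tsv"),
                truth = file.path(out_dir, "truth_arms.tsv"))
  Biostrings::writeXStringSet(genome, paths$genome)
  write_gene_gff3(genes, paths$genes)
  mir_records <- lapply(mirnas, function(m)
    list(mirna_gene_id = m$mir_id, locus = m$locus))
  write_mirna_gff3(mir_records, paths$mirnas)
  mature <- rbind_all(mature_rows)
  utils::write.table(mature, paths$mature, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$arms, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(dir = out_dir, paths = paths, truth = truth, config = config)
}

#' Simulate EST-style tail reads with internal-priming decoys
#'
#' Per true cleavage site, `tail_depth_per_site` reads aligned up to the
#' cleavage with a 12-A untemplated soft clip and varying aligned lengths;
#' per decoy locus, the same kind of read at a position whose downstream
#' genomic window is A-rich, so detection must reject it.
#'
#' @param cohort Output of [generate_cohort()].
#' @param path Optional TSV path; when given the placements are written.
#' @return Placement data.frame (with a logical `is_decoy` attribute column
#'   dropped from the TSV).
#' @export
simulate_tail_reads <- function(cohort, path = NULL) {
  config <- cohort$config
  set.seed(config$rng_seed + 101L)
  mk <- function(df, label) {
    rows <- list()
    for (j in seq_len(nrow(df))) {
      for (r in seq_len(config$tail_depth_per_site)) {
        alen <- 30L + ((j + r) %% 10L)
        cpos <- df$genomic_pos[j]
        if (df$strand[j] == "+") { st <- cpos - alen; en <- cpos }
        else { st <- cpos + 1L; en <- cpos + 1L + alen }
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_%s_s%d_r%d", label, df$gene_id[j],
                            df$utr_offset[j], r),
          chrom = df$chrom[j], start = st, end = en, strand = df$strand[j],
          mapq = 60L, unique = TRUE,
          clipped_tail_3p = strrep("A", 12L),
          aligned_length = alen, is_decoy = label == "decoy",
          stringsAsFactors = FALSE)
      }
    }
    rbind_all(rows)
  }
  out <- rbind(mk(cohort$truth$sites, "tail"),
               if (!is.null(cohort$truth$decoys) && nrow(cohort$truth$decoys))
                 mk(cohort$truth$decoys, "decoy"))
  if (is.null(out))
    out <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      unique = logical(0), clipped_tail_3p = character(0),
                      aligned_length = integer(0), is_decoy = logical(0))
  if (!is.null(path)) write_placements_tsv(out, path)
  out
}

# study/control region weights for one gene with K regions
shift_weights <- function(K, label, effect_size) {
  w <- (seq_len(K) + 1); w <- w / sum(w)   # distal-heavy baseline
  if (label == "none" || effect_size == 0 || K < 2L)
    return(list(control = w, study = w))
  prox <- seq_len(floor(K / 2)); dist <- setdiff(seq_len(K), prox)
  ws <- w
  if (label == "shorter") {
    moved <- effect_size * sum(w[dist])
    ws[dist] <- w[dist] * (1 - effect_size)
    ws[prox] <- w[prox] + moved * w[prox] / sum(w[prox])
  } else {
    moved <- effect_size * sum(w[prox])
    ws[prox] <- w[prox] * (1 - effect_size)
    ws[dist] <- w[dist] + moved * w[dist] / sum(w[dist])
  }
  list(control = w, study = ws)
}

#' Simulate two-condition poly(A)-region read counts
#'
#' Control counts are multinomial over a gene's regions with a distal-heavy
#' baseline; study counts use the same baseline re-weighted by the gene's
#' planted shift (an `effect_size` fraction of distal mass moved proximally
#' for "shorter", the reverse for "longer"). Study depth is scaled by the
#' library-size ratio so null genes match the binomial null.
#'
#' @param cohort Output of [generate_cohort()].
#' @return data.frame: gene_id, index, count_study, count_control; library
#'   sizes are attached as attributes `lib_study` / `lib_control`.
#' @export
simulate_region_counts <- function(cohort) {
  config <- cohort$config
  set.seed(config$rng_seed + 202L)
  ratio <- config$lib_sizes[["study"]] / config$lib_sizes[["control"]]
  rows <- list()
  for (g in names(cohort$truth$utr_len)) {
    K <- sum(cohort$truth$sites$gene_id == g)
    if (K == 0L) next
    label <- cohort$truth$shift$label[cohort$truth$shift$gene_id == g]
    w <- shift_weights(K, label, config$effect_size)
    nc <- config$depth_per_gene
    ns <- max(1L, round(config$depth_per_gene * ratio))
    rows[[g]] <- data.frame(
      gene_id = g, index = seq_len(K),
      count_study = as.integer(stats::rmultinom(1L, ns, w$study)),
      count_control = as.integer(stats::rmultinom(1L, nc, w$control)),
      stringsAsFactors = FALSE)
  }
  out <- rbind_all(rows)
  attr(out, "lib_study") <- config$lib_sizes[["study"]]
  attr(out, "lib_control") <- config$lib_sizes[["control"]]
  out
}

#' Simulate per-read placements for the two RNA-Seq conditions
#'
#' Read-level version of [simulate_region_counts()]: every counted read gets
#' a placement whose 3'-most aligned base falls inside its region, so the
#' read-counting path reproduces the simulated counts exactly.
#'
#' @param cohort Output of [generate_cohort()].
#' @param counts Output of [simulate_region_counts()] (regenerated when
#'   omitted).
#' @return list of two placement data.frames, `study` and `control`.
#' @export
simulate_condition_reads <- function(cohort, counts = simulate_region_counts(cohort)) {
  config <- cohort$config
  set.seed(config$rng_seed + 303L)
  truth <- cohort$truth
  mk_reads <- function(cond) {
    rows <- list()
    for (j in seq_len(nrow(counts))) {
      g <- counts$gene_id[j]
      sites <- sort(truth$sites$utr_offset[truth$sites$gene_id == g])
      lo <- if (counts$index[j] == 1L) 0L else sites[counts$index[j] - 1L]
      hi <- sites[counts$index[j]]
      n_reads <- counts[[paste0("count_", cond)]][j]
      if (n_reads == 0L) next
      ends <- lo + sample.int(hi - lo, n_reads, replace = TRUE)  # in (lo, hi]
      st <- truth$sites[truth$sites$gene_id == g, ][1L, ]
      # genomic coordinates of a 30-nt alignment ending at UTR offset e
      rows[[length(rows) + 1L]] <- do.call(rbind, lapply(seq_len(n_reads), function(r) {
        e <- ends[r]
        if (st$strand == "+") {
          # utr genomic start = site genomic pos - site utr offset
          ug0 <- st$genomic_pos - st$utr_offset
          en <- ug0 + e; sta <- en - 30L
        } else {
          ug1 <- st$genomic_pos + 1L + st$utr_offset  # utr genomic end
          sta <- ug1 - e; en <- sta + 30L
        }
        data.frame(read_id = sprintf("%s_%s_%d_%d", cond, g, j, r),
                   chrom = st$chrom, start = sta, end = en,
                   strand = st$strand, mapq = 60L, unique = TRUE,
                   clipped_tail_3p = "", aligned_length = 30L,
                   stringsAsFactors = FALSE)
      }))
    }
    rbind_all(rows)
  }
  list(study = mk_reads("study"), control = mk_reads("control"))
}

#' Deterministic host-gene fixture mirroring the worked biological example
#'
#' Builds a synthetic minus-strand 20-exon gene ("ZFRL") whose longest
#' transcript has a 1409-nt 3'UTR, hosting one miRNA in intron 11 (intron
#' length 4722 nt, 684 nt from the upstream exon) whose planted seed match
#' sits at UTR position 1301 (1-based). Canonical signals are planted at
#' UTR positions 135 and 314 (AUUAAA) and 738 (AAUAAA), and three cleavage
#' sites at UTR offsets 42, 341 and 1135, so only the longest isoform
#' carries the seed match. All values are synthetic reconstructions of the
#' published gene's geometry, not its real sequence.
#'
#' @param out_dir Output directory.
#' @return Same shape as [generate_cohort()] (single-gene cohort).
#' @export
zfr_like_fixture <- function(out_dir = tempfile("zfrl")) {
  set.seed(420L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utr_len <- 1409L
  exon_lens <- c(rep(150L, 19L), 150L + utr_len)
  intron_lens <- rep(300L, 19L); intron_lens[11L] <- 4722L
  glen <- sum(exon_lens) + sum(intron_lens)
  gap <- 200L
  chrom_name <- "chrZ"
  chrom <- strsplit(random_dna(glen + 2L * gap), "", fixed = TRUE)[[1L]]
  g0 <- gap; strand <- "-"
  gm <- make_gene_model("ZFRL", chrom_name, strand, g0, exon_lens,
                        intron_lens, utr_len)
  utr_sense_start <- glen - utr_len

  mature <- "UCGGAAUCCUUAAGGCAUUCA"
  seed_site <- rna_to_dna(revcomp_rna(substr(mature, 2L, 8L)))
  site_off <- c(42L, 341L, 1135L)
  sig <- data.frame(utr_offset = c(134L, 313L, 737L),
                    motif = c("AUUAAA", "AUUAAA", "AAUAAA"))

  plants <- rbind(
    data.frame(off = site_off, seq = SAFE_DOWNSTREAM),
    data.frame(off = sig$utr_offset, seq = rna_to_dna(sig$motif)),
    data.frame(off = 1300L, seq = seed_site))
  for (j in seq_len(nrow(plants)))
    chrom <- plant_sense(chrom, g0, glen, strand,
                         utr_sense_start + plants$off[j], plants$seq[j])
  # scrub accidental canonical signals / seed sites outside planted spots:
  # regenerate clashes until the UTR carries exactly the planted features
  genome <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
  names(genome) <- chrom_name
  utr <- extract_utr_sequence(gm, genome)
  planted_ok <- function(utr) {
    hits <- scan_polya_signals(utr)
    m <- find_seed_matches(utr, mature)
    identical(sort(hits$utr_offset), sort(sig$utr_offset)) &&
      identical(m$utr_offset, 1300L)
  }
  tries <- 0L
  while (!planted_ok(utr)) {
    tries <- tries + 1L
    if (tries > 50L) stop("could not scrub accidental motifs from fixture UTR")
    hits <- scan_polya_signals(utr)
    bad <- setdiff(hits$utr_offset, sig$utr_offset)
    m <- find_seed_matches(utr, mature)
    bad <- c(bad, setdiff(m$utr_offset, 1300L))
    for (b in bad)
      chrom <- plant_sense(chrom, g0, glen, strand, utr_sense_start + b,
                           random_dna(7L))
    genome <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
    names(genome) <- chrom_name
    utr <- extract_utr_sequence(gm, genome)
  }

  # miRNA in intron 11, 684 nt from the upstream exon (transcription order)
  intron11_sense_start <- sum(exon_lens[1:11]) + sum(intron_lens[1:10])
  mir_sense <- intron11_sense_start + 684L + c(0L, 96L)
  mg <- sort(c(sense_to_genomic(g0, glen, strand, mir_sense[1L]),
               sense_to_genomic(g0, glen, strand, mir_sense[2L] - 1L)))
  mir <- list(mirna_gene_id = "sim-mir-579",
              locus = interval(chrom_name, mg[1L], mg[2L] + 1L, strand))

  sites <- data.frame(gene_id = "ZFRL", utr_offset = site_off,
                      genomic_pos = vapply(site_off, function(s) {
                        gl <- sense_to_genomic(g0, glen, strand,
                                               utr_sense_start + s - 1L)
                        gl - 1L
                      }, integer(1)),
                      chrom = chrom_name, strand = strand,
                      stringsAsFactors = FALSE)

  paths <- list(genome = file.path(out_dir, "genome.fa"),
                genes = file.path(out_dir, "genes.gff3"),
                mirnas = file.path(out_dir, "mirnas.gff3"),
                mature = file.path(out_dir, "mature.tsv"))
  Biostrings::writeXStringSet(genome, paths$genome)
  write_gene_gff3(list(ZFRL = gm), paths$genes)
  write_mirna_gff3(list(mir), paths$mirnas)
  utils::write.table(data.frame(mirna_gene_id = "sim-mir-579",
                                arm_name = "-5p", mature_seq = mature),
                     paths$mature, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    arms = data.frame(mirna_gene_id = "sim-mir-579", arm_name = "-5p",
                      host_gene_id = "ZFRL", is_HT = TRUE,
                      planted_offset = 1300L, stringsAsFactors = FALSE),
    sites = sites,
    signals = cbind(gene_id = "ZFRL", sig, stringsAsFactors = FALSE),
    utr_len = c(ZFRL = utr_len), intron_index = 11L,
    distance_to_upstream_exon = 684L)
  cfg <- sim_config(rng_seed = 420L, n_genes = 1L, n_intronic_mirnas = 1L,
                    tail_depth_per_site = 5L, n_priming_decoys = 0L)
  list(dir = out_dir, paths = paths, truth = truth, config = cfg)
}
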