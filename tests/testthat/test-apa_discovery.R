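# hand-built one-chromosome genome: 60 nt prefix, then a named 20-nt
# downstream window, then filler
tail_genome <- function(downstream) {
  Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("CGT", 20), downstream, strrep("GCT", 20))))
}

tail_placement <- function(clip, strand = "+", end = 60L, start = end - 30L) {
  data.frame(read_id = "r1", chrom = "chr1", start = start, end = end,
             strand = strand, mapq = 60L, unique = TRUE,
             clipped_tail_3p = clip, aligned_length = end - start,
             stringsAsFactors = FALSE)
}

test_that("EST tail detection applies the >10-A rule and the priming filter", {
  safe <- "CGTCGATCGGATCCGATGCA"
  g <- tail_genome(safe)
  ev <- detect_est_tail(tail_placement(strrep("A", 12)), g)
  expect_equal(ev$pos, 60L)
  expect_equal(ev$tail_len, 12L)

  # exactly 10 A's: below the "more than 10" boundary
  expect_null(detect_est_tail(tail_placement(strrep("A", 10)), g))
  expect_null(detect_est_tail(tail_placement(""), g))

  # A-run of 6 in the downstream window: internal priming
  g_run6 <- tail_genome("AAAAAAGCGCGCGCGCGCGC")
  expect_null(detect_est_tail(tail_placement(strrep("A", 12)), g_run6))

  # 14 scattered A's in the window (no run of 6): internal priming by count
  g_many <- tail_genome("AAGAAGAAGAAGAAGAAGAA")
  expect_null(detect_est_tail(tail_placement(strrep("A", 12)), g_many))

  # tail fully templated by a genomic A-run is not cleavage evidence
  g_tmpl <- tail_genome(strrep("A", 20))
  expect_null(detect_est_tail(tail_placement(strrep("A", 12)), g_tmpl))
})

test_that("EST tail detection works on the minus strand", {
  # gene on minus strand: cleavage at start-1; downstream (sense) is the
  # reverse complement of the genomic bases 5'-genomic of the alignment
  safe_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("CGTCGATCGGATCCGATGCA")))
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("G", 40), safe_rc, strrep("C", 30))))
  pl <- tail_placement(strrep("A", 12), strand = "-", start = 60L, end = 90L)
  ev <- detect_est_tail(pl, g)
  expect_equal(ev$pos, 59L)
  expect_equal(ev$strand, "-")
})

test_that("RNA-Seq cleavage support needs two tailed reads of different length", {
  g <- tail_genome("CGTCGATCGGATCCGATGCA")
  two <- rbind(tail_placement("AA", end = 60L, start = 25L),
               tail_placement("AAA", end = 60L, start = 28L))
  two$read_id <- c("a", "b")
  expect_true(detect_rnaseq_tail(two, g)$supported)

  same_len <- two; same_len$start <- c(25L, 25L)
  same_len$aligned_length <- 35L
  expect_false(detect_rnaseq_tail(same_len, g)$supported)

  expect_false(detect_rnaseq_tail(two[1L, ], g)$supported)
})

test_that("site clustering subsumes positions within 40 nt and is idempotent", {
  ev <- function(pos) data.frame(pos = pos, source = "EST")
  one <- cluster_apa_sites(ev(c(100L, 139L)), "+")
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_members, 2L)
  two <- cluster_apa_sites(ev(c(100L, 141L)), "+")
  expect_equal(nrow(two), 2L)
  single <- cluster_apa_sites(ev(55L), "+")
  expect_equal(single$position, 55L)

  # representative: maximal support, ties to the most proximal member
  tied <- cluster_apa_sites(ev(c(100L, 100L, 130L, 130L)), "+")
  expect_equal(tied$position, 100L)
  tied_minus <- cluster_apa_sites(ev(c(100L, 100L, 130L, 130L)), "-")
  expect_equal(tied_minus$position, 130L)

  set.seed(77)
  for (i in 1:25) {
    pos <- sort(sample(1:2000, sample(2:30, 1), replace = TRUE))
    src <- sample(c("EST", "RNASEQ", "EXTERNAL"), length(pos), replace = TRUE)
    cl <- cluster_apa_sites(data.frame(pos = pos, source = src), "+")
    # support conservation
    expect_equal(sum(cl$support_total), length(pos))
    # representatives of distinct clusters are > 40 nt apart when chains break
    expect_true(all(diff(sort(cl$position)) > 0))
    # idempotence: clustering the representatives changes nothing
    cl2 <- cluster_apa_sites(data.frame(pos = rep(cl$position, cl$support_total),
                                        source = "EST"), "+")
    expect_equal(cl2$position, cl$position)
    expect_equal(cl2$support_total, cl$support_total)
  }
})

test_that("the catalog merges sources, restricts to the longest transcript, and orders sites", {
  co <- generate_cohort(sim_config(rng_seed = 13, n_genes = 4,
                                   n_intronic_mirnas = 2,
                                   n_priming_decoys = 0))
  b <- load_annotation_bundle(co$paths$genes, co$paths$mirnas, co$paths$mature,
                              co$paths$genome)
  s1 <- co$truth$sites[1L, ]
  ev <- data.frame(chrom = s1$chrom, pos = s1$genomic_pos, strand = s1$strand,
                   source = c("EST", "RNASEQ", "EXTERNAL"))
  ct <- build_catalog(ev, b)
  site <- ct$sites[[s1$gene_id]]
  expect_equal(nrow(site), 1L)
  expect_equal(site$support_EST + site$support_RNASEQ + site$support_EXTERNAL, 3L)

  # evidence beyond the longest transcript is discarded
  tx <- b$genes[[s1$gene_id]]$transcripts[[1L]]
  outside <- data.frame(chrom = s1$chrom, pos = tx$span[2L] + 10L,
                        strand = s1$strand, source = "EST")
  ct2 <- build_catalog(outside, b)
  expect_equal(sum(ct2$n_sites), 0L)

  # unknown chromosome: skipped with a warning
  expect_warning(build_catalog(data.frame(chrom = "chrUn", pos = 5L,
                                          strand = "+", source = "EST"), b),
                 "unknown chromosome")

  # full truth: sites come back proximal -> distal with increasing offsets
  ev_all <- data.frame(chrom = co$truth$sites$chrom,
                       pos = co$truth$sites$genomic_pos,
                       strand = co$truth$sites$strand, source = "EST")
  ct3 <- build_catalog(ev_all, b)
  for (g in names(ct3$sites))
    expect_true(all(diff(ct3$sites[[g]]$utr_offset) > 0), info = g)
})

test_that("planted cleavage sites are recovered exactly and decoys rejected", {
  co <- generate_cohort(sim_config(rng_seed = 29, n_genes = 10,
                                   n_intronic_mirnas = 5,
                                   n_priming_decoys = 10))
  b <- load_annotation_bundle(co$paths$genes, co$paths$mirnas, co$paths$mature,
                              co$paths$genome)
  tails <- simulate_tail_reads(co, file.path(co$dir, "tails.tsv"))
  pl <- load_read_placements(file.path(co$dir, "tails.tsv"))
  ev <- rbind_all_test(lapply(seq_len(nrow(pl)), function(i)
    detect_est_tail(pl[i, , drop = FALSE], b$genome)))
  # every decoy read rejected, every genuine tail kept
  expect_equal(nrow(ev), sum(!tails$is_decoy))
  expect_false(any(grepl("^decoy", ev$read_id)))
  ct <- build_catalog(ev, b)
  rec <- unlist(lapply(ct$sites, function(s) s$position))
  expect_setequal(rec, co$truth$sites$genomic_pos)
})
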