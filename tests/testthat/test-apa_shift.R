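test_that("poly(A) regions tile the UTR prefix between consecutive sites", {
  u <- make_utr(random_rna(1000))
  sites <- data.frame(utr_offset = c(200L, 600L, 1000L))
  r <- partition_polya_regions(u, sites)
  expect_equal(r$index, 1:3)
  expect_equal(r$start_off, c(0L, 200L, 600L))
  expect_equal(r$end_off, c(200L, 600L, 1000L))

  one <- partition_polya_regions(u, data.frame(utr_offset = 1000L))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start_off, one$end_off), c(0L, 1000L))

  none <- partition_polya_regions(u, data.frame(utr_offset = integer(0)))
  expect_equal(nrow(none), 0L)
})

test_that("reads are assigned to regions by their 3'-most aligned base", {
  u <- make_utr(random_rna(1000), chrom = "chrT", start = 5000L)
  r <- partition_polya_regions(u, data.frame(utr_offset = c(200L, 600L, 1000L)))
  mk <- function(end_off) data.frame(
    read_id = "r", chrom = "chrT", start = 5000L + end_off - 30L,
    end = 5000L + end_off, strand = "+", mapq = 60L, unique = TRUE,
    clipped_tail_3p = "", aligned_length = 30L, stringsAsFactors = FALSE)
  expect_equal(count_reads_by_region(mk(250L), r, u), c(0L, 1L, 0L))
  # a read ending exactly at a site belongs to the region it terminates
  expect_equal(count_reads_by_region(mk(200L), r, u), c(1L, 0L, 0L))
  expect_equal(count_reads_by_region(mk(0L)[0L, ], r, u), c(0L, 0L, 0L))

  # conservation on simulated reads: region counts sum to assigned reads
  co <- generate_cohort(sim_config(rng_seed = 37, n_genes = 6,
                                   n_intronic_mirnas = 3, depth_per_gene = 80L,
                                   n_priming_decoys = 0))
  cnt <- simulate_region_counts(co)
  reads <- simulate_condition_reads(co, cnt)
  b <- load_annotation_bundle(co$paths$genes, co$paths$mirnas, co$paths$mature,
                              co$paths$genome)
  for (g in unique(cnt$gene_id)) {
    utr <- extract_utr_sequence(b$genes[[g]], b$genome)
    reg <- partition_polya_regions(
      utr, data.frame(utr_offset = sort(co$truth$sites$utr_offset[
        co$truth$sites$gene_id == g])))
    got <- count_reads_by_region(reads$control, reg, utr)
    expect_equal(got, cnt$count_control[cnt$gene_id == g], info = g)
  }
})

test_that("region tests compare study fractions to the library-size null", {
  reg <- data.frame(gene_id = "G", index = 1:3,
                    count_study = c(30L, 10L, 5L),
                    count_control = c(10L, 20L, 10L))
  t1 <- test_regions(reg, 1e6, 2e6)
  expect_equal(t1$p_value[2L], 1, tolerance = 0.1)  # x/n == p0: no signal
  expect_lt(t1$p_value[1L], 0.001)                  # strong enrichment
  expect_equal(t1$p_value[3L],
               binomial_two_sided(5, 15, 1 / 3)$p_value, tolerance = 1e-12)
  # equal libraries reproduce the p0 = 1/2 enumeration value
  t2 <- test_regions(data.frame(gene_id = "G", index = 1L, count_study = 5L,
                                count_control = 10L), 1e6, 1e6)
  expect_equal(t2$p_value, 2 * 4944 / 32768, tolerance = 1e-9)
  # empty region: p = 1, no direction
  t3 <- test_regions(data.frame(gene_id = "G", index = 1L, count_study = 0L,
                                count_control = 0L), 1e6, 1e6)
  expect_equal(t3$p_value, 1)
  expect_equal(t3$direction, "none")
})

test_that("the median-index rule calls shortening and lengthening with ties shorter", {
  mk <- function(idx, dir) data.frame(gene_id = "G", index = idx,
                                      direction = dir)
  sh <- call_utr_shift(mk(c(1, 2, 4), c("up", "up", "down")))
  expect_equal(sh$call, "shorter")  # median up 1.5 < median down 4
  lo <- call_utr_shift(mk(c(4, 1, 2), c("up", "down", "down")))
  expect_equal(lo$call, "longer")
  nc <- call_utr_shift(mk(c(1, 2), c("up", "none")))
  expect_equal(nc$call, "not_called")
  tie <- call_utr_shift(mk(c(1, 3, 2), c("up", "up", "down")))
  expect_equal(tie$call, "shorter")  # 2 vs 2: the tie rule
  expect_true(tie$tie)
})

test_that("the depth filter retains genes at the threshold boundary", {
  reg <- data.frame(gene_id = c("a", "a", "b", "c"),
                    count_study = c(5L, 5L, 10L, 0L),
                    count_control = c(5L, 4L, 10L, 0L))
  expect_setequal(filter_genes_for_depth(reg, 20L), "b")  # a has 19
  expect_setequal(filter_genes_for_depth(reg, 19L), c("a", "b"))
  expect_setequal(filter_genes_for_depth(reg, 0L), c("a", "b", "c"))
})

test_that("swapping conditions flips every non-tied call", {
  co <- generate_cohort(sim_config(rng_seed = 43, n_genes = 60,
                                   n_intronic_mirnas = 0,
                                   n_priming_decoys = 0))
  cnt <- simulate_region_counts(co)
  fwd <- call_utr_shift(test_regions(cnt, attr(cnt, "lib_study"),
                                     attr(cnt, "lib_control")))
  swapped <- cnt
  swapped$count_study <- cnt$count_control
  swapped$count_control <- cnt$count_study
  rev <- call_utr_shift(test_regions(swapped, attr(cnt, "lib_control"),
                                     attr(cnt, "lib_study")))
  m <- merge(fwd, rev, by = "gene_id", suffixes = c(".f", ".r"))
  non_tied <- !m$tie.f & !m$tie.r
  flip <- c(shorter = "longer", longer = "shorter", not_called = "not_called")
  expect_equal(unname(flip[m$call.f[non_tied]]), m$call.r[non_tied])
})

test_that("class summaries report shorter/longer fractions per gene class", {
  calls <- data.frame(gene_id = c("a", "b", "c", "d"),
                      call = c("shorter", "shorter", "longer", "not_called"),
                      median_up_index = 1, median_down_index = 2, tie = FALSE)
  lab <- c(a = "HT-host", b = "NT-host", c = "HT-host", d = "HT-host")
  s <- summarize_shift_by_class(calls, lab)
  ht <- s[s$class == "HT-host", ]
  expect_equal(ht$n_called, 2L)
  expect_equal(ht$fraction_shorter, 0.5)
  all_long <- summarize_shift_by_class(
    data.frame(gene_id = "a", call = "longer", median_up_index = 2,
               median_down_index = 1, tie = FALSE), lab)
  expect_equal(all_long$fraction_shorter, 0)
})

test_that("upstream windows of cleavage sites export in sense orientation", {
  co <- generate_cohort(sim_config(rng_seed = 47, n_genes = 4,
                                   n_intronic_mirnas = 2,
                                   n_priming_decoys = 0))
  b <- load_annotation_bundle(co$paths$genes, co$paths$mirnas, co$paths$mature,
                              co$paths$genome)
  ev <- data.frame(chrom = co$truth$sites$chrom,
                   pos = co$truth$sites$genomic_pos,
                   strand = co$truth$sites$strand, source = "EST")
  ct <- build_catalog(ev, b)
  fa <- file.path(co$dir, "upstream.fa")
  export_upstream_sequences(ct, b, fa)
  xs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(xs), sum(ct$n_sites))
  # each record equals the UTR substring ending at the site offset
  for (g in names(ct$sites)) {
    utr <- extract_utr_sequence(b$genes[[g]], b$genome)
    s <- ct$sites[[g]]
    for (i in seq_len(nrow(s))) {
      rec <- as.character(xs[[s$site_id[i]]])
      want <- substring(chartr("U", "T", utr$seq),
                        s$utr_offset[i] - nchar(rec) + 1L, s$utr_offset[i])
      expect_equal(rec, want, info = s$site_id[i])
      expect_lte(nchar(rec), 40L)
    }
  }
  # a site closer than the window to the UTR start triggers truncation
  short_site <- structure(list(sites = list(), n_sites = integer(0)),
                          class = "apa_catalog")
  g1 <- names(ct$sites)[1L]
  short_site$sites[[g1]] <- ct$sites[[g1]][1L, ]
  short_site$sites[[g1]]$utr_offset <- 30L
  short_site$sites[[g1]]$position <-
    co$truth$sites$genomic_pos[co$truth$sites$gene_id == g1][1L]
  expect_warning(export_upstream_sequences(short_site, b,
                                           file.path(co$dir, "trunc.fa")),
                 "truncated")
})
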