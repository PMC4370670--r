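test_that("seed-match scanning finds the two 7-nt site classes", {
  mature <- "UCGGAAUCCUUAAGGCAUUCA"
  # revcomp of nt 2-8 is GAUUCCG; of nt 2-7 plus A is AUUCCGA
  u1 <- make_utr(paste0(strrep("C", 10), "GAUUCCG", strrep("C", 10)))
  m1 <- find_seed_matches(u1, mature)
  expect_equal(m1$utr_offset, 10L)
  expect_equal(m1$site_type, "7mer-m8")

  u2 <- make_utr(paste0(strrep("C", 4), "AUUCCGA", strrep("C", 4)))
  m2 <- find_seed_matches(u2, mature)
  expect_equal(m2$utr_offset, 4L)
  expect_equal(m2$site_type, "7mer-A1")

  expect_equal(nrow(find_seed_matches(make_utr(strrep("C", 50)), mature)), 0L)
  expect_error(find_seed_matches(u1, "UCGGAAU"), "at least 8")
})

test_that("a site satisfying both definitions is reported once as 7mer-m8", {
  # with mature nt 2-8 all U, the m8 site and the A1 site are both AAAAAAA
  mature <- "GUUUUUUUCCGGCCGGCCAUG"
  u <- make_utr(paste0("CCC", strrep("A", 7), "CCC"))
  m <- find_seed_matches(u, mature)
  expect_equal(nrow(m), 1L)
  expect_equal(m$site_type, "7mer-m8")
})

test_that("seed-match scanning equals the brute-force oracle on random pairs", {
  set.seed(41)
  for (i in 1:150) {
    L <- sample(50:500, 1)
    utr <- make_utr(random_rna(L))
    mature <- random_rna(sample(18:23, 1))
    got <- find_seed_matches(utr, mature)
    want <- oracle_seed_matches(utr$seq, mature)
    expect_equal(got$utr_offset, want$utr_offset, info = i)
    expect_equal(got$site_type, want$site_type, info = i)
    # every reported match re-verifies from its stored offset
    if (nrow(got)) {
      k <- substring(utr$seq, got$utr_offset + 1L, got$utr_offset + 7L)
      expect_equal(k, got$site_seq)
    }
  }
})

test_that("miRNA loci classify as intronic, exonic or intergenic by containment", {
  co <- generate_cohort(sim_config(rng_seed = 9, n_genes = 4,
                                   n_intronic_mirnas = 2,
                                   n_priming_decoys = 0))
  b <- load_annotation_bundle(co$paths$genes, co$paths$mirnas, co$paths$mature,
                              co$paths$genome)
  for (m in b$mirnas) {
    a <- classify_mirna_location(m, b$genes)
    expect_equal(a$category, "intronic")
    expect_equal(a$intron_index, 1L)
  }
  # intergenic: a locus in the gap between genes
  gaps <- interval("chrS", 5L, 60L, "+")
  fake <- list(mirna_gene_id = "mir-x", locus = gaps)
  a <- classify_mirna_location(fake, b$genes)
  expect_equal(a$category, "intergenic")
  expect_true(is.na(a$host_gene_id))
  # exonic: straddles the first exon-intron boundary of gene 1
  tx <- b$genes[[1L]]$transcripts[[1L]]
  straddle <- interval("chrS", tx$exons$end[1L] - 10L, tx$exons$end[1L] + 10L,
                       tx$strand)
  a2 <- classify_mirna_location(list(mirna_gene_id = "mir-y", locus = straddle),
                                b$genes)
  expect_equal(a2$category, "exonic")
})

test_that("the host-gene fixture places its miRNA in intron 11 at 684 nt", {
  z <- zfr_like_fixture()
  b <- load_annotation_bundle(z$paths$genes, z$paths$mirnas, z$paths$mature,
                              z$paths$genome)
  a <- classify_mirna_location(b$mirnas[[1L]], b$genes)
  expect_equal(a$category, "intronic")
  expect_equal(a$intron_index, 11L)
  expect_equal(a$distance_to_upstream_exon, 684L)
})

test_that("host-targeting calls recover the planted HT/NT labels", {
  co <- generate_cohort(sim_config(rng_seed = 17, n_genes = 20,
                                   n_intronic_mirnas = 10, fraction_HT = 0.5,
                                   n_priming_decoys = 0))
  b <- load_annotation_bundle(co$paths$genes, co$paths$mirnas, co$paths$mature,
                              co$paths$genome)
  utrs <- lapply(b$genes, extract_utr_sequence, genome = b$genome)
  asg <- lapply(b$mirnas, classify_mirna_location, genes = b$genes)
  calls <- classify_host_targeting(asg, b$mirnas, utrs)
  expect_equal(nrow(calls), 10L)
  truth <- co$truth$arms
  m <- merge(calls, truth, by = c("mirna_gene_id", "arm_name"))
  expect_equal(m$is_HT.x, m$is_HT.y)
  expect_equal(sum(calls$is_HT), 5L)
  expect_true(all(calls$n_matches[calls$is_HT] >= 1L))
  expect_true(all(calls$n_matches[!calls$is_HT] == 0L))

  # permutation invariance of the input order
  calls2 <- classify_host_targeting(rev(asg), b$mirnas, utrs)
  expect_equal(calls, calls2)
})

test_that("zero host-targeting fraction yields zero HT calls", {
  co <- generate_cohort(sim_config(rng_seed = 18, n_genes = 8,
                                   n_intronic_mirnas = 4, fraction_HT = 0,
                                   n_priming_decoys = 0))
  b <- load_annotation_bundle(co$paths$genes, co$paths$mirnas, co$paths$mature,
                              co$paths$genome)
  utrs <- lapply(b$genes, extract_utr_sequence, genome = b$genome)
  asg <- lapply(b$mirnas, classify_mirna_location, genes = b$genes)
  expect_equal(sum(classify_host_targeting(asg, b$mirnas, utrs)$is_HT), 0L)
})

test_that("cohort summary reports planted UTR-length medians and null MWU p", {
  co <- generate_cohort(sim_config(rng_seed = 19, n_genes = 12,
                                   n_intronic_mirnas = 12, fraction_HT = 0.5,
                                   utr_length_range = c(1000L, 1000L),
                                   utr_length_range_ht = c(2000L, 2000L),
                                   n_priming_decoys = 0))
  b <- load_annotation_bundle(co$paths$genes, co$paths$mirnas, co$paths$mature,
                              co$paths$genome)
  utrs <- lapply(b$genes, extract_utr_sequence, genome = b$genome)
  asg <- lapply(b$mirnas, classify_mirna_location, genes = b$genes)
  calls <- classify_host_targeting(asg, b$mirnas, utrs)
  s <- cohort_summary(calls, utrs)
  expect_equal(s$median_utr_ht, 2000)
  expect_equal(s$median_utr_nt, 1000)
  expect_lt(s$p_utr_length, 0.05)

  # identical distributions: p = 1 under the exact permutation test
  same <- cohort_summary(
    data.frame(mirna_gene_id = c("a", "b"), arm_name = "-5p",
               category = "intronic", host_gene_id = c("g1", "g2"),
               is_HT = c(TRUE, FALSE), n_matches = c(1L, 0L)),
    list(g1 = make_utr(random_rna(500), "g1"),
         g2 = make_utr(random_rna(500), "g2")))
  expect_equal(same$median_utr_ht, same$median_utr_nt)
  expect_gt(same$p_utr_length, 0.9)
})
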