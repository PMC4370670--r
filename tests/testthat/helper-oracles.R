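# Independent brute-force oracles, deliberately written without reusing any
# package internals.

RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

oracle_revcomp_rna <- function(s) {
  ch <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
  paste(RNA_COMP[ch], collapse = "")
}

# position-by-position seed-match scan (0-based offsets)
oracle_seed_matches <- function(utr_seq, mature) {
  L <- nchar(utr_seq)
  if (L < 7L || nchar(mature) < 8L) return(data.frame(utr_offset = integer(0),
                                                      site_type = character(0)))
  m8 <- oracle_revcomp_rna(substr(mature, 2, 8))
  a1 <- paste0(oracle_revcomp_rna(substr(mature, 2, 7)), "A")
  off <- integer(0); typ <- character(0)
  for (i in 0:(L - 7L)) {
    k <- substr(utr_seq, i + 1L, i + 7L)
    if (k == m8) { off <- c(off, i); typ <- c(typ, "7mer-m8") }
    else if (k == a1) { off <- c(off, i); typ <- c(typ, "7mer-A1") }
  }
  data.frame(utr_offset = off, site_type = typ, stringsAsFactors = FALSE)
}

# exact permutation Mann-Whitney p: 2*min(tails), enumerating all labelings
oracle_mwu_p <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y)
  r <- rank(pooled)
  u <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, u)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# minimum-likelihood two-sided binomial p by direct enumeration
oracle_binom_p <- function(x, n, p0) {
  if (n == 0) return(1)
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# minimum-likelihood two-sided Fisher p over the hypergeometric support
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  pr <- dhyper(support, m1, m2, k)
  sum(pr[pr <= dhyper(a, m1, m2, k) * (1 + 1e-7)])
}

# step-up BH by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  run_min <- 1
  for (r in m:1) {
    run_min <- min(run_min, p[o[r]] * m / r)
    q[o[r]] <- run_min
  }
  pmin(q, 1)
}

# wrap a bare RNA string as a utr_sequence on a dummy plus-strand interval
make_utr <- function(seq, gene_id = "G", chrom = "chrT", start = 1000L) {
  structure(list(gene_id = gene_id, seq = seq, length = nchar(seq),
                 genomic = interval(chrom, start, start + nchar(seq), "+")),
            class = "utr_sequence")
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

rbind_all_test <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

genome_fetch_for_test <- function(genome, iv) {
  as.character(Biostrings::subseq(genome[[iv$chrom]], iv$start + 1L, iv$end))
}

# tiny two-exon gene annotation written to disk; returns file paths
write_toy_annotation <- function(dir, strand = "+", utr_seq = "ACGTACGTACGT") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # layout: exon1 [100,200) CDS; intron [200,300); exon2 [300,300+50+L):
  # 50 nt CDS then the 3'UTR
  L <- nchar(utr_seq)
  g_end <- 300L + 50L + L
  chrom_len <- g_end + 100L
  set.seed(99L)
  chrom <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  if (strand == "+") {
    chrom[(300L + 50L + 1L):(300L + 50L + L)] <- strsplit(chartr("U", "T", utr_seq),
                                                          "")[[1L]]
    utr_g <- c(350L, 350L + L)
    cds_row <- c(100L + 1L, 350L)
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
    sense <- strsplit(chartr("U", "T", utr_seq), "")[[1L]]
    # minus-strand gene occupies the same span; UTR is at the genomic start
    chrom[100L:(100L + L - 1L)] <- rev(unname(comp[sense]))
    utr_g <- c(99L, 99L + L)
    cds_row <- c(99L + L + 1L, g_end)
  }
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chrT", paste(chrom, collapse = "")), fa)
  gff <- file.path(dir, "genes.gff3")
  if (strand == "+") {
    rows <- c(
      paste("chrT", "t", "gene", 101, g_end, ".", strand, ".", "ID=G1", sep = "\t"),
      paste("chrT", "t", "mRNA", 101, g_end, ".", strand, ".", "ID=G1.t1;Parent=G1", sep = "\t"),
      paste("chrT", "t", "exon", 101, 200, ".", strand, ".", "Parent=G1.t1", sep = "\t"),
      paste("chrT", "t", "exon", 301, g_end, ".", strand, ".", "Parent=G1.t1", sep = "\t"),
      paste("chrT", "t", "CDS", 101, 350, ".", strand, ".", "Parent=G1.t1", sep = "\t"),
      paste("chrT", "t", "three_prime_UTR", 351, 350 + L, ".", strand, ".", "Parent=G1.t1", sep = "\t"))
  } else {
    rows <- c(
      paste("chrT", "t", "gene", 100, g_end, ".", strand, ".", "ID=G1", sep = "\t"),
      paste("chrT", "t", "mRNA", 100, g_end, ".", strand, ".", "ID=G1.t1;Parent=G1", sep = "\t"),
      paste("chrT", "t", "exon", 100, 99 + L + 50, ".", strand, ".", "Parent=G1.t1", sep = "\t"),
      paste("chrT", "t", "exon", 99 + L + 151, g_end, ".", strand, ".", "Parent=G1.t1", sep = "\t"),
      paste("chrT", "t", "CDS", 99 + L + 1, g_end, ".", strand, ".", "Parent=G1.t1", sep = "\t"),
      paste("chrT", "t", "three_prime_UTR", 100, 99 + L, ".", strand, ".", "Parent=G1.t1", sep = "\t"))
  }
  writeLines(c("##gff-version 3", rows), gff)
  mir <- file.path(dir, "mirnas.gff3")
  writeLines(c("##gff-version 3",
               paste("chrT", "t", "miRNA_primary_transcript", 221, 260, ".",
                     strand, ".", "ID=mir-1", sep = "\t")), mir)
  mat <- file.path(dir, "mature.tsv")
  writeLines(c("mirna_gene_id\tarm_name\tmature_seq",
               "mir-1\t-5p\tUCGGAAUCCUUAAGGCAUUCA"), mat)
  list(genome = fa, genes = gff, mirnas = mir, mature = mat)
}
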