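# Promoter extraction coordinates, background frequencies, PWM construction,
# scanning vs the exhaustive oracle, merging, masking and the match matrix.

test_that("extract_promoter window arithmetic and truncation", {
  set.seed(71)
  contig <- random_seq(20000)
  genome <- c(chrA = contig)

  # plus strand, TSS at 10001: 5500 bp starting at genomic 5001
  r <- extract_promoter(genome, "g1", "chrA", 10001, "+")
  expect_equal(nchar(r$sequence), 5500)
  expect_equal(r$sequence, substr(contig, 5001, 10500))

  # minus strand: reverse complement of the mirrored window (coordinate
  # oracle by independent slicing)
  rm <- extract_promoter(genome, "g2", "chrA", 10001, "-")
  expect_equal(rm$sequence, oracle_revcomp(substr(contig, 9502, 15001)))

  # TSS near the contig start: upstream side truncated
  rt <- extract_promoter(genome, "g3", "chrA", 100, "+")
  expect_equal(nchar(rt$sequence), 599)  # positions 1..599
  expect_equal(rt$truncated, "upstream")

  expect_error(extract_promoter(genome, "g", "chrB", 100, "+"), "absent")
  # mask mapping: genomic interval lands at the right local offset
  masks <- data.frame(chrom = "chrA", start = 5000L, end = 5008L)
  r2 <- extract_promoter(genome, "g1", "chrA", 10001, "+", masks = masks)
  expect_equal(unname(r2$mask_intervals[1, ]), c(0, 8))
  expect_equal(r2$nonmasked_length, 5500 - 8)
  # same mask through the minus-strand mirror
  masks2 <- data.frame(chrom = "chrA", start = 15001L - 8L, end = 15001L)
  rm2 <- extract_promoter(genome, "g2", "chrA", 10001, "-", masks = masks2)
  expect_equal(unname(rm2$mask_intervals[1, ]), c(0, 8))
})

test_that("empirical_background counts non-masked, non-N bases", {
  alt <- promoter_region("g", "c", 1, "+",
                         paste(rep("ACGT", 25), collapse = ""))
  expect_equal(unname(empirical_background(list(alt))), rep(0.25, 4))

  # 20 bp with an 8 bp mask: count the remaining 12 by hand
  seq20 <- "AAAACCCCGGGGTTTTACGT"
  masked <- promoter_region("g", "c", 1, "+", seq20,
                            mask_intervals = matrix(c(4, 12), ncol = 2))
  # remaining: AAAA (1-4) + TTTTACGT (13-20) -> A5 C1 G1 T5 of 12
  expect_equal(unname(empirical_background(list(masked))),
               c(5, 1, 1, 5) / 12)

  # N bases excluded too
  withN <- promoter_region("g", "c", 1, "+", "AANN")
  expect_equal(unname(empirical_background(list(withN))), c(1, 0, 0, 0))
  expect_error(empirical_background(list(promoter_region("g", "c", 1, "+",
                                                         "NNNN"))),
               "usable")
})

test_that("ppm_to_pwm produces log2 odds with psi_max at the argmax", {
  uni <- new_ppm("u", matrix(0.25, 4, 5))
  pw <- ppm_to_pwm(uni)
  expect_true(pw$degenerate)
  expect_equal(pw$psi_max, 0)

  p <- new_ppm("x", matrix(c(0.93182, 0.02273, 0.02273, 0.02272), 4, 1))
  w <- ppm_to_pwm(p)$weights
  expect_equal(unname(w["A", 1]), log2(0.93182 / 0.25), tolerance = 1e-6)

  set.seed(72)
  rp <- random_ppm("r", 6)
  pw2 <- ppm_to_pwm(rp)
  argmax <- ppm_consensus(rp)
  expect_equal(pw2$psi_max, unname(oracle_window_psi(pw2$weights, argmax)))
  expect_error(ppm_to_pwm(rp, background = c(0, 0.5, 0.25, 0.25)), "> 0")
})

test_that("scan_pwm finds planted sites, merges overlaps, honors strand", {
  motif <- ppm_from_consensus("m", "GATTACA", q = 0.97)
  pwm <- ppm_to_pwm(motif)
  bg <- paste(rep("C", 100), collapse = "")
  seq <- paste0(substr(bg, 1, 40), "GATTACA", substr(bg, 48, 100))
  hits <- scan_pwm(pwm, seq)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 40)
  expect_equal(hits$best_ratio, 1, tolerance = 1e-9)
  expect_equal(hits$strand, "+")

  # reverse complement of the whole region: identical match count
  expect_equal(nrow(scan_pwm(pwm, oracle_revcomp(seq))), 1)

  # two overlapping hits merge into one interval
  m2 <- ppm_from_consensus("m2", "AAAA", q = 0.97)
  merged <- scan_pwm(ppm_to_pwm(m2), "GGGAAAAAGGG")
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(3, 8))

  expect_error(scan_pwm(ppm_to_pwm(new_ppm("u", matrix(0.25, 4, 4))), "ACGT"),
               "degenerate")
})

test_that("scan_pwm equals the brute-force oracle (incl. masks and Ns)", {
  set.seed(73)
  for (i in 1:30) {
    ppm <- random_ppm("r", sample(4:9, 1))
    pwm <- ppm_to_pwm(ppm)
    seq <- random_seq(120, bases = c("A", "C", "G", "T", "N"))
    mask <- matrix(c(30, 38), ncol = 2)
    region <- promoter_region("g", "c", 1, "+", seq, mask_intervals = mask)
    got <- scan_pwm(pwm, region, threshold = 0.7)
    masked <- rep(FALSE, 120)
    masked[31:38] <- TRUE
    want <- oracle_scan(pwm, seq, threshold = 0.7, masked = masked)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, unname(want[, 1]))
      expect_equal(got$end, unname(want[, 2]))
    }
  }
})

test_that("masking more bases never increases counts", {
  set.seed(74)
  ppm <- random_ppm("r", 5)
  pwm <- ppm_to_pwm(ppm)
  seq <- random_seq(300)
  base <- nrow(scan_pwm(pwm, seq, threshold = 0.75))
  for (mstart in c(0, 50, 150)) {
    region <- promoter_region("g", "c", 1, "+", seq,
                              mask_intervals = matrix(c(mstart, mstart + 40),
                                                      ncol = 2))
    expect_lte(nrow(scan_pwm(pwm, region, threshold = 0.75)), base)
  }
})

test_that("build_match_matrix recovers isolated planted instances", {
  gm <- generate_motifs(4, width_range = c(7, 10), seed = 75)
  dict <- motif_dictionary(gm$records)
  pr <- generate_promoters(dict, n_genes = 12, length = 900, rate_deg = 1.5,
                           rate_bg = 0.8, mask_fraction = 0, seed = 76)
  mm <- build_match_matrix(dict, pr$regions)
  expect_equal(dim(mm$counts), c(12L, 4L))
  expect_true(all(mm$counts >= 0))
  planted <- table(factor(pr$truth$gene_id, levels = rownames(mm$counts)),
                   factor(pr$truth$motif_id, levels = colnames(mm$counts)))
  # planted instances are found (spurious background hits may add more)
  expect_true(all(mm$counts >= planted))

  # all-N promoter: zero counts and zero non-masked length
  nreg <- promoter_region("gN", "gN", 1, "+", strrep("N", 900))
  expect_equal(nreg$nonmasked_length, 0)
  mmN <- build_match_matrix(dict, c(pr$regions[1], list(gN = nreg)),
                            background = "uniform")
  expect_true(all(mmN$counts["gN", ] == 0))
})

test_that("motif_density_fold arithmetic and pooling additivity", {
  m2 <- ppm_from_consensus("m2", "GGATCC", q = 0.97)
  pwm <- ppm_to_pwm(m2)
  seq <- paste0(strrep("A", 300), "GGATCC", strrep("A", 300),
                "GGATCC", strrep("A", 388))
  region <- promoter_region("g", "c", 1, "+", seq)
  expect_equal(motif_density_fold(region, pwm, genomewide_mean_density = 1),
               2 / 1)  # 2 matches in exactly 1 kb
  expect_equal(motif_density_fold(promoter_region("g", "c", 1, "+",
                                                  strrep("A", 500)),
                                  pwm, 1), 0)
  # pooling halves equals the whole
  left <- promoter_region("gl", "c", 1, "+", substr(seq, 1, 500))
  right <- promoter_region("gr", "c", 1, "+", substr(seq, 501, 1000))
  nl <- nrow(scan_pwm(pwm, left)); nr <- nrow(scan_pwm(pwm, right))
  pooled <- ((nl + nr) / 1) / 1
  expect_equal(pooled,
               motif_density_fold(region, pwm, genomewide_mean_density = 1))
  expect_error(motif_density_fold(region, pwm, 0), "> 0")
})

test_that("genome/TSS/mask round-trip through files reproduces regions", {
  gm <- generate_motifs(3, seed = 77)
  pr <- generate_promoters(motif_dictionary(gm$records), n_genes = 4,
                           length = 700, seed = 78)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "masks.bed")
  write_genome_fasta(pr$genome, fa)
  write_mask_bed(pr$masks, bed)
  genome <- read_genome_fasta(fa)
  masks <- read_mask_bed(bed)
  regs <- extract_promoters(genome, pr$tss_table, masks,
                            upstream = 200, downstream = 500)
  for (g in names(pr$regions)) {
    expect_equal(regs[[g]]$sequence, pr$regions[[g]]$sequence)
    expect_equal(regs[[g]]$mask_intervals, pr$regions[[g]]$mask_intervals)
  }
})
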