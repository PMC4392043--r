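# Motif matrix conversion, trimming, consensus, redundancy filtering,
# parsing, and curation-pipeline properties.

test_that("pfm_to_ppm applies the split pseudocount correctly", {
  even <- new_pfm("even", matrix(1, 4, 1))
  expect_equal(unname(pfm_to_ppm(even, 0.8)$probs[, 1]), rep(0.25, 4))

  zero <- new_pfm("zero", matrix(0, 4, 1))
  expect_equal(unname(pfm_to_ppm(zero, 0.8)$probs[, 1]), rep(0.25, 4))

  skew <- new_pfm("skew", matrix(c(8, 0, 0, 0), 4, 1))
  p <- pfm_to_ppm(skew, 0.8)$probs[, 1]
  expect_equal(unname(p), c(8.2, 0.2, 0.2, 0.2) / 8.8)
  expect_equal(sum(p), 1)

  expect_error(new_pfm("bad", matrix(c(-1, 1, 1, 1), 4, 1)), "non-negative")
  expect_error(pfm_to_ppm(even, pseudocount = 0))
})

test_that("column_ic matches closed forms and validates input", {
  expect_equal(column_ic(rep(0.25, 4)), 0)
  expect_equal(column_ic(c(1, 0, 0, 0)), 2)
  expect_equal(column_ic(c(0.5, 0.5, 0, 0)), 1)
  expect_error(column_ic(c(0.5, 0.2, 0.1, 0.1)), "sum")
})

# columns with IC just above / just below the 0.25 trimming threshold
col_hi <- col_q("A", 0.55)    # IC ~ 0.294
col_lo <- col_q("A", 0.50)    # IC ~ 0.208
col_zero <- rep(0.25, 4)
col_two <- c(1, 0, 0, 0)

test_that("trim_ppm applies strict then relaxed flank rules", {
  # IC pattern (0, 0, 2, 2, 2, 2, 0) -> strict keeps columns 3..6
  p1 <- new_ppm("p1", cbind(col_zero, col_zero, col_two, col_two,
                            col_two, col_two, col_zero))
  t1 <- trim_ppm(p1)
  expect_equal(ncol(t1$probs), 4)
  expect_equal(unname(t1$probs), unname(p1$probs[, 3:6]))
  expect_equal(attr(t1, "trim_rule"), "strict")

  # all uniform -> discarded
  expect_null(trim_ppm(new_ppm("u", matrix(0.25, 4, 6))))

  # IC pattern (0, hi, lo, hi, hi): strict width 2 < 4, relaxed keeps 2..5
  p2 <- new_ppm("p2", cbind(col_zero, col_hi, col_lo, col_hi, col_hi))
  expect_gt(column_ic(col_hi), 0.25)
  expect_lt(column_ic(col_lo), 0.25)
  t2 <- trim_ppm(p2)
  expect_equal(unname(t2$probs), unname(p2$probs[, 2:5]))
  expect_equal(attr(t2, "trim_rule"), "relaxed")

  # relaxed result narrower than 4 -> discarded
  p3 <- new_ppm("p3", cbind(col_zero, col_hi, col_hi, col_hi, col_zero))
  expect_null(trim_ppm(p3))
})

test_that("ppm_to_iupac uses the p >= 0.25 degenerate-set rule", {
  expect_equal(ppm_to_iupac(new_ppm("a", matrix(c(1, 0, 0, 0), 4, 1))), "A")
  expect_equal(ppm_to_iupac(new_ppm("m", matrix(c(0.5, 0.5, 0, 0), 4, 1))), "M")
  expect_equal(ppm_to_iupac(new_ppm("n", matrix(0.25, 4, 1))), "N")
  expect_equal(
    ppm_to_iupac(new_ppm("x", cbind(c(1, 0, 0, 0), c(0, 0, 0.3, 0.7)))), "AK")
})

test_that("dedup_consensus removes lower-IC same-consensus twins only", {
  a <- record_from_ppm(ppm_from_consensus("mA", "ACGT", q = 0.91))
  b <- record_from_ppm(ppm_from_consensus("mB", "ACGT", q = 0.91))
  dd <- dedup_consensus(list(a, b))
  expect_length(dd$kept, 1)
  expect_equal(dd$kept[[1]]$motif_id, "mA")  # equal IC: id order
  expect_equal(dd$removed$kept_id, "mA")
  expect_equal(dd$removed$step, "consensus_dedup")

  # same consensus but mean |delta PPM| = 0.06 > 0.05: both kept
  hi <- record_from_ppm(ppm_from_consensus("hi", "AAAA", q = 0.82))
  lo <- record_from_ppm(ppm_from_consensus("lo", "AAAA", q = 0.70))
  expect_equal(mean(abs(ppm_from_consensus("x", "AAAA", 0.82)$probs -
                        ppm_from_consensus("x", "AAAA", 0.70)$probs)), 0.06)
  expect_length(dedup_consensus(list(hi, lo))$kept, 2)

  # mean |delta| = 0.04 <= 0.05: lower-IC removed
  lo2 <- record_from_ppm(ppm_from_consensus("lo2", "AAAA", q = 0.74))
  dd2 <- dedup_consensus(list(hi, lo2))
  expect_equal(vapply(dd2$kept, `[[`, character(1), "motif_id"), "hi")

  # same consensus string, different widths: untouched at this stage
  w4 <- record_from_ppm(ppm_from_consensus("w4", "AAAA"))
  w5 <- record_from_ppm(ppm_from_consensus("w5", "AAAAA"))
  expect_length(dedup_consensus(list(w4, w5))$kept, 2)
})

test_that("motif_distance is a symmetric alignment distance", {
  a <- ppm_from_consensus("a", "GATTACA", q = 0.8)
  expect_equal(motif_distance(a, a), 0)
  expect_equal(motif_distance(a, ppm_revcomp(a)), 0)

  b <- ppm_from_consensus("b", "CCCGGG", q = 0.8)
  expect_equal(motif_distance(a, b), motif_distance(b, a))

  # brute-force oracle over all offsets and both orientations
  oracle_distance <- function(x, y, min_overlap = 4) {
    best <- -Inf
    for (py in list(y$probs, ppm_revcomp(y)$probs)) {
      ma <- ncol(x$probs); mb <- ncol(py)
      for (sa in seq_len(ma)) for (sb in seq_len(mb)) {
        n <- min(ma - sa, mb - sb) + 1
        if (n < min_overlap) next
        # only alignments where one matrix starts at its first column are
        # distinct offsets
        if (sa > 1 && sb > 1) next
        u <- as.vector(x$probs[, sa:(sa + n - 1)])
        v <- as.vector(py[, sb:(sb + n - 1)])
        if (sd(u) == 0 || sd(v) == 0) next
        best <- max(best, cor(u, v))
      }
    }
    if (!is.finite(best)) 1 else 1 - best
  }
  set.seed(11)
  for (i in 1:20) {
    x <- random_ppm("x", sample(4:9, 1))
    y <- random_ppm("y", sample(4:9, 1))
    expect_equal(motif_distance(x, y), oracle_distance(x, y), tolerance = 1e-12)
  }
  polyA <- ppm_from_consensus("pa", "AAAAA", q = 0.97)
  polyC <- ppm_from_consensus("pc", "CCCCC", q = 0.97)
  expect_equal(motif_distance(polyA, polyC), oracle_distance(polyA, polyC))
  expect_gt(motif_distance(polyA, polyC), 1)  # anti-correlated
})

test_that("collapse_similar keeps the highest-IC member per linkage group", {
  a <- record_from_ppm(ppm_from_consensus("a", "GATTAC", q = 0.90))
  b <- record_from_ppm(ppm_from_consensus("b", "GATTAC", q = 0.90))
  c3 <- record_from_ppm(ppm_from_consensus("c", "GATTAC", q = 0.90))
  cs <- collapse_similar(list(a, b, c3))
  expect_length(cs$kept, 1)
  expect_equal(nrow(cs$removed), 2)
  expect_true(all(cs$removed$kept_id == cs$kept[[1]]$motif_id))

  far <- record_from_ppm(ppm_from_consensus("far", "CCGGCC", q = 0.90))
  cs2 <- collapse_similar(list(a, far))
  expect_length(cs2$kept, 2)

  # single-linkage closure: a~b and b~c under a threshold that a-c misses
  set.seed(21)
  base1 <- random_ppm("a1", 6)
  base2 <- random_ppm("c1", 6)
  mid <- new_ppm("b1", sweep(0.5 * base1$probs + 0.5 * base2$probs, 2,
                             colSums(0.5 * base1$probs + 0.5 * base2$probs),
                             "/"))
  dab <- motif_distance(base1, mid)
  dbc <- motif_distance(mid, base2)
  dac <- motif_distance(base1, base2)
  thr <- (max(dab, dbc) + dac) / 2
  expect_true(max(dab, dbc) < thr && thr < dac)  # valid chain construction
  cs3 <- collapse_similar(lapply(list(base1, mid, base2), record_from_ppm),
                          distance_threshold = thr)
  expect_length(cs3$kept, 1)
})

test_that("parse_motifs reads all three dialects and round-trips", {
  # JASPAR counts
  jf <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M001 testA",
               "A [ 4 19  0 ]",
               "C [16  0 20 ]",
               "G [ 0  1  0 ]",
               "T [ 0  0  0 ]",
               ">M002 testB",
               "1 2 3 4",
               "0 0 0 0",
               "1 1 1 1",
               "2 2 2 2"), jf)
  pfms <- parse_motifs(jf, "jaspar_counts")
  expect_length(pfms, 2)
  expect_equal(ncol(pfms[[1]]$counts), 3)
  expect_equal(unname(pfms[[1]]$counts["C", ]), c(16, 0, 20))
  jf2 <- withr::local_tempfile()
  write_motifs(pfms, jf2, "jaspar_counts")
  rt <- parse_motifs(jf2, "jaspar_counts")
  expect_equal(rt[[1]]$counts, pfms[[1]]$counts)

  # MEME probabilities
  mf <- withr::local_tempfile(fileext = ".meme")
  ppm <- ppm_from_consensus("MX", "GATA", q = 0.88)
  write_motifs(list(ppm), mf, "meme_probs")
  back <- parse_motifs(mf, "meme_probs")
  expect_length(back, 1)
  expect_lt(max(abs(back[[1]]$probs - ppm$probs)), 2e-6)  # 6-decimal files
  expect_equal(back[[1]]$pseudocount, 0)
  expect_equal(colSums(back[[1]]$probs), rep(1, 4), ignore_attr = TRUE)

  # TRANSFAC-like
  tf <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID  motifT", "P0  A C G T",
               "01  1 2 3 4 N", "02  4 0 0 0 A", "//"), tf)
  tfs <- parse_motifs(tf, "transfac_like")
  expect_length(tfs, 1)
  expect_equal(unname(tfs[[1]]$counts[, 1]), c(1, 2, 3, 4))
  expect_equal(unname(tfs[[1]]$counts[, 2]), c(4, 0, 0, 0))

  # ragged rows -> error naming the offending line
  bad <- withr::local_tempfile()
  writeLines(c(">B1", "1 2 3", "1 2", "1 2 3", "1 2 3"), bad)
  expect_error(parse_motifs(bad, "jaspar_counts"), "line 3")
})

test_that("curation pipeline: provenance, sizes and tie-break order", {
  set.seed(31)
  gm <- generate_motifs(18, n_families = 3, n_duplicates = 4, seed = 17)
  dict <- curate_dictionary(gm$records)
  n_in <- length(gm$records)

  # every removed motif logged exactly once, with a surviving superseder
  expect_equal(length(dict$records) + nrow(dict$provenance), n_in)
  expect_false(anyDuplicated(dict$provenance$motif_id) > 0)
  sup <- dict$provenance$kept_id[dict$provenance$step != "trim_discard"]
  expect_true(all(sup %in% names(dict$records)))

  # width >= 4 and duplicates collapsed
  expect_true(all(vapply(dict$records,
                         function(r) ncol(r$ppm$probs), integer(1)) >= 4))
  dup_ids <- grep("dup$", vapply(gm$records, `[[`, character(1), "motif_id"),
                  value = TRUE)
  expect_true(all(vapply(gm$records[seq_along(dup_ids)], function(r) {
    !(paste0(r$motif_id, "dup") %in% names(dict$records)) ||
      !(r$motif_id %in% names(dict$records))
  }, logical(1))))

  # avg IC of a kept motif >= every record it superseded in distance collapse
  dc <- dict$provenance[dict$provenance$step == "distance_collapse", ]
  if (nrow(dc) > 0) {
    ic_in <- vapply(gm$records, `[[`, numeric(1), "avg_ic")
    names(ic_in) <- vapply(gm$records, `[[`, character(1), "motif_id")
    for (i in seq_len(nrow(dc))) {
      expect_gte(dict$records[[dc$kept_id[i]]]$avg_ic, ic_in[dc$motif_id[i]])
    }
  }

  # order-insensitivity up to exact-tie groups: permuted input, same ids
  perm <- sample(gm$records)
  dict2 <- curate_dictionary(perm)
  expect_setequal(names(dict2$records), names(dict$records))
})

test_that("dictionary serialization round-trips", {
  gm <- generate_motifs(6, seed = 23)
  dict <- curate_dictionary(gm$records)
  dir <- withr::local_tempdir()
  write_dictionary(dict, dir)
  back <- read_dictionary(dir)
  expect_setequal(names(back$records), names(dict$records))
  for (id in names(dict$records)) {
    expect_lt(max(abs(back$records[[id]]$ppm$probs -
                      dict$records[[id]]$ppm$probs)), 2e-6)
    expect_equal(back$records[[id]]$genes, dict$records[[id]]$genes)
  }
  expect_equal(nrow(back$provenance), nrow(dict$provenance))
})
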