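# Risk-allele scoring vs the exhaustive oracle, classification thresholds,
# panel summaries, group comparisons, the resampling null and filtering.

test_that("risk_allele_effect: antisymmetry and the disrupted toy case", {
  motif <- ppm_from_consensus("gaaa", "GAAA", q = 0.97)
  pwm <- ppm_to_pwm(motif)
  flank <- paste0("CCCCCCC", "GAAA", "CCCCCCC")  # planted match, center = G
  snp <- snp_record("s1", "c", 8, risk_allele = "T", nonrisk_allele = "G",
                    flank = flank, center = 8)
  eff <- risk_allele_effect(pwm, snp)
  expect_lt(eff$effect, 0)
  expect_equal(eff$change, "disrupted")
  ora <- oracle_snp_effect(pwm, snp)
  expect_equal(eff$effect, ora$effect, tolerance = 1e-12)
  expect_equal(eff$psi_r, ora$psi_r)
  expect_equal(eff$psi_nr, ora$psi_nr)

  # swapping the alleles flips the sign exactly
  swp <- snp_record("s1r", "c", 8, risk_allele = "G", nonrisk_allele = "T",
                    flank = flank, center = 8)
  effs <- risk_allele_effect(pwm, swp)
  expect_equal(effs$effect, -eff$effect)
  expect_equal(effs$change, "engendered")

  expect_error(snp_record("bad", "c", 1, "AT", "A", "AAAA", 2), "indel")
  expect_error(risk_allele_effect(
    pwm, snp_record("short", "c", 2, "A", "C", "CCA", 2)), "flank too short")
})

test_that("risk_allele_effect agrees with the exhaustive-window oracle", {
  set.seed(91)
  for (i in 1:30) {
    ppm <- random_ppm("r", sample(4:8, 1))
    pwm <- ppm_to_pwm(ppm)
    flank <- random_seq(21)
    alleles <- sample(c("A", "C", "G", "T"), 2)
    substr(flank, 11, 11) <- alleles[1]
    snp <- snp_record("s", "c", 11, alleles[2], alleles[1], flank, 11)
    got <- risk_allele_effect(pwm, snp)
    want <- oracle_snp_effect(pwm, snp)
    expect_equal(got$effect, want$effect, tolerance = 1e-12)
  }
})

test_that("classify_binding_change applies thresholds exactly", {
  expect_equal(classify_binding_change(0.90, 0.70, 1), "engendered")
  expect_equal(classify_binding_change(0.70, 0.90, 1), "disrupted")
  expect_equal(classify_binding_change(0.82, 0.78, 1), "none")
  expect_equal(classify_binding_change(0.85, 0.70, 1), "none")  # not strict >
  expect_error(classify_binding_change(1, 1, 0), "psi_max > 0")
})

test_that("summarize_risk_effects counts, percentages, ratio", {
  grid <- expand.grid(snp_id = paste0("s", 1:4),
                      motif_id = paste0("m", 1:5),
                      stringsAsFactors = FALSE)
  grid$change <- "none"
  grid$change[1:3] <- "disrupted"
  grid$change[4:5] <- "engendered"
  s <- summarize_risk_effects(grid)
  expect_equal(s$total, 20)
  expect_equal(s$n_disrupted, 3)
  expect_equal(s$n_engendered, 2)
  expect_equal(s$pct_changed, 100 * 5 / 20)
  expect_equal(s$ratio, 1.5)
  expect_equal(s$n_engendered + s$n_disrupted +
                 sum(grid$change == "none"), s$total)

  grid$change[4:5] <- "none"
  s0 <- summarize_risk_effects(grid)
  expect_true(s0$ratio_undefined)
  expect_true(is.na(s0$ratio))

  expect_error(summarize_risk_effects(grid[1:7, ]), "cross product")
})

test_that("group_effect_comparison targets the median difference", {
  set.seed(92)
  snps <- paste0("s", 1:11)
  eff_for <- function(mid, shift) {
    data.frame(snp_id = snps, motif_id = mid,
               effect = shift + rnorm(11, 0, 0.01))
  }
  pre <- do.call(rbind, lapply(paste0("pre", 1:50), eff_for, shift = -0.05))
  oth <- do.call(rbind, lapply(paste0("oth", 1:200), eff_for, shift = 0))
  effects <- rbind(pre, oth)
  res <- group_effect_comparison(effects, paste0("pre", 1:50),
                                 paste0("oth", 1:200))
  expect_lt(res$p, 0.01)
  expect_lt(res$median_a, res$median_b)

  # equal medians, different spread: large p (median-targeted design)
  sp1 <- do.call(rbind, lapply(paste0("a", 1:40), function(m)
    data.frame(snp_id = snps, motif_id = m,
               effect = median(c(-1, 0, 1)) + sample(c(-0.001, 0, 0.001), 11,
                                                     replace = TRUE))))
  sp2 <- do.call(rbind, lapply(paste0("b", 1:40), function(m)
    data.frame(snp_id = snps, motif_id = m,
               effect = sample(c(-0.5, 0, 0.5), 11, replace = TRUE))))
  res2 <- group_effect_comparison(rbind(sp1, sp2), paste0("a", 1:40),
                                  paste0("b", 1:40))
  expect_gt(res2$p, 0.05)

  expect_error(group_effect_comparison(effects, "pre1", paste0("oth", 1:5)),
               ">= 2")
})

test_that("simulation_null is seeded, bounded and self-consistent", {
  gm <- generate_motifs(3, width_range = c(6, 8), seed = 93)
  dict <- motif_dictionary(gm$records)
  pr <- generate_promoters(dict, n_genes = 8, length = 600, mask_fraction = 0,
                           seed = 94)
  pwms <- lapply(dict_records <- lapply(dict$records, `[[`, "ppm"),
                 ppm_to_pwm)
  sampler <- make_null_snp_sampler(pr, flank_half = 10)
  snps <- sampler(6, seed = 95)
  obs <- summarize_risk_effects(score_snp_panel(pwms, snps))

  expect_warning(r1 <- simulation_null(sampler, pwms, obs, n_trials = 40,
                                       seed = 7), "coarse")
  r2 <- suppressWarnings(simulation_null(sampler, pwms, obs, n_trials = 40,
                                         seed = 7))
  expect_identical(r1$trials, r2$trials)  # same seed, same trials

  # observed beyond every trial: p hits the 1/(1+n) bound
  obs_hi <- obs
  obs_hi$pct_changed <- 101
  r3 <- suppressWarnings(simulation_null(sampler, pwms, obs_hi,
                                         n_trials = 40, seed = 7))
  expect_equal(unname(r3$p_upper["pct_changed"]), 1 / 41)
  expect_equal(unname(r3$p_lower["pct_changed"]), 1)
})

test_that("filter_candidate_sites applies the conservation/DEG OR-rule", {
  eff <- data.frame(
    snp_id = paste0("s", 1:4), motif_id = c("m1", "m2", "m3", "m4"),
    effect = c(-0.3, 0.2, -0.5, -0.4),
    change = c("disrupted", "engendered", "none", "disrupted"),
    phastcons = c(0.9, 0.1, 0.95, 0.2), stringsAsFactors = FALSE)
  out <- filter_candidate_sites(eff, deg_encoded_motifs = "m2")
  expect_setequal(out$snp_id, c("s1", "s2"))   # s3: change none; s4: neither
  expect_equal(out$snp_id, c("s1", "s2"))      # sorted by |effect|
})

test_that("planted disrupt/engender SNPs classify correctly vs their motif", {
  gm <- generate_motifs(4, width_range = c(7, 10),
                        ic_per_column_range = c(1.2, 1.8), seed = 96)
  dict <- motif_dictionary(gm$records)
  pr <- generate_promoters(dict, n_genes = 25, length = 1500, rate_deg = 2,
                          rate_bg = 1, mask_fraction = 0, seed = 97)
  sp <- generate_snp_panel(pr, dict, n_snps = 40,
                           fractions = c(disrupt = 0.5, engender = 0.25,
                                         neutral = 0.25), seed = 98)
  pwms <- lapply(lapply(dict$records, `[[`, "ppm"), ppm_to_pwm)
  names(pwms) <- names(dict$records)
  tr <- sp$truth
  hits <- 0; tot <- 0
  for (i in which(tr$type != "neutral")) {
    snp <- sp$snps[[match(tr$snp_id[i],
                          vapply(sp$snps, `[[`, character(1), "snp_id"))]]
    got <- risk_allele_effect(pwms[[tr$motif_id[i]]], snp)
    want <- if (tr$type[i] == "disrupt") "disrupted" else "engendered"
    tot <- tot + 1
    hits <- hits + (got$change == want)
  }
  expect_gte(hits / tot, 0.95)
})
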