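# Risk-allele effects on PWM matches at SNP loci: per-allele best-match
# scoring, engendered/disrupted classification, panel summaries, motif-group
# comparisons, a resampling null, and candidate-site filtering.

#' Create a SNP record
#'
#' @param snp_id identifier.
#' @param chrom,pos locus (1-based `pos`).
#' @param risk_allele,nonrisk_allele single differing bases.
#' @param flank sequence string containing the locus; `center` is the 1-based
#'   index of the SNP base within `flank` (default: the middle base). The
#'   current flank base must equal one of the two alleles.
#' @param noncoding,enhancer logical annotation flags.
#' @param phastcons conservation probability in `[0, 1]` or `NA`.
#' @return an object of class `snp_record`.
#' @export
snp_record <- function(snp_id, chrom, pos, risk_allele, nonrisk_allele,
                       flank, center = (nchar(flank) + 1) %/% 2,
                       noncoding = TRUE, enhancer = FALSE,
                       phastcons = NA_real_) {
  risk_allele <- toupper(risk_allele)
  nonrisk_allele <- toupper(nonrisk_allele)
  if (nchar(risk_allele) != 1 || nchar(nonrisk_allele) != 1) {
    stop("unsupported variant: alleles must be single bases (no indels)")
  }
  if (!all(c(risk_allele, nonrisk_allele) %in% DNA_BASES)) {
    stop("alleles must be A, C, G or T")
  }
  if (risk_allele == nonrisk_allele) stop("alleles must differ")
  flank <- toupper(flank)
  cur <- substr(flank, center, center)
  if (!cur %in% c(risk_allele, nonrisk_allele)) {
    stop("flank center base matches neither allele")
  }
  structure(list(snp_id = snp_id, chrom = chrom, pos = pos,
                 risk_allele = risk_allele, nonrisk_allele = nonrisk_allele,
                 flank = flank, center = center, noncoding = noncoding,
                 enhancer = enhancer, phastcons = phastcons),
            class = "snp_record")
}

# best psi over the m windows containing position `center` of `seq`,
# both strands; windows with N are skipped
best_psi_at <- function(pwm, seq, center) {
  w <- pwm$weights
  m <- ncol(w)
  lo <- center - m + 1
  hi <- center + m - 1
  if (lo < 1 || hi > nchar(seq)) stop("flank too short for motif width ", m)
  sub <- substr(seq, lo, hi)
  idx <- seq_to_idx(sub)
  valid <- !vapply(seq_len(m), function(i) anyNA(idx[i:(i + m - 1)]), logical(1))
  if (!any(valid)) return(-Inf)
  sf <- pwm_window_scores(w, idx)
  sr <- pwm_window_scores(pwm_rc_weights(w), idx)
  max(pmax(sf, sr)[valid])
}

#' Risk-allele effect of a SNP on a motif
#'
#' For each allele, the SNP base is substituted into the flank and the best
#' match score (`psi`) over all windows containing the SNP position, on both
#' strands, is taken. The effect is `(psi_R - psi_NR) / psi_max`, and the
#' binding change is classified with [classify_binding_change()].
#'
#' @param pwm a [ppm_to_pwm()] model (uniform background is the convention
#'   for SNP-window scans).
#' @param snp a [snp_record()].
#' @param engender_hi,disrupt_lo classification thresholds (defaults 0.85
#'   and 0.75).
#' @return data.frame row with `snp_id`, `motif_id`, `psi_r`, `psi_nr`,
#'   `effect`, `change`.
#' @export
risk_allele_effect <- function(pwm, snp, engender_hi = 0.85,
                               disrupt_lo = 0.75) {
  stopifnot(inherits(pwm, "pwm_model"), inherits(snp, "snp_record"))
  if (pwm$degenerate) stop("degenerate PWM model")
  swap_base <- function(a) {
    s <- snp$flank
    substr(s, snp$center, snp$center) <- a
    s
  }
  psi_r <- best_psi_at(pwm, swap_base(snp$risk_allele), snp$center)
  psi_nr <- best_psi_at(pwm, swap_base(snp$nonrisk_allele), snp$center)
  effect <- (psi_r - psi_nr) / pwm$psi_max
  change <- classify_binding_change(psi_r, psi_nr, pwm$psi_max,
                                    engender_hi, disrupt_lo)
  data.frame(snp_id = snp$snp_id, motif_id = pwm$motif_id,
             psi_r = psi_r, psi_nr = psi_nr, effect = effect,
             change = change, stringsAsFactors = FALSE)
}

#' Classify a binding-site change between alleles
#'
#' Engendered: `psi_R/psi_max > engender_hi` and `psi_NR/psi_max <
#' disrupt_lo`. Disrupted: the mirror condition. Anything else is `none`.
#'
#' @param psi_r,psi_nr best-match scores per allele.
#' @param psi_max maximum attainable score (`> 0`).
#' @param engender_hi,disrupt_lo thresholds (defaults 0.85 / 0.75).
#' @return one of `"engendered"`, `"disrupted"`, `"none"`.
#' @export
classify_binding_change <- function(psi_r, psi_nr, psi_max,
                                    engender_hi = 0.85, disrupt_lo = 0.75) {
  stopifnot(psi_max > 0)
  rr <- psi_r / psi_max
  rn <- psi_nr / psi_max
  if (rr > engender_hi && rn < disrupt_lo) "engendered"
  else if (rr < disrupt_lo && rn > engender_hi) "disrupted"
  else "none"
}

#' Score every SNP against every motif
#'
#' @param pwms list of [ppm_to_pwm()] models (e.g. the enriched-motif set,
#'   uniform background).
#' @param snps list of [snp_record()]s.
#' @return data.frame with one row per SNP x motif combination.
#' @export
score_snp_panel <- function(pwms, snps) {
  stopifnot(length(pwms) > 0, length(snps) > 0)
  out <- vector("list", length(pwms) * length(snps))
  k <- 1L
  for (pw in pwms) {
    for (sn in snps) {
      out[[k]] <- risk_allele_effect(pw, sn)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}

#' Summarize risk-allele effects over a SNP x motif cross product
#'
#' @param effects data.frame from [score_snp_panel()] (must cover the full
#'   cross product of its SNPs and motifs).
#' @return list with `n_snps`, `n_motifs`, `total`, counts and percentages
#'   of engendered/disrupted combinations, `pct_changed`, the
#'   disrupted/engendered `ratio` and `ratio_undefined`.
#' @export
summarize_risk_effects <- function(effects) {
  if (is.null(effects) || nrow(effects) == 0) stop("no effects supplied")
  n_snps <- length(unique(effects$snp_id))
  n_motifs <- length(unique(effects$motif_id))
  total <- n_snps * n_motifs
  if (nrow(effects) != total) {
    stop("effects do not cover the full SNP x motif cross product")
  }
  n_eng <- sum(effects$change == "engendered")
  n_dis <- sum(effects$change == "disrupted")
  list(n_snps = n_snps, n_motifs = n_motifs, total = total,
       n_engendered = n_eng, n_disrupted = n_dis,
       pct_engendered = 100 * n_eng / total,
       pct_disrupted = 100 * n_dis / total,
       pct_changed = 100 * (n_eng + n_dis) / total,
       ratio = if (n_eng > 0) n_dis / n_eng else NA_real_,
       ratio_undefined = n_eng == 0)
}

#' Compare median risk-allele effects between two motif groups
#'
#' Each motif is reduced to its median effect across SNPs; the two groups'
#' median-effect vectors are compared with a two-sided Wilcoxon rank-sum
#' test (a median-targeted comparison).
#'
#' @param effects data.frame from [score_snp_panel()].
#' @param group_a,group_b motif-id vectors (each of size >= 2).
#' @return list with `medians_a`, `medians_b` (named per-motif vectors),
#'   group medians and `p`.
#' @export
group_effect_comparison <- function(effects, group_a, group_b) {
  per_motif <- tapply(effects$effect, effects$motif_id, stats::median)
  ma <- per_motif[intersect(names(per_motif), group_a)]
  mb <- per_motif[intersect(names(per_motif), group_b)]
  if (length(ma) < 2 || length(mb) < 2) stop("each group needs >= 2 motifs")
  p <- suppressWarnings(
    stats::wilcox.test(ma, mb, alternative = "two.sided")$p.value)
  list(medians_a = ma, medians_b = mb,
       median_a = stats::median(ma), median_b = stats::median(mb), p = p)
}

#' Resampling null for panel summary statistics
#'
#' Repeatedly draws random SNP panels of the observed size from
#' `snp_sampler`, recomputes the [summarize_risk_effects()] statistics, and
#' reports empirical tail p-values
#' `(1 + #\{trials >= observed\}) / (1 + n_trials)` (and the lower-tail
#' mirror) for the changed percentage and the disrupted/engendered ratio.
#'
#' @param snp_sampler `function(n, seed)` returning a list of
#'   [snp_record()]s.
#' @param pwms list of PWM models (the motif set under study).
#' @param observed list from [summarize_risk_effects()] on the real panel.
#' @param n_trials number of resampled panels (default 200; < 100 warns).
#' @param seed master seed; per-trial seeds are derived deterministically.
#' @return list with `p_upper`, `p_lower` (named per statistic) and the
#'   per-trial statistic data.frame `trials`.
#' @export
simulation_null <- function(snp_sampler, pwms, observed, n_trials = 200,
                            seed = 1) {
  if (n_trials < 100) warning("fewer than 100 trials; p-values are coarse")
  seeds <- derive_seeds(seed, n_trials)
  stats_names <- c("pct_changed", "pct_engendered", "pct_disrupted", "ratio")
  trials <- matrix(NA_real_, n_trials, length(stats_names),
                   dimnames = list(NULL, stats_names))
  for (t in seq_len(n_trials)) {
    snps <- snp_sampler(observed$n_snps, seeds[t])
    s <- summarize_risk_effects(score_snp_panel(pwms, snps))
    trials[t, ] <- c(s$pct_changed, s$pct_engendered, s$pct_disrupted,
                     s$ratio %||% NA_real_)
  }
  obs <- c(observed$pct_changed, observed$pct_engendered,
           observed$pct_disrupted,
           if (observed$ratio_undefined) NA_real_ else observed$ratio)
  names(obs) <- stats_names
  p_upper <- p_lower <- stats::setNames(rep(NA_real_, length(obs)),
                                        stats_names)
  for (s in stats_names) {
    tv <- trials[, s]
    ok <- !is.na(tv)
    if (!is.na(obs[s]) && any(ok)) {
      p_upper[s] <- (1 + sum(tv[ok] >= obs[s])) / (1 + sum(ok))
      p_lower[s] <- (1 + sum(tv[ok] <= obs[s])) / (1 + sum(ok))
    }
  }
  list(observed = obs, p_upper = p_upper, p_lower = p_lower,
       trials = as.data.frame(trials))
}

#' Filter engendered/disrupted combinations to candidate sites
#'
#' Keeps combinations whose binding change is not `none` and which are
#' conserved (`phastcons >= phastcons_min`) OR whose motif is recognized by a
#' DEG-encoded TF/uDBP; sorted by decreasing `|effect|`.
#'
#' @param effects data.frame from [score_snp_panel()] with an added
#'   `phastcons` column (per SNP).
#' @param deg_encoded_motifs motif ids recognized by DEG-encoded proteins.
#' @param phastcons_min conservation cutoff (default 0.50).
#' @return filtered, sorted data.frame.
#' @export
filter_candidate_sites <- function(effects, deg_encoded_motifs = character(0),
                                   phastcons_min = 0.50) {
  changed <- effects$change != "none"
  conserved <- !is.na(effects$phastcons) & effects$phastcons >= phastcons_min
  deg_motif <- effects$motif_id %in% deg_encoded_motifs
  out <- effects[changed & (conserved | deg_motif), , drop = FALSE]
  out[order(-abs(out$effect)), , drop = FALSE]
}
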