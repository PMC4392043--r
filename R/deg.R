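# Paired lesional (PP) / uninvolved (PN) differential expression:
# QC outlier filtering, label-swap detection, signed-rank DEG calling with
# BH FDR, fold-change gates, and per-dataset consistency.

#' Paired expression container
#'
#' @param pp,pn genes x patients matrices of log2 intensities with identical
#'   dimensions and shared gene row names.
#' @param patients `data.frame(patient_id, dataset_id)`, one row per column.
#' @param expressed logical per-gene flag (genes expressed above background);
#'   defaults to all `TRUE`.
#' @return an object of class `paired_expression_set`.
#' @export
paired_expression_set <- function(pp, pn, patients, expressed = NULL) {
  stopifnot(is.matrix(pp), is.matrix(pn), all(dim(pp) == dim(pn)),
            nrow(patients) == ncol(pp),
            all(c("patient_id", "dataset_id") %in% names(patients)))
  if (!is.null(rownames(pn)) && !identical(rownames(pp), rownames(pn))) {
    stop("pp and pn gene rows differ")
  }
  if (anyDuplicated(patients$patient_id)) stop("duplicate patient ids")
  if (is.null(expressed)) expressed <- rep(TRUE, nrow(pp))
  stopifnot(length(expressed) == nrow(pp))
  structure(list(genes = rownames(pp), pp = pp, pn = pn,
                 patients = patients, expressed = expressed),
            class = "paired_expression_set")
}

#' @export
print.paired_expression_set <- function(x, ...) {
  cat("paired_expression_set:", nrow(x$pp), "genes x", ncol(x$pp),
      "patients in", length(unique(x$patients$dataset_id)), "datasets\n")
  invisible(x)
}

#' Subset a paired expression set to a set of patients
#' @param expr a [paired_expression_set()].
#' @param patient_ids patients to keep.
#' @return a [paired_expression_set()].
#' @export
subset_patients <- function(expr, patient_ids) {
  keep <- expr$patients$patient_id %in% patient_ids
  paired_expression_set(expr$pp[, keep, drop = FALSE],
                        expr$pn[, keep, drop = FALSE],
                        expr$patients[keep, , drop = FALSE],
                        expressed = expr$expressed)
}

#' Remove QC-outlying samples (and their patients' pairs)
#'
#' QC metrics are converted to Z-scores within each dataset, per metric; a
#' sample with any `|Z| > z_cut` is removed, and removal of either member of
#' a PP/PN pair removes the whole patient. Datasets with fewer than 3 samples
#' are kept unfiltered with a warning. Missing metric values are skipped.
#'
#' @param metrics data.frame with columns `sample_id`, `patient_id`,
#'   `dataset_id` plus one numeric column per QC metric.
#' @param z_cut absolute Z-score cutoff (default 3.5).
#' @return list with `kept` (sample ids), `removed_samples`,
#'   `removed_patients` and a per-flag `log` data.frame.
#' @export
qc_outlier_filter <- function(metrics, z_cut = 3.5) {
  idcols <- c("sample_id", "patient_id", "dataset_id")
  stopifnot(all(idcols %in% names(metrics)))
  mcols <- setdiff(names(metrics), idcols)
  stopifnot(length(mcols) >= 1)
  flagged <- character(0)
  log <- data.frame(sample_id = character(0), metric = character(0),
                    z = numeric(0), stringsAsFactors = FALSE)
  for (ds in unique(metrics$dataset_id)) {
    rows <- metrics[metrics$dataset_id == ds, , drop = FALSE]
    if (nrow(rows) < 3) {
      warning("dataset ", ds, " has < 3 samples; QC Z-scores not computed")
      next
    }
    for (mc in mcols) {
      v <- rows[[mc]]
      ok <- !is.na(v)
      if (sum(ok) < 3 || stats::sd(v[ok]) == 0) next
      z <- (v - mean(v[ok])) / stats::sd(v[ok])
      bad <- ok & abs(z) > z_cut
      if (any(bad)) {
        flagged <- union(flagged, rows$sample_id[bad])
        log <- rbind(log, data.frame(sample_id = rows$sample_id[bad],
                                     metric = mc, z = z[bad],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  bad_patients <- unique(metrics$patient_id[metrics$sample_id %in% flagged])
  removed <- metrics$sample_id[metrics$patient_id %in% bad_patients]
  list(kept = setdiff(metrics$sample_id, removed),
       removed_samples = removed,
       removed_patients = bad_patients,
       log = log)
}

#' Detect patients with swapped PP/PN labels
#'
#' A patient is flagged when the median PP-PN difference over the up
#' signature is negative AND the median over the down signature is positive,
#' i.e. both signature directions are inverted.
#'
#' @param expr a [paired_expression_set()].
#' @param signature_up,signature_down non-empty gene sets with known
#'   direction (e.g. consensus disease-increased / -decreased genes).
#' @return character vector of flagged patient ids.
#' @export
detect_label_swaps <- function(expr, signature_up, signature_down) {
  if (length(signature_up) == 0 || length(signature_down) == 0) {
    stop("signatures must be non-empty")
  }
  up <- intersect(signature_up, expr$genes)
  dn <- intersect(signature_down, expr$genes)
  if (length(up) == 0 || length(dn) == 0) {
    stop("signatures do not overlap the expression gene set")
  }
  d <- expr$pp - expr$pn
  med_up <- apply(d[up, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  med_dn <- apply(d[dn, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  expr$patients$patient_id[med_up < 0 & med_dn > 0]
}

#' Call differentially expressed genes from paired PP/PN data
#'
#' Per expressed gene, the PP-PN differences are tested against zero with a
#' two-sided Wilcoxon signed-rank test; `median_fc = 2^median(PP-PN)`.
#' P-values are BH-adjusted over the tested genes. Classification requires
#' `fdr < fdr_cut` plus the fold-change gate (`> fc_up` or `< fc_down`) plus
#' per-dataset consistency (every dataset median FC on the same side of 1).
#' Genes with more than `1 - min_complete` missing pairs are skipped;
#' constant difference vectors get `p = 1` by convention.
#'
#' @param expr a [paired_expression_set()].
#' @param fdr_cut FDR threshold (default 0.05).
#' @param fc_up,fc_down fold-change gates on the ratio scale (defaults 1.50
#'   and 0.67).
#' @param min_complete minimum fraction of non-missing pairs (default 0.8).
#' @return data.frame (one row per gene) with `median_fc`, `p`, `fdr`,
#'   per-dataset medians (`fc_<dataset>` columns), `tested` and `class`
#'   (`pp_increased` / `pp_decreased` / `not_de`).
#' @export
call_degs <- function(expr, fdr_cut = 0.05, fc_up = 1.50, fc_down = 0.67,
                      min_complete = 0.8) {
  stopifnot(inherits(expr, "paired_expression_set"))
  if (ncol(expr$pp) < 2) stop("need at least 2 patients")
  d <- expr$pp - expr$pn
  datasets <- sort(unique(expr$patients$dataset_id))
  genes <- expr$genes %||% as.character(seq_len(nrow(d)))
  n <- nrow(d)
  p <- rep(NA_real_, n)
  med <- rep(NA_real_, n)
  tested <- rep(FALSE, n)
  dsmed <- matrix(NA_real_, n, length(datasets),
                  dimnames = list(NULL, datasets))
  for (g in seq_len(n)) {
    if (!expr$expressed[g]) next
    dg <- d[g, ]
    ok <- !is.na(dg)
    if (mean(ok) < min_complete) next
    dg <- dg[ok]
    tested[g] <- TRUE
    med[g] <- stats::median(dg)
    if (length(unique(dg)) == 1) {
      p[g] <- 1  # zero-variance convention
    } else {
      p[g] <- suppressWarnings(
        stats::wilcox.test(dg, mu = 0, alternative = "two.sided")$p.value)
    }
    for (ds in datasets) {
      sel <- ok & expr$patients$dataset_id == ds
      if (any(sel)) dsmed[g, ds] <- stats::median(d[g, sel])
    }
  }
  fdr <- rep(NA_real_, n)
  fdr[tested] <- bh_adjust(p[tested])
  median_fc <- 2^med
  ds_fc <- 2^dsmed
  all_up <- apply(ds_fc, 1, function(x) all(is.na(x) | x > 1) && any(!is.na(x)))
  all_dn <- apply(ds_fc, 1, function(x) all(is.na(x) | x < 1) && any(!is.na(x)))
  class <- rep("not_de", n)
  class[tested & !is.na(fdr) & fdr < fdr_cut & median_fc > fc_up & all_up] <-
    "pp_increased"
  class[tested & !is.na(fdr) & fdr < fdr_cut & median_fc < fc_down & all_dn] <-
    "pp_decreased"
  out <- data.frame(gene_id = genes, median_fc = median_fc, p = p, fdr = fdr,
                    tested = tested, class = class, stringsAsFactors = FALSE)
  colnames(ds_fc) <- paste0("fc_", datasets)
  cbind(out, as.data.frame(ds_fc))
}
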