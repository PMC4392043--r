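# Motif enrichment in DEG upstream regions: semiparametric logistic
# regression (linear match-count term + smooth length term), BH FDR,
# PRE selection and TF/uDBP cross-linking.

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, monotone in rank and `>=` the raw p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Test whether match counts are elevated among labelled genes
#'
#' Fits a binomial generalized additive model
#' `label ~ log10(counts + 1) + s(log10(lengths), k = spline_k)`:
#' the enrichment covariate is parametric (so it carries a Wald Z statistic)
#' while scanned-sequence length enters through a penalized spline whose
#' smoothness is chosen by GCV. Falls back to a plain logistic fit when the
#' length covariate is (nearly) constant.
#'
#' @param counts per-gene merged match counts (x1).
#' @param lengths per-gene non-masked scanned bp (x2, `> 0`).
#' @param labels 0/1 gene-set membership; both classes must be present.
#' @param spline_k spline basis dimension (default 5).
#' @return list with `z` (Wald statistic of the count term) and `p`
#'   (two-sided p-value).
#' @export
fit_enrichment_model <- function(counts, lengths, labels, spline_k = 5) {
  stopifnot(length(counts) == length(lengths),
            length(counts) == length(labels))
  if (length(counts) < 50) stop("need at least 50 genes")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (any(lengths <= 0)) stop("lengths must be positive")
  x1 <- log10(counts + 1)
  x2 <- log10(lengths)
  if (stats::sd(x1) == 0) {
    warning("match counts are constant; no enrichment information")
    return(list(z = 0, p = 1))
  }
  separated <- FALSE
  fit <- withCallingHandlers({
    if (length(unique(x2)) > spline_k) {
      mgcv::gam(labels ~ x1 + s(x2, k = spline_k),
                family = stats::binomial(), method = "GCV.Cp")
    } else {
      stats::glm(labels ~ x1, family = stats::binomial())
    }
  }, warning = function(w) {
    if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  })
  if (inherits(fit, "gam")) {
    tab <- summary(fit)$p.table
  } else {
    tab <- summary(fit)$coefficients
  }
  z <- unname(tab["x1", 3])
  p <- unname(tab["x1", 4])
  if (separated) {
    warning("possible complete separation; Wald statistic may be unstable")
  }
  list(z = z, p = p)
}

#' Per-motif enrichment over the three DEG gene sets
#'
#' Runs [fit_enrichment_model()] for every motif against the PP-increased,
#' PP-decreased and combined DEG sets (each versus all other genes), adjusts
#' p-values per gene set with [bh_adjust()], and flags enriched motifs
#' (`fdr < fdr_cut` with `z > 0`).
#'
#' @param mm a [build_match_matrix()] result.
#' @param deg_classes named character vector per gene
#'   (`pp_increased` / `pp_decreased` / `not_de`), names matching the rows
#'   of the match matrix.
#' @param fdr_cut enrichment FDR threshold (default 0.10).
#' @param spline_k passed to [fit_enrichment_model()].
#' @return data.frame with `motif_id`, `gene_set`, `z`, `p`, `fdr`, `is_pre`.
#' @export
motif_enrichment <- function(mm, deg_classes, fdr_cut = 0.10, spline_k = 5) {
  stopifnot(inherits(mm, "match_matrix"))
  genes <- rownames(mm$counts)
  stopifnot(all(genes %in% names(deg_classes)))
  cls <- deg_classes[genes]
  sets <- list(pp_increased = cls == "pp_increased",
               pp_decreased = cls == "pp_decreased",
               combined = cls %in% c("pp_increased", "pp_decreased"))
  out <- list()
  for (set_name in names(sets)) {
    labels <- as.integer(sets[[set_name]])
    res <- lapply(colnames(mm$counts), function(mid) {
      r <- tryCatch(
        suppressWarnings(fit_enrichment_model(mm$counts[, mid], mm$lengths,
                                              labels, spline_k)),
        error = function(e) list(z = NA_real_, p = NA_real_))
      data.frame(motif_id = mid, gene_set = set_name, z = r$z, p = r$p,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    ok <- !is.na(res$p)
    res$fdr <- NA_real_
    res$fdr[ok] <- bh_adjust(res$p[ok])
    res$is_pre <- !is.na(res$fdr) & res$fdr < fdr_cut & res$z > 0
    out[[set_name]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Select enriched-motif ("response element") sets per gene set
#'
#' @param results data.frame from [motif_enrichment()] (or with the same
#'   columns).
#' @param fdr_cut FDR threshold (default 0.10).
#' @return named list of motif-id vectors (`pp_increased`, `pp_decreased`,
#'   `combined`).
#' @export
select_pre_sets <- function(results, fdr_cut = 0.10) {
  lapply(split(results, results$gene_set), function(df) {
    sort(df$motif_id[!is.na(df$fdr) & df$fdr < fdr_cut & df$z > 0])
  })
}

#' Cross-link DEGs with the motifs they encode
#'
#' Every TF/uDBP-encoding gene in `tf_genes` is labelled by whether any motif
#' it recognizes is enriched for the PP-increased set, the PP-decreased set,
#' both, or none; genes with no motif in the dictionary are excluded from the
#' test denominator. A one-sided Fisher's exact test asks whether DEGs are
#' more likely than non-DEG TF genes to interact with enriched motifs.
#'
#' @param deg_table data.frame from [call_degs()].
#' @param dict a [motif_dictionary()] (gene symbols on the records).
#' @param pre_sets list from [select_pre_sets()].
#' @param tf_genes character vector: the TF/uDBP-encoding gene universe.
#' @return list with `classes` (`data.frame(gene_id, is_deg, pre_class)`),
#'   `table` (2x2) and `p`.
#' @export
crosslink_degs <- function(deg_table, dict, pre_sets, tf_genes) {
  gene_motifs <- list()
  for (rec in dict$records) {
    for (g in rec$genes) {
      gene_motifs[[g]] <- c(gene_motifs[[g]], rec$motif_id)
    }
  }
  if (length(gene_motifs) == 0) stop("dictionary carries no gene annotations")
  cls <- vapply(tf_genes, function(g) {
    motifs <- gene_motifs[[g]]
    if (is.null(motifs)) return("no_motif")
    up <- any(motifs %in% pre_sets$pp_increased)
    dn <- any(motifs %in% pre_sets$pp_decreased)
    if (up && dn) "both" else if (up) "pp_increased_only"
    else if (dn) "pp_decreased_only" else "none"
  }, character(1))
  is_deg <- tf_genes %in% deg_table$gene_id[deg_table$class != "not_de"]
  keep <- cls != "no_motif"
  interacts <- cls %in% c("both", "pp_increased_only", "pp_decreased_only")
  tab <- matrix(c(sum(keep & is_deg & interacts),
                  sum(keep & is_deg & !interacts),
                  sum(keep & !is_deg & interacts),
                  sum(keep & !is_deg & !interacts)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("deg", "non_deg"),
                                c("interacts", "no_interaction")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(classes = data.frame(gene_id = tf_genes, is_deg = is_deg,
                            pre_class = cls, stringsAsFactors = FALSE),
       table = tab, p = p)
}
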