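# Position frequency / probability matrices and per-motif curation steps:
# pseudocount conversion, information-content trimming, IUPAC consensus.

#' Position frequency matrix
#'
#' A PFM holds raw (non-negative, possibly fractional) base counts for a
#' binding-site model, rows `A`, `C`, `G`, `T`, one column per position.
#'
#' @param motif_id single string identifying the motif.
#' @param counts 4 x m numeric matrix of non-negative counts. Rows may be
#'   named `A,C,G,T`; unnamed rows are taken in that order.
#' @return an object of class `pfm`.
#' @export
new_pfm <- function(motif_id, counts) {
  counts <- as.matrix(counts)
  stopifnot(is.character(motif_id), length(motif_id) == 1,
            nrow(counts) == 4, ncol(counts) >= 1)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("PFM counts must be finite and non-negative")
  }
  rownames(counts) <- DNA_BASES
  structure(list(motif_id = motif_id, counts = counts), class = "pfm")
}

#' Position probability matrix
#'
#' Columns must sum to one. `pseudocount` records the total pseudocount that
#' was applied when the PPM was derived from counts (0 for matrices that
#' arrived as probabilities).
#'
#' @param motif_id single string.
#' @param probs 4 x m numeric matrix of probabilities (rows `A,C,G,T`).
#' @param pseudocount non-negative scalar, bookkeeping only.
#' @return an object of class `ppm`.
#' @export
new_ppm <- function(motif_id, probs, pseudocount = 0) {
  probs <- as.matrix(probs)
  stopifnot(is.character(motif_id), length(motif_id) == 1,
            nrow(probs) == 4, ncol(probs) >= 1)
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("PPM entries must be finite and non-negative")
  }
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("PPM columns must sum to 1 (tolerance 1e-9)")
  }
  rownames(probs) <- DNA_BASES
  structure(list(motif_id = motif_id, probs = probs,
                 pseudocount = pseudocount), class = "ppm")
}

#' @export
print.ppm <- function(x, ...) {
  cat("PPM", x$motif_id, "width", ncol(x$probs),
      "consensus", ppm_to_iupac(x), "\n")
  print(round(x$probs, 3))
  invisible(x)
}

ppm_probs <- function(ppm) ppm$probs

motif_width <- function(x) ncol(if (inherits(x, "ppm")) x$probs else x$counts)

#' Convert counts to probabilities with a pseudocount
#'
#' Each column entry becomes `(count + pseudocount/4) / (total + pseudocount)`,
#' i.e. the total pseudocount is split equally across the four bases.
#'
#' @param pfm a [new_pfm()] object.
#' @param pseudocount positive scalar total pseudocount per column (default 0.80).
#' @return a [new_ppm()] object.
#' @export
pfm_to_ppm <- function(pfm, pseudocount = 0.80) {
  stopifnot(inherits(pfm, "pfm"), is.numeric(pseudocount), pseudocount > 0)
  counts <- pfm$counts
  totals <- colSums(counts)
  probs <- sweep(counts + pseudocount / 4, 2, totals + pseudocount, "/")
  new_ppm(pfm$motif_id, probs, pseudocount = pseudocount)
}

#' Information content of a PPM column
#'
#' `IC = 2 + sum(p * log2(p))` in bits, with `0 * log2(0)` taken as 0.
#'
#' @param ppm_column numeric vector of 4 probabilities summing to 1.
#' @return scalar in `[0, 2]`.
#' @export
column_ic <- function(ppm_column) {
  stopifnot(is.numeric(ppm_column), length(ppm_column) == 4)
  if (abs(sum(ppm_column) - 1) > 1e-6) {
    stop("column does not sum to 1")
  }
  terms <- ifelse(ppm_column > 0, ppm_column * log2(ppm_column), 0)
  2 + sum(terms)
}

# per-column IC vector of a ppm
ppm_column_ics <- function(ppm) apply(ppm_probs(ppm), 2, column_ic)

#' Average information content of a motif (mean over columns, bits)
#' @param ppm a `ppm`.
#' @return scalar.
#' @export
avg_information_content <- function(ppm) mean(ppm_column_ics(ppm))

#' Trim low-information flanks from a PPM
#'
#' The strict rule removes columns from each flank until two consecutive
#' columns with IC above `ic_threshold` are met. If that removes everything or
#' leaves fewer than `min_width` columns, a relaxed rule (stop at a single
#' high-IC column) is applied to the original matrix. A matrix still narrower
#' than `min_width` is discarded.
#'
#' @param ppm a `ppm`.
#' @param ic_threshold per-column IC cutoff in bits (default 0.25).
#' @param min_width minimum retained width (default 4).
#' @return the trimmed `ppm` (with attribute `trim_rule` = "strict" or
#'   "relaxed"), or `NULL` with attribute-free return when discarded.
#' @export
trim_ppm <- function(ppm, ic_threshold = 0.25, min_width = 4) {
  stopifnot(inherits(ppm, "ppm"))
  ic <- ppm_column_ics(ppm)
  m <- length(ic)
  hi <- ic > ic_threshold

  strict_bounds <- function() {
    left <- NA_integer_
    for (i in seq_len(m - 1)) {
      if (hi[i] && hi[i + 1]) { left <- i; break }
    }
    if (is.na(left)) return(NULL)
    right <- NA_integer_
    for (j in seq(m, 2)) {
      if (hi[j] && hi[j - 1]) { right <- j; break }
    }
    c(left, right)
  }
  relaxed_bounds <- function() {
    idx <- which(hi)
    if (length(idx) == 0) return(NULL)
    c(min(idx), max(idx))
  }

  sb <- strict_bounds()
  rule <- "strict"
  if (is.null(sb) || (sb[2] - sb[1] + 1) < min_width) {
    sb <- relaxed_bounds()
    rule <- "relaxed"
  }
  if (is.null(sb) || (sb[2] - sb[1] + 1) < min_width) {
    return(NULL)
  }
  out <- new_ppm(ppm$motif_id, ppm_probs(ppm)[, sb[1]:sb[2], drop = FALSE],
                 pseudocount = ppm$pseudocount)
  attr(out, "trim_rule") <- rule
  out
}

#' IUPAC consensus of a PPM
#'
#' Per column, every base with probability at least 0.25 joins the degenerate
#' set, which maps to the standard IUPAC letter. Deterministic.
#'
#' @param ppm a `ppm`.
#' @return single consensus string.
#' @export
ppm_to_iupac <- function(ppm) {
  stopifnot(inherits(ppm, "ppm"))
  p <- ppm_probs(ppm)
  letters <- apply(p, 2, function(col) {
    keys <- paste(DNA_BASES[col >= 0.25], collapse = "")
    IUPAC_CODES[[keys]]
  })
  paste(letters, collapse = "")
}

#' Most-preferred (argmax) sequence of a PPM
#'
#' Ties within a column are broken toward the alphabetically first base.
#'
#' @param ppm a `ppm`.
#' @return single string of length `ncol(probs)`.
#' @export
ppm_consensus <- function(ppm) {
  p <- ppm_probs(ppm)
  paste(DNA_BASES[apply(p, 2, which.max)], collapse = "")
}

#' Reverse complement of a PPM
#' @param ppm a `ppm`.
#' @return a `ppm` for the opposite strand.
#' @export
ppm_revcomp <- function(ppm) {
  p <- ppm_probs(ppm)
  new_ppm(ppm$motif_id, p[4:1, rev(seq_len(ncol(p))), drop = FALSE],
          pseudocount = ppm$pseudocount)
}
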