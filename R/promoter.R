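# TSS-proximal region extraction, masking, PWM construction and scanning,
# and the gene x motif match matrix that feeds the enrichment model.

#' TSS-anchored promoter region
#'
#' Coordinates are 0-based half-open locally; `mask_intervals` is a 2-column
#' matrix of local (start, end) pairs. The sequence is oriented so that
#' upstream bases precede the TSS regardless of gene strand.
#'
#' @param gene_id,chrom,tss,strand annotation fields (`tss` 1-based genomic).
#' @param sequence region sequence over `ACGTN`.
#' @param mask_intervals local 0-based half-open intervals (matrix or NULL).
#' @param truncated character vector naming truncated sides (`"upstream"`,
#'   `"downstream"`), if any.
#' @return an object of class `promoter_region`.
#' @export
promoter_region <- function(gene_id, chrom, tss, strand, sequence,
                            mask_intervals = NULL, truncated = character(0)) {
  stopifnot(strand %in% c("+", "-"))
  len <- nchar(sequence)
  mi <- merge_intervals(mask_intervals)
  if (nrow(mi) > 0 && (min(mi[, 1]) < 0 || max(mi[, 2]) > len)) {
    stop("mask intervals outside region")
  }
  # assembly gaps (N) count as masked: they are never scanned
  bad <- is.na(match(strsplit(toupper(sequence), "")[[1]], DNA_BASES))
  if (nrow(mi) > 0) {
    for (r in seq_len(nrow(mi))) bad[(mi[r, 1] + 1):mi[r, 2]] <- TRUE
  }
  structure(list(gene_id = gene_id, chrom = chrom, tss = tss,
                 strand = strand, sequence = toupper(sequence),
                 mask_intervals = mi,
                 nonmasked_length = len - sum(bad),
                 truncated = truncated),
            class = "promoter_region")
}

#' @export
print.promoter_region <- function(x, ...) {
  cat("promoter_region", x$gene_id, sprintf("(%s:%d%s)", x$chrom, x$tss,
                                            x$strand),
      nchar(x$sequence), "bp,", x$nonmasked_length, "non-masked\n")
  invisible(x)
}

#' Extract a TSS-proximal region from a genome
#'
#' Plus strand: genomic positions `tss - upstream .. tss + downstream - 1`
#' (1-based). Minus strand: the mirrored window, reverse complemented so
#' upstream still comes first. Windows are truncated at contig ends and the
#' truncation recorded. Genomic mask intervals (BED convention, 0-based
#' half-open) are mapped into local coordinates.
#'
#' @param genome named character vector (or `DNAStringSet`) of contigs.
#' @param gene_id,chrom,tss,strand annotation (single gene).
#' @param masks optional `data.frame(chrom, start, end)` of genomic masks.
#' @param upstream,downstream window extents in bp (defaults 5000 and 500).
#' @return a [promoter_region()].
#' @export
extract_promoter <- function(genome, gene_id, chrom, tss, strand,
                             masks = NULL, upstream = 5000, downstream = 500) {
  if (!is.character(genome)) genome <- toupper(as.character(genome))
  if (!chrom %in% names(genome)) stop("contig absent from genome: ", chrom)
  contig <- genome[[chrom]]
  L <- nchar(contig)
  if (tss < 1 || tss > L) stop("TSS outside contig ", chrom)
  if (strand == "+") {
    gstart <- tss - upstream; gend <- tss + downstream - 1
  } else {
    gstart <- tss - downstream + 1; gend <- tss + upstream
  }
  truncated <- character(0)
  if (gstart < 1) {
    truncated <- c(truncated, if (strand == "+") "upstream" else "downstream")
    gstart <- 1
  }
  if (gend > L) {
    truncated <- c(truncated, if (strand == "+") "downstream" else "upstream")
    gend <- L
  }
  seq <- substr(contig, gstart, gend)
  len <- gend - gstart + 1
  local_masks <- NULL
  if (!is.null(masks) && nrow(masks) > 0) {
    mk <- masks[masks$chrom == chrom, , drop = FALSE]
    if (nrow(mk) > 0) {
      os <- pmax(mk$start, gstart - 1)
      oe <- pmin(mk$end, gend)
      sel <- os < oe
      if (any(sel)) {
        ls <- os[sel] - (gstart - 1)
        le <- oe[sel] - (gstart - 1)
        if (strand == "-") {
          tmp <- len - le
          le <- len - ls
          ls <- tmp
        }
        local_masks <- cbind(ls, le)
      }
    }
  }
  if (strand == "-") seq <- revcomp(seq)
  promoter_region(gene_id, chrom, tss, strand, seq,
                  mask_intervals = local_masks, truncated = truncated)
}

#' Extract promoters for a TSS annotation table
#' @param genome named character vector of contigs.
#' @param tss_table `data.frame(gene_id, chrom, tss, strand)`.
#' @param masks optional genomic mask data.frame.
#' @param upstream,downstream window extents.
#' @return named list of [promoter_region()]s.
#' @export
extract_promoters <- function(genome, tss_table, masks = NULL,
                              upstream = 5000, downstream = 500) {
  out <- lapply(seq_len(nrow(tss_table)), function(i) {
    extract_promoter(genome, tss_table$gene_id[i], tss_table$chrom[i],
                     tss_table$tss[i], tss_table$strand[i], masks,
                     upstream, downstream)
  })
  names(out) <- tss_table$gene_id
  out
}

region_bad_positions <- function(region) {
  # logical vector: TRUE where masked or N
  len <- nchar(region$sequence)
  bad <- is.na(seq_to_idx(region$sequence))
  mi <- region$mask_intervals
  if (nrow(mi) > 0) {
    for (r in seq_len(nrow(mi))) bad[(mi[r, 1] + 1):mi[r, 2]] <- TRUE
  }
  bad
}

#' Empirical base frequencies of a promoter set
#'
#' Counts A/C/G/T over all non-masked, non-N positions.
#'
#' @param regions list of [promoter_region()]s.
#' @return named numeric vector of 4 probabilities summing to 1.
#' @export
empirical_background <- function(regions) {
  stopifnot(length(regions) >= 1)
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (rg in regions) {
    idx <- seq_to_idx(rg$sequence)
    idx[region_bad_positions(rg)] <- NA
    tab <- tabulate(idx, nbins = 4)
    counts <- counts + tab
  }
  if (sum(counts) == 0) stop("no usable (non-masked, non-N) bases")
  counts / sum(counts)
}

#' Build a position weight matrix (log2 odds) from a PPM
#'
#' `weights = log2(p / f)`; `psi_max` is the sum of the column maxima.
#' A model whose `psi_max <= 0` (e.g. uniform PPM on uniform background) is
#' flagged degenerate.
#'
#' @param ppm a `ppm`.
#' @param background 4 base probabilities (default uniform), all `> 0`.
#' @return an object of class `pwm_model` with fields `motif_id`, `weights`,
#'   `psi_max`, `background`, `degenerate`.
#' @export
ppm_to_pwm <- function(ppm, background = rep(0.25, 4)) {
  stopifnot(inherits(ppm, "ppm"), length(background) == 4)
  if (any(background <= 0)) stop("background entries must be > 0")
  background <- background / sum(background)
  w <- log2(sweep(ppm_probs(ppm), 1, background, "/"))
  psi_max <- sum(apply(w, 2, max))
  structure(list(motif_id = ppm$motif_id, weights = w, psi_max = psi_max,
                 background = background, degenerate = psi_max <= 0),
            class = "pwm_model")
}

# forward-strand window scores of a weight matrix over an index-encoded
# sequence; idx entries may be NA (invalid windows handled by caller)
pwm_window_scores <- function(weights, idx) {
  m <- ncol(weights)
  L <- length(idx)
  if (L < m) return(numeric(0))
  nw <- L - m + 1
  idx0 <- idx
  idx0[is.na(idx0)] <- 1L  # placeholder; such windows are filtered out
  s <- numeric(nw)
  for (j in seq_len(m)) {
    s <- s + weights[cbind(idx0[j:(j + nw - 1)], j)]
  }
  s
}

# reverse-complement of a weight matrix (A<->T, C<->G, column order flipped)
pwm_rc_weights <- function(weights) {
  weights[4:1, rev(seq_len(ncol(weights))), drop = FALSE]
}

#' Scan a region with a PWM and merge overlapping matches
#'
#' Every window on either strand with `psi / psi_max >= threshold` is a hit;
#' windows containing any masked base or `N` are skipped entirely.
#' Overlapping hits (sharing at least one base, across strands) are merged
#' into maximal intervals; strictly adjacent hits are not merged.
#'
#' @param pwm a [ppm_to_pwm()] model (non-degenerate).
#' @param region a [promoter_region()] or plain sequence string.
#' @param threshold fraction of the maximum score (default 0.80).
#' @return data.frame of merged matches with 0-based half-open `start`/`end`,
#'   `best_ratio` and `strand` of the best window inside each interval.
#' @export
scan_pwm <- function(pwm, region, threshold = 0.80) {
  stopifnot(inherits(pwm, "pwm_model"))
  if (pwm$degenerate) stop("degenerate PWM model (psi_max <= 0)")
  if (is.character(region)) {
    region <- promoter_region("seq", "seq", 1, "+", region)
  }
  w <- pwm$weights
  m <- ncol(w)
  idx <- seq_to_idx(region$sequence)
  L <- length(idx)
  empty <- data.frame(start = integer(0), end = integer(0),
                      best_ratio = numeric(0), strand = character(0))
  if (L < m) return(empty)
  bad <- region_bad_positions(region)
  cs <- cumsum(c(0, bad))
  nw <- L - m + 1
  ok <- (cs[(1:nw) + m] - cs[1:nw]) == 0
  if (!any(ok)) return(empty)
  sf <- pwm_window_scores(w, idx) / pwm$psi_max
  sr <- pwm_window_scores(pwm_rc_weights(w), idx) / pwm$psi_max
  ratio <- pmax(sf, sr)
  hit <- ok & ratio >= threshold - 1e-9
  if (!any(hit)) return(empty)
  starts <- which(hit) - 1L  # 0-based
  ints <- merge_intervals(cbind(starts, starts + m))
  out <- lapply(seq_len(nrow(ints)), function(r) {
    within <- starts >= ints[r, 1] & starts < ints[r, 2]
    ws <- which(hit)[within]
    best <- ws[which.max(ratio[ws])]
    data.frame(start = ints[r, 1], end = ints[r, 2],
               best_ratio = ratio[best],
               strand = if (sf[best] >= sr[best]) "+" else "-",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count merged matches for every gene x motif pair
#'
#' @param dict a [motif_dictionary()].
#' @param regions list of [promoter_region()]s.
#' @param threshold match threshold on `psi / psi_max` (default 0.80).
#' @param background `"empirical"` (computed from `regions`; the promoter-scan
#'   default), `"uniform"`, or a numeric vector of 4 probabilities.
#' @return an object of class `match_matrix`: list with `counts`
#'   (genes x motifs integer matrix) and `lengths` (per-gene non-masked bp).
#' @export
build_match_matrix <- function(dict, regions, threshold = 0.80,
                               background = "empirical") {
  stopifnot(inherits(dict, "motif_dictionary"), length(dict$records) > 0)
  bg <- if (is.numeric(background)) background
        else if (identical(background, "uniform")) rep(0.25, 4)
        else empirical_background(regions)
  pwms <- lapply(dict_ppms(dict), ppm_to_pwm, background = bg)
  genes <- vapply(regions, `[[`, character(1), "gene_id")
  counts <- matrix(0L, length(regions), length(pwms),
                   dimnames = list(genes, names(pwms)))
  for (i in seq_along(regions)) {
    for (j in seq_along(pwms)) {
      if (pwms[[j]]$degenerate) next
      counts[i, j] <- nrow(scan_pwm(pwms[[j]], regions[[i]], threshold))
    }
  }
  lengths <- vapply(regions, `[[`, numeric(1), "nonmasked_length")
  names(lengths) <- genes
  structure(list(counts = counts, lengths = lengths, background = bg,
                 threshold = threshold), class = "match_matrix")
}

#' Fold elevation of motif density in one region
#'
#' `(matches per non-masked kb) / genomewide_mean_density`.
#'
#' @param region a [promoter_region()].
#' @param pwm a [ppm_to_pwm()] model.
#' @param genomewide_mean_density background density in matches/kb (`> 0`).
#' @param threshold match threshold (default 0.80).
#' @return scalar fold value.
#' @export
motif_density_fold <- function(region, pwm, genomewide_mean_density,
                               threshold = 0.80) {
  stopifnot(genomewide_mean_density > 0)
  if (region$nonmasked_length == 0) stop("region has no non-masked sequence")
  n <- nrow(scan_pwm(pwm, region, threshold))
  (n / (region$nonmasked_length / 1000)) / genomewide_mean_density
}
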