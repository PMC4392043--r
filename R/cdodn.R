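# Complex decoy oligonucleotide (cdODN) design: enumeration of block
# orderings/orientations, dictionary screening, ranking by average
# enrichment Z with a specificity tie-break, and dODN profiling.

# all permutations of 1..n in lexicographic order
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

#' Enumerate candidate cdODN designs
#'
#' Every ordering of the blocks combined with every per-block 5'-3'
#' orientation: exactly `n! * 2^n` candidates (duplicates arising from
#' palindromic blocks are deliberately not collapsed). Blocks are
#' concatenated directly; `spacer` (default none) is inserted between them.
#'
#' @param blocks named character vector of consensus block sequences
#'   (1 to 8 blocks, all non-empty).
#' @param spacer string placed between blocks (default `""`).
#' @return data.frame with `design_id`, `block_order` (comma-joined ids),
#'   `orientations` (`+`/`-` per block) and `sequence`.
#' @export
enumerate_designs <- function(blocks, spacer = "") {
  n <- length(blocks)
  stopifnot(n >= 1, n <= 8)
  if (any(nchar(blocks) == 0)) stop("empty block sequence")
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_len(n))
  blocks <- toupper(blocks)
  perms <- permutations_of(n)
  orient_grid <- as.matrix(do.call(expand.grid, rep(list(c(FALSE, TRUE)), n)))
  rows <- vector("list", length(perms) * nrow(orient_grid))
  k <- 1L
  for (p in perms) {
    for (o in seq_len(nrow(orient_grid))) {
      rc <- orient_grid[o, ]
      parts <- vapply(seq_len(n), function(i) {
        b <- blocks[[p[i]]]
        if (rc[i]) revcomp(b) else b
      }, character(1))
      rows[[k]] <- data.frame(
        block_order = paste(names(blocks)[p], collapse = ","),
        orientations = paste(ifelse(rc, "-", "+"), collapse = ","),
        sequence = paste(parts, collapse = spacer),
        stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(design_id = sprintf("cdODN%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out
}

# best psi/psi_max of each dictionary motif against a naked sequence
# (both strands, all fully-contained windows, uniform background by default)
best_match_scores <- function(sequence, dict, background = rep(0.25, 4)) {
  stopifnot(inherits(dict, "motif_dictionary"))
  idx <- seq_to_idx(toupper(sequence))
  scores <- vapply(dict_ppms(dict), function(ppm) {
    pwm <- ppm_to_pwm(ppm, background)
    if (pwm$degenerate) return(NA_real_)
    m <- ncol(pwm$weights)
    if (length(idx) < m) return(-Inf)
    valid <- !vapply(seq_len(length(idx) - m + 1), function(i) {
      anyNA(idx[i:(i + m - 1)])
    }, logical(1))
    if (!any(valid)) return(-Inf)
    sf <- pwm_window_scores(pwm$weights, idx)
    sr <- pwm_window_scores(pwm_rc_weights(pwm$weights), idx)
    max(pmax(sf, sr)[valid]) / pwm$psi_max
  }, numeric(1))
  scores
}

#' Screen an oligo against the motif dictionary
#'
#' A motif is matched when any window on either strand reaches
#' `psi / psi_max >= threshold` (uniform background); presence per motif,
#' not a match count. Degenerate models are skipped and reported in the
#' `skipped` attribute.
#'
#' @param sequence oligo sequence.
#' @param dict a [motif_dictionary()].
#' @param threshold match threshold (default 0.80).
#' @return character vector of matched motif ids (attribute `skipped` lists
#'   degenerate motifs).
#' @export
screen_oligo <- function(sequence, dict, threshold = 0.80) {
  scores <- best_match_scores(sequence, dict)
  matched <- names(scores)[!is.na(scores) & scores >= threshold - 1e-9]
  structure(sort(matched), skipped = names(scores)[is.na(scores)])
}

#' Rank cdODN candidates by average enrichment Z, then specificity
#'
#' `avg_z` is the mean enrichment Z over a candidate's matched motifs
#' (motifs absent from `enrichment_z` contribute 0 and are logged in the
#' `missing_z` attribute). Candidates are sorted by decreasing `avg_z`;
#' runs of candidates whose consecutive `avg_z` differ by less than
#' `tie_window` are treated as tied and re-ordered by fewer matches, then
#' lexicographic sequence. Candidates matching nothing are ranked last and
#' flagged.
#'
#' @param candidates data.frame from [enumerate_designs()].
#' @param dict a [motif_dictionary()].
#' @param enrichment_z named numeric vector of per-motif Z statistics
#'   (e.g. for the disease-increased gene set).
#' @param threshold screening threshold (default 0.80).
#' @param tie_window `avg_z` difference treated as a tie (default 0.02).
#' @return `candidates` with added `n_matches`, `avg_z`, `matched_motifs`
#'   (semicolon-joined), `no_match` flag and `rank`, sorted by rank.
#' @export
rank_designs <- function(candidates, dict, enrichment_z, threshold = 0.80,
                         tie_window = 0.02) {
  missing_z <- character(0)
  res <- lapply(candidates$sequence, function(s) {
    matched <- screen_oligo(s, dict, threshold)
    zs <- enrichment_z[matched]
    absent <- matched[is.na(zs) | !(matched %in% names(enrichment_z))]
    missing_z <<- union(missing_z, absent)
    zs[is.na(zs)] <- 0
    data.frame(n_matches = length(matched),
               avg_z = if (length(matched) > 0) mean(zs) else NA_real_,
               matched_motifs = paste(matched, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- cbind(candidates, do.call(rbind, res))
  out$no_match <- is.na(out$avg_z)
  key <- ifelse(out$no_match, -1e9, out$avg_z)  # finite sentinel: last place
  ord <- order(-key, out$n_matches, out$sequence)
  out <- out[ord, , drop = FALSE]
  # chain consecutive near-ties into groups, re-sort inside each group
  key <- ifelse(out$no_match, -1e9, out$avg_z)
  grp <- cumsum(c(1, diff(key) < -tie_window))
  pieces <- split(seq_len(nrow(out)), grp)
  idx <- unlist(lapply(pieces, function(ii) {
    ii[order(out$n_matches[ii], out$sequence[ii])]
  }), use.names = FALSE)
  out <- out[idx, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "missing_z") <- missing_z
  out
}

#' Profile a decoy oligo against the dictionary
#'
#' Ranks all motifs by their best normalized match score over every window
#' and strand, returning the top `k` with their associated genes (so
#' off-target best hits are visible).
#'
#' @param sequence decoy sequence.
#' @param dict a [motif_dictionary()].
#' @param k number of motifs to report (default 10; larger than the
#'   dictionary returns the full ranking).
#' @return data.frame with `motif_id`, `score`, `genes`.
#' @export
profile_dodn <- function(sequence, dict, k = 10) {
  scores <- best_match_scores(sequence, dict)
  scores <- scores[!is.na(scores)]
  ord <- order(-scores, names(scores))
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(
    motif_id = names(scores)[top],
    score = unname(scores[top]),
    genes = vapply(names(scores)[top], function(id)
      paste(dict$records[[id]]$genes, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
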