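# Motif dictionary: records, redundancy filtering, provenance, curation.

MOTIF_SOURCES <- c("hpdi", "jaspar", "uniprobe", "transfac",
                   "encode_chipseq", "selex", "synthetic")

#' Create a motif record
#'
#' Bundles a probability matrix with its source, the gene symbols of the
#' binding protein(s) and optional DNA-binding-domain annotation.
#'
#' @param ppm a [new_ppm()] object.
#' @param source one of `r paste(MOTIF_SOURCES, collapse=", ")`.
#' @param genes character vector of associated gene symbols.
#' @param dbd_superfamily,dbd_class optional DBD annotation strings (`NA` if
#'   unknown; assignments are consumed as annotation, never computed here).
#' @return an object of class `motif_record`.
#' @export
motif_record <- function(ppm, source = "synthetic", genes = character(0),
                         dbd_superfamily = NA_character_,
                         dbd_class = NA_character_) {
  stopifnot(inherits(ppm, "ppm"))
  source <- match.arg(source, MOTIF_SOURCES)
  structure(list(motif_id = ppm$motif_id, ppm = ppm, source = source,
                 genes = as.character(genes),
                 dbd_superfamily = dbd_superfamily, dbd_class = dbd_class,
                 avg_ic = avg_information_content(ppm)),
            class = "motif_record")
}

empty_provenance <- function() {
  data.frame(motif_id = character(0), step = character(0),
             kept_id = character(0), stringsAsFactors = FALSE)
}

#' Assemble a motif dictionary
#'
#' @param records list of [motif_record()] objects with unique ids.
#' @param provenance removal log `data.frame(motif_id, step, kept_id)`;
#'   `step` is one of `trim_discard`, `consensus_dedup`, `distance_collapse`.
#' @return an object of class `motif_dictionary`.
#' @export
motif_dictionary <- function(records, provenance = empty_provenance()) {
  ids <- vapply(records, function(r) r$motif_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate motif_ids in dictionary")
  names(records) <- ids
  structure(list(records = records, provenance = provenance),
            class = "motif_dictionary")
}

#' @export
print.motif_dictionary <- function(x, ...) {
  cat("motif_dictionary:", length(x$records), "motifs,",
      nrow(x$provenance), "removals logged\n")
  invisible(x)
}

#' @export
length.motif_dictionary <- function(x) length(x$records)

dict_ids <- function(dict) names(dict$records)

dict_ppms <- function(dict) lapply(dict$records, `[[`, "ppm")

#' Remove same-length, same-consensus duplicates
#'
#' Among records sharing width and IUPAC consensus, the lower-average-IC
#' member is removed unless the mean absolute difference of the two PPMs
#' exceeds `max_ppm_diff`. Equal-IC ties are broken by lexicographic
#' `motif_id` (the earlier id survives).
#'
#' @param records list of `motif_record`s (already trimmed).
#' @param max_ppm_diff mean-|delta| threshold above which both members are
#'   kept (default 0.05).
#' @return `list(kept = records, removed = provenance data.frame)`.
#' @export
dedup_consensus <- function(records, max_ppm_diff = 0.05) {
  keys <- vapply(records, function(r) {
    paste(motif_width(r$ppm), ppm_to_iupac(r$ppm))
  }, character(1))
  removed <- empty_provenance()
  kept <- list()
  for (key in unique(keys)) {
    group <- records[keys == key]
    ord <- order(-vapply(group, `[[`, numeric(1), "avg_ic"),
                 vapply(group, `[[`, character(1), "motif_id"))
    group <- group[ord]
    surv <- list()
    for (rec in group) {
      by <- NULL
      for (s in surv) {
        d <- mean(abs(ppm_probs(rec$ppm) - ppm_probs(s$ppm)))
        if (d <= max_ppm_diff) { by <- s$motif_id; break }
      }
      if (is.null(by)) {
        surv[[length(surv) + 1]] <- rec
      } else {
        removed <- rbind(removed, data.frame(
          motif_id = rec$motif_id, step = "consensus_dedup",
          kept_id = by, stringsAsFactors = FALSE))
      }
    }
    kept <- c(kept, surv)
  }
  ids <- vapply(kept, `[[`, character(1), "motif_id")
  kept <- kept[order(ids)]
  list(kept = kept, removed = removed)
}

#' Alignment distance between two motifs
#'
#' `1 - max(Pearson r)` over every ungapped column offset of `a` against `b`
#' and against the reverse complement of `b`, requiring at least
#' `min_overlap` overlapping columns; correlations are computed over the
#' flattened 4 x overlap probability blocks. Symmetric; identical motifs have
#' distance 0. If no offset yields a computable correlation the distance is 1.
#'
#' @param a,b `ppm` objects.
#' @param min_overlap minimum aligned columns (default 4).
#' @return scalar in `[0, 2]`.
#' @export
motif_distance <- function(a, b, min_overlap = 4) {
  stopifnot(inherits(a, "ppm"), inherits(b, "ppm"))
  pa <- ppm_probs(a)
  best <- -Inf
  for (pb in list(ppm_probs(b), ppm_probs(ppm_revcomp(b)))) {
    ma <- ncol(pa); mb <- ncol(pb)
    for (off in seq(-(mb - min_overlap), ma - min_overlap)) {
      ia <- max(1L, off + 1L)
      ib <- ia - off
      n <- min(ma - ia, mb - ib) + 1L
      if (n < min_overlap) next
      x <- as.vector(pa[, ia:(ia + n - 1), drop = FALSE])
      y <- as.vector(pb[, ib:(ib + n - 1), drop = FALSE])
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      r <- stats::cor(x, y)
      if (r > best) best <- r
    }
  }
  if (!is.finite(best)) return(1)
  1 - best
}

#' Collapse groups of near-identical motifs
#'
#' Single-linkage groups are formed over pairs with
#' `motif_distance < distance_threshold`; within each group only the motif
#' with the highest average IC is kept (ties broken by lexicographic id).
#'
#' @param records list of `motif_record`s.
#' @param distance_threshold grouping cutoff (default 1e-14, which in
#'   practice groups byte-identical or numerically identical matrices only).
#' @return `list(kept, removed)` as in [dedup_consensus()].
#' @export
collapse_similar <- function(records, distance_threshold = 1e-14) {
  n <- length(records)
  if (n <= 1) return(list(kept = records, removed = empty_provenance()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- motif_distance(records[[i]]$ppm, records[[j]]$ppm)
      if (d < distance_threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  removed <- empty_provenance()
  keep <- logical(n)
  for (r in unique(roots)) {
    members <- which(roots == r)
    ics <- vapply(records[members], `[[`, numeric(1), "avg_ic")
    ids <- vapply(records[members], `[[`, character(1), "motif_id")
    best <- members[order(-ics, ids)][1]
    keep[best] <- TRUE
    for (m in setdiff(members, best)) {
      removed <- rbind(removed, data.frame(
        motif_id = records[[m]]$motif_id, step = "distance_collapse",
        kept_id = records[[best]]$motif_id, stringsAsFactors = FALSE))
    }
  }
  kept <- records[keep]
  ids <- vapply(kept, `[[`, character(1), "motif_id")
  list(kept = kept[order(ids)], removed = removed)
}

#' Run the full curation pipeline over raw motif records
#'
#' Trims every matrix ([trim_ppm()]), discards too-narrow ones, removes
#' same-consensus duplicates ([dedup_consensus()]) and collapses
#' near-identical matrices ([collapse_similar()]), logging every removal.
#'
#' @param records list of `motif_record`s (PPMs already pseudocounted).
#' @param ic_threshold,min_width passed to [trim_ppm()].
#' @param max_ppm_diff passed to [dedup_consensus()].
#' @param distance_threshold passed to [collapse_similar()].
#' @return a [motif_dictionary()].
#' @export
curate_dictionary <- function(records, ic_threshold = 0.25, min_width = 4,
                              max_ppm_diff = 0.05,
                              distance_threshold = 1e-14) {
  prov <- empty_provenance()
  trimmed <- list()
  for (rec in records) {
    tp <- trim_ppm(rec$ppm, ic_threshold, min_width)
    if (is.null(tp)) {
      prov <- rbind(prov, data.frame(motif_id = rec$motif_id,
                                     step = "trim_discard",
                                     kept_id = NA_character_,
                                     stringsAsFactors = FALSE))
    } else {
      trimmed[[length(trimmed) + 1]] <- motif_record(
        tp, source = rec$source, genes = rec$genes,
        dbd_superfamily = rec$dbd_superfamily, dbd_class = rec$dbd_class)
    }
  }
  dd <- dedup_consensus(trimmed, max_ppm_diff)
  prov <- rbind(prov, dd$removed)
  cs <- collapse_similar(dd$kept, distance_threshold)
  prov <- rbind(prov, cs$removed)
  motif_dictionary(cs$kept, prov)
}
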