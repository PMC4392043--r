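# k-mer preference scores, similarity profiles, nearest-neighbor DBD
# enrichment, and motif clustering with a median-split-silhouette rule.

#' k-mer preference score of a motif
#'
#' For each orientation of the word (the word itself and its reverse
#' complement), the word is slid over the probability matrix; at each start
#' position the minimum of the k matched probabilities is taken, the maximum
#' of those minima is recorded, and the final score is the larger of the two
#' orientations. Motifs narrower than the word score 0.
#'
#' @param ppm a `ppm`.
#' @param word k-mer string over ACGT, 3 <= k <= 4 for profiles (any k >= 1
#'   is accepted here).
#' @return scalar in `[0, 1]`.
#' @export
kmer_score <- function(ppm, word) {
  stopifnot(inherits(ppm, "ppm"))
  word <- toupper(word)
  if (grepl("[^ACGT]", word)) stop("word must be over {A,C,G,T}")
  p <- ppm_probs(ppm)
  m <- ncol(p)
  one <- function(w) {
    idx <- seq_to_idx(w)
    k <- length(idx)
    if (m < k) return(0)
    starts <- seq_len(m - k + 1)
    max(vapply(starts, function(i) {
      min(p[cbind(idx, i:(i + k - 1))])
    }, numeric(1)))
  }
  max(one(word), one(revcomp(word)))
}

#' Full 3-mer + 4-mer score profile of a motif
#'
#' @param ppm a `ppm`.
#' @return named numeric vector of length 320 (64 3-mers then 256 4-mers,
#'   each block in lexicographic order); reverse-complement symmetric by
#'   construction.
#' @export
kmer_profile <- function(ppm) {
  words <- c(kmer_words(3), kmer_words(4))
  vapply(words, function(w) kmer_score(ppm, w), numeric(1))
}

#' k-mer profiles for a whole dictionary
#' @param dict a [motif_dictionary()] (or list of `motif_record`s).
#' @return motifs x 320 numeric matrix with motif ids as row names.
#' @export
profile_matrix <- function(dict) {
  ppms <- if (inherits(dict, "motif_dictionary")) dict_ppms(dict) else
    lapply(dict, `[[`, "ppm")
  t(vapply(ppms, kmer_profile, numeric(320)))
}

#' Nearest-neighbor DNA-binding-domain enrichment
#'
#' The `fraction` most similar motifs (Pearson correlation of k-mer profiles,
#' query excluded; correlation ties broken by motif id) form the neighbor
#' set. For every DBD superfamily/class label present in the annotation, a
#' one-sided Fisher's exact test asks whether motifs carrying the label are
#' overrepresented among neighbors; the enrichment score is `-log10(p)`.
#'
#' @param profiles motifs x 320 matrix from [profile_matrix()].
#' @param annotations `data.frame(motif_id, dbd_superfamily, dbd_class)`;
#'   `NA` annotation allowed.
#' @param motif_id query motif (must be a row of `profiles`).
#' @param fraction neighbor fraction of the dictionary (default 0.10);
#'   neighbor count is `ceiling(fraction * nrow(profiles))`.
#' @return data.frame with one row per (category_type, category).
#' @export
neighbor_dbd_enrichment <- function(profiles, annotations, motif_id,
                                    fraction = 0.10) {
  stopifnot(motif_id %in% rownames(profiles))
  n <- nrow(profiles)
  n_nb <- ceiling(fraction * n)
  others <- setdiff(rownames(profiles), motif_id)
  cors <- vapply(others, function(id) {
    stats::cor(profiles[motif_id, ], profiles[id, ])
  }, numeric(1))
  cors[is.na(cors)] <- -Inf
  ord <- others[order(-cors, others)]
  neighbors <- ord[seq_len(min(n_nb, length(ord)))]
  out <- list()
  for (type in c("dbd_superfamily", "dbd_class")) {
    ann <- annotations[[type]]
    names(ann) <- annotations$motif_id
    ann <- ann[others]
    for (cat in sort(unique(ann[!is.na(ann)]))) {
      in_cat <- !is.na(ann) & ann == cat
      is_nb <- others %in% neighbors
      tab <- matrix(c(sum(is_nb & in_cat), sum(is_nb & !in_cat),
                      sum(!is_nb & in_cat), sum(!is_nb & !in_cat)),
                    nrow = 2, byrow = TRUE)
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
      out[[length(out) + 1]] <- data.frame(
        motif_id = motif_id, category_type = type, category = cat,
        n_neighbors = length(neighbors),
        neighbors_in_category = sum(is_nb & in_cat),
        fisher_p = p, score = -log10(p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||%
    data.frame(motif_id = character(0), category_type = character(0),
               category = character(0), n_neighbors = integer(0),
               neighbors_in_category = integer(0), fisher_p = numeric(0),
               score = numeric(0))
}

# silhouette widths from a full distance matrix and integer labels
silhouette_widths <- function(dmat, labels) {
  n <- length(labels)
  vapply(seq_len(n), function(i) {
    same <- labels == labels[i]
    a <- if (sum(same) > 1) mean(dmat[i, same & seq_len(n) != i]) else 0
    bs <- vapply(setdiff(unique(labels), labels[i]),
                 function(g) mean(dmat[i, labels == g]), numeric(1))
    if (length(bs) == 0) return(0)
    b <- min(bs)
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# median split silhouette of a k-group partition: each cluster of size >= 3
# is split in two (average linkage) and the median silhouette of its members
# under that split measures how divisible it still is; MSS is the median over
# clusters. Clusters too small to split (< 3) contribute the worst value (1)
# so that fragmenting into tiny clusters is never rewarded.
median_split_silhouette <- function(dmat, labels) {
  vals <- vapply(unique(labels), function(g) {
    idx <- which(labels == g)
    if (length(idx) < 3) return(1)
    sub <- dmat[idx, idx, drop = FALSE]
    hc <- stats::hclust(stats::as.dist(sub), method = "average")
    sublab <- stats::cutree(hc, k = 2)
    stats::median(silhouette_widths(sub, sublab))
  }, numeric(1))
  stats::median(vals)
}

#' Cluster motifs by k-mer profile similarity
#'
#' Average-linkage hierarchical clustering on correlation distance
#' (`1 - Pearson r` between profiles). The number of top-level groups is
#' chosen by minimizing the median split silhouette over `k_range`
#' (a cluster that is hard to split further is considered homogeneous).
#' For each resulting branch, the discriminative k-mer is the word whose
#' scores are most significantly elevated inside the branch (one-sided
#' rank-sum test; ties broken lexicographically).
#'
#' @param profiles motifs x 320 matrix from [profile_matrix()] (>= 2 rows).
#' @param k_range candidate group counts (default `2:10`, truncated to the
#'   number of motifs).
#' @param seed integer; the procedure is deterministic but the seed is fixed
#'   around the rank-sum calls for reproducibility of any tie handling.
#' @return list with `assignments` (`data.frame(motif_id, group)`), `k`,
#'   `mss` (per-candidate criterion values) and `branch_kmers`
#'   (`data.frame(group, kmer, p)`).
#' @export
cluster_motifs <- function(profiles, k_range = 2:10, seed = 1) {
  n <- nrow(profiles)
  if (is.null(n) || n < 2) stop("need at least 2 profiles")
  cmat <- suppressWarnings(stats::cor(t(profiles)))
  cmat[is.na(cmat)] <- 1  # constant profiles: treat as identical
  dmat <- 1 - cmat
  diag(dmat) <- 0
  if (max(dmat) < 1e-12) {
    return(list(
      assignments = data.frame(motif_id = rownames(profiles), group = 1L,
                               stringsAsFactors = FALSE),
      k = 1L, mss = numeric(0),
      branch_kmers = data.frame(group = integer(0), kmer = character(0),
                                p = numeric(0))))
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  k_range <- k_range[k_range <= n]
  mss <- vapply(k_range, function(k) {
    median_split_silhouette(dmat, stats::cutree(hc, k = k))
  }, numeric(1))
  names(mss) <- k_range
  k <- k_range[which.min(mss)]
  labels <- stats::cutree(hc, k = k)
  words <- colnames(profiles) %||% c(kmer_words(3), kmer_words(4))
  branch <- with_seed(seed, {
    do.call(rbind, lapply(sort(unique(labels)), function(g) {
      inb <- labels == g
      if (all(inb) || !any(inb)) {
        return(data.frame(group = g, kmer = NA_character_, p = NA_real_))
      }
      ps <- vapply(seq_along(words), function(j) {
        suppressWarnings(stats::wilcox.test(
          profiles[inb, j], profiles[!inb, j],
          alternative = "greater", exact = FALSE)$p.value)
      }, numeric(1))
      ps[is.na(ps)] <- 1
      best <- order(ps, words)[1]
      data.frame(group = g, kmer = words[best], p = ps[best],
                 stringsAsFactors = FALSE)
    }))
  })
  list(assignments = data.frame(motif_id = rownames(profiles),
                                group = as.integer(labels),
                                stringsAsFactors = FALSE),
       k = as.integer(k), mss = mss, branch_kmers = branch)
}
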