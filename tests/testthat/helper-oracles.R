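# Independent brute-force oracles. These re-derive scores with naive
# character-level loops (no shared code with the package scan engine).

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_complement <- function(ch) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[ch]]
}

oracle_revcomp <- function(s) {
  chars <- strsplit(s, "")[[1]]
  paste(rev(vapply(chars, oracle_complement, character(1))), collapse = "")
}

# psi of one window string against a weight matrix; NA if any non-ACGT base
oracle_window_psi <- function(weights, window) {
  chars <- strsplit(window, "")[[1]]
  if (any(!chars %in% ORACLE_BASES)) return(NA_real_)
  s <- 0
  for (j in seq_along(chars)) s <- s + weights[chars[j], j]
  s
}

# every (start, strand) window psi over a sequence; forward windows are the
# substrings, reverse windows are scored on the reverse-complemented
# substring with the same weights
oracle_all_window_scores <- function(weights, seq) {
  m <- ncol(weights)
  L <- nchar(seq)
  if (L < m) {
    return(data.frame(start = integer(0), strand = character(0),
                      psi = numeric(0)))
  }
  rows <- list()
  for (i in seq_len(L - m + 1)) {
    win <- substr(seq, i, i + m - 1)
    rows[[length(rows) + 1]] <- data.frame(
      start = i, strand = "+", psi = oracle_window_psi(weights, win))
    rows[[length(rows) + 1]] <- data.frame(
      start = i, strand = "-",
      psi = oracle_window_psi(weights, oracle_revcomp(win)))
  }
  do.call(rbind, rows)
}

# merged match intervals (0-based half-open) by exhaustive evaluation;
# masked positions given as a logical vector
oracle_scan <- function(pwm, seq, threshold = 0.80, masked = NULL) {
  m <- ncol(pwm$weights)
  sc <- oracle_all_window_scores(pwm$weights, seq)
  if (!is.null(masked)) {
    covers_mask <- vapply(sc$start, function(i) any(masked[i:(i + m - 1)]),
                          logical(1))
    sc <- sc[!covers_mask, , drop = FALSE]
  }
  sc <- sc[!is.na(sc$psi) & sc$psi / pwm$psi_max >= threshold - 1e-9, ,
           drop = FALSE]
  if (nrow(sc) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  starts <- sort(unique(sc$start)) - 1L
  merged <- list(c(starts[1], starts[1] + m))
  for (s in starts[-1]) {
    last <- merged[[length(merged)]]
    if (s < last[2]) {
      merged[[length(merged)]][2] <- max(last[2], s + m)
    } else {
      merged[[length(merged) + 1]] <- c(s, s + m)
    }
  }
  do.call(rbind, merged)
}

# Eq.-style k-mer score by exhaustive (orientation, start) enumeration
oracle_kmer_score <- function(ppm, word) {
  p <- ppm$probs
  m <- ncol(p)
  best <- 0
  for (w in c(word, oracle_revcomp(word))) {
    chars <- strsplit(w, "")[[1]]
    k <- length(chars)
    if (m < k) next
    for (i in seq_len(m - k + 1)) {
      lo <- Inf
      for (j in seq_len(k)) {
        lo <- min(lo, p[chars[j], i + j - 1])
      }
      best <- max(best, lo)
    }
  }
  best
}

# risk-allele effect by exhaustive evaluation of every window overlapping
# the SNP base, on both strands, per allele
oracle_snp_effect <- function(pwm, snp) {
  m <- ncol(pwm$weights)
  allele_psi <- function(a) {
    s <- snp$flank
    substr(s, snp$center, snp$center) <- a
    best <- -Inf
    for (i in seq_len(nchar(s) - m + 1)) {
      if (i > snp$center || i + m - 1 < snp$center) next  # must cover SNP
      win <- substr(s, i, i + m - 1)
      for (w in c(win, oracle_revcomp(win))) {
        psi <- oracle_window_psi(pwm$weights, w)
        if (!is.na(psi)) best <- max(best, psi)
      }
    }
    best
  }
  psi_r <- allele_psi(snp$risk_allele)
  psi_nr <- allele_psi(snp$nonrisk_allele)
  list(psi_r = psi_r, psi_nr = psi_nr,
       effect = (psi_r - psi_nr) / pwm$psi_max)
}

# one-sided hypergeometric upper tail (Fisher oracle):
# P(X >= k) with k successes among n draws, K successes in population N
oracle_fisher_greater <- function(k, n, K, N) {
  sum(stats::dhyper(k:min(n, K), K, N - K, n))
}
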