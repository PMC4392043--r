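# Shared low-level helpers (sequences, seeds, small numerics).

DNA_BASES <- c("A", "C", "G", "T")

# degenerate-base letter for every non-empty subset of {A,C,G,T};
# names are the sorted concatenated subsets
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' Reverse complement of DNA strings
#'
#' Plain-character reverse complement over the alphabet `ACGTN` (case kept
#' upper). Vectorised over `x`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("GAAAC")
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# A,C,G,T -> 1..4; anything else (N, masked placeholder) -> NA
seq_to_idx <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

idx_to_seq <- function(idx) paste(DNA_BASES[idx], collapse = "")

# all k-mer words over ACGT in lexicographic order
kmer_words <- function(k) {
  stopifnot(k >= 1)
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; flip for lexicographic order
  sort(apply(grid, 1L, paste, collapse = ""))
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) withr::with_seed(seed, code)

# deterministic sub-seeds (kept below 2^31) derived from a master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# merge 0-based half-open intervals given as a 2-column matrix (start, end);
# overlapping intervals are unioned, strictly adjacent ones are kept apart
merge_intervals <- function(ints, merge_adjacent = FALSE) {
  if (is.null(ints) || nrow(ints) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  ints <- ints[order(ints[, 1], ints[, 2]), , drop = FALSE]
  out <- ints[1, , drop = FALSE]
  for (i in seq_len(nrow(ints))[-1]) {
    last <- nrow(out)
    touch <- if (merge_adjacent) ints[i, 1] <= out[last, 2] else ints[i, 1] < out[last, 2]
    if (touch) {
      out[last, 2] <- max(out[last, 2], ints[i, 2])
    } else {
      out <- rbind(out, ints[i, , drop = FALSE])
    }
  }
  colnames(out) <- c("start", "end")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
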