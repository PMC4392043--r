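# Shared fixtures: hand-built matrices and random generators used across
# test files. Kept independent of package internals where they serve as
# oracle inputs.

# a column preferring `base` with probability q, rest split evenly
col_q <- function(base, q) {
  col <- rep((1 - q) / 3, 4)
  col[match(base, c("A", "C", "G", "T"))] <- q
  col
}

# PPM from a consensus string with per-column consensus probability q
ppm_from_consensus <- function(id, consensus, q = 0.94) {
  chars <- strsplit(consensus, "")[[1]]
  new_ppm(id, vapply(chars, col_q, numeric(4), q = q))
}

# random PPM via normalized uniform draws
random_ppm <- function(id, width) {
  m <- matrix(runif(4 * width, 0.01, 1), nrow = 4)
  new_ppm(id, sweep(m, 2, colSums(m), "/"))
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

record_from_ppm <- function(ppm, genes = character(0), sf = NA_character_,
                            cl = NA_character_) {
  motif_record(ppm, source = "synthetic", genes = genes,
               dbd_superfamily = sf, dbd_class = cl)
}
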