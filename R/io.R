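# File formats: motif matrices (JASPAR counts / MEME probabilities /
# TRANSFAC-like tables), dictionary directories, FASTA, BED, TSV tables.

parse_error <- function(line, msg) {
  stop(sprintf("motif parse error at line %d: %s", line, msg), call. = FALSE)
}

numeric_fields <- function(txt, line) {
  fields <- strsplit(trimws(txt), "[ \t]+")[[1]]
  vals <- suppressWarnings(as.numeric(fields))
  if (any(is.na(vals))) parse_error(line, paste("non-numeric cell in:", txt))
  vals
}

#' Parse motif matrices from a file
#'
#' Supported dialects:
#' * `jaspar_counts`: `>id name` header followed by four rows
#'   (`A [ 4 19 0 ]` style or bare numbers) -> PFMs.
#' * `meme_probs`: MEME minimal format (`MOTIF`, `letter-probability matrix:`
#'   headers, one row per position) -> PPMs with `pseudocount = 0`.
#' * `transfac_like`: `ID`-headed blocks with numbered count rows terminated
#'   by `//` -> PFMs.
#'
#' @param path file to read.
#' @param dialect one of `jaspar_counts`, `meme_probs`, `transfac_like`.
#' @return list of `pfm` (count dialects) or `ppm` (probability dialects).
#' @export
parse_motifs <- function(path, dialect = c("jaspar_counts", "meme_probs",
                                           "transfac_like")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  switch(dialect,
         jaspar_counts = parse_jaspar(lines),
         meme_probs = parse_meme(lines),
         transfac_like = parse_transfac(lines))
}

parse_jaspar <- function(lines) {
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!startsWith(ln, ">")) parse_error(i, "expected '>' header")
    id <- strsplit(sub("^>", "", ln), "[ \t]+")[[1]][1]
    rows <- list()
    for (r in 1:4) {
      j <- i + r
      if (j > length(lines)) parse_error(j, "truncated matrix block")
      body <- gsub("^[ \t]*[ACGTacgt][ \t:]*", "", lines[j])
      body <- gsub("[][]", " ", body)
      rows[[r]] <- numeric_fields(body, j)
      if (r > 1 && length(rows[[r]]) != length(rows[[1]])) {
        parse_error(j, sprintf("row has %d values, expected %d",
                               length(rows[[r]]), length(rows[[1]])))
      }
    }
    out[[length(out) + 1]] <- new_pfm(id, do.call(rbind, rows))
    i <- i + 5L
  }
  out
}

parse_meme <- function(lines) {
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^MOTIF\\b", ln)) {
      id <- strsplit(ln, "[ \t]+")[[1]][2]
      if (is.na(id)) parse_error(i, "MOTIF line without identifier")
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", trimws(lines[j]))) {
        j <- j + 1L
      }
      if (j > length(lines)) parse_error(i, "missing letter-probability matrix")
      w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[j]))
      if (is.na(w)) parse_error(j, "cannot read motif width (w=)")
      rows <- list()
      for (r in seq_len(w)) {
        vals <- numeric_fields(lines[j + r], j + r)
        if (length(vals) != 4) {
          parse_error(j + r, sprintf("row has %d values, expected 4",
                                     length(vals)))
        }
        rows[[r]] <- vals
      }
      probs <- t(do.call(rbind, rows))
      probs <- sweep(probs, 2, colSums(probs), "/")  # absorb print rounding
      out[[length(out) + 1]] <- new_ppm(id, probs, pseudocount = 0)
      i <- j + w + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

parse_transfac <- function(lines) {
  out <- list()
  id <- NULL
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^ID\\b", ln)) {
      id <- strsplit(ln, "[ \t]+")[[1]][2]
      rows <- list()
    } else if (grepl("^[0-9]+[ \t]", ln)) {
      if (is.null(id)) parse_error(i, "matrix row before ID line")
      body <- sub("^[0-9]+[ \t]+", "", ln)
      body <- sub("[ \t]+[ACGTNRYSWKMBDHVacgtnryswkmbdhv]$", "", body)
      vals <- numeric_fields(body, i)
      if (length(vals) != 4) {
        parse_error(i, sprintf("row has %d values, expected 4", length(vals)))
      }
      rows[[length(rows) + 1]] <- vals
    } else if (ln == "//") {
      if (!is.null(id) && length(rows) > 0) {
        out[[length(out) + 1]] <- new_pfm(id, t(do.call(rbind, rows)))
      }
      id <- NULL
    }
  }
  out
}

#' Write motif matrices
#'
#' @param motifs list of `pfm` (for `jaspar_counts`) or `ppm`
#'   (for `meme_probs`).
#' @param path output file.
#' @param dialect `jaspar_counts` or `meme_probs`.
#' @param digits decimals for probabilities (default 6; round-trips losslessly
#'   at that precision).
#' @export
write_motifs <- function(motifs, path,
                         dialect = c("jaspar_counts", "meme_probs"),
                         digits = 6) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "jaspar_counts") {
    for (m in motifs) {
      stopifnot(inherits(m, "pfm"))
      writeLines(paste0(">", m$motif_id), con)
      for (r in 1:4) {
        writeLines(sprintf("%s [ %s ]", DNA_BASES[r],
                           paste(format(m$counts[r, ], trim = TRUE),
                                 collapse = " ")), con)
      }
    }
  } else {
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
    for (m in motifs) {
      stopifnot(inherits(m, "ppm"))
      w <- ncol(m$probs)
      writeLines(sprintf("MOTIF %s", m$motif_id), con)
      writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", w), con)
      for (j in seq_len(w)) {
        writeLines(paste(sprintf(paste0("%.", digits, "f"), m$probs[, j]),
                         collapse = " "), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Serialize a motif dictionary to a directory
#'
#' Writes `motifs.meme` (probability matrices), `index.tsv` (id, source,
#' genes, DBD annotation, average IC, width) and `provenance.jsonl`
#' (one JSON removal record per line).
#'
#' @param dict a [motif_dictionary()].
#' @param dir output directory (created if missing).
#' @export
write_dictionary <- function(dict, dir) {
  stopifnot(inherits(dict, "motif_dictionary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_motifs(dict_ppms(dict), file.path(dir, "motifs.meme"), "meme_probs")
  idx <- data.frame(
    motif_id = dict_ids(dict),
    source = vapply(dict$records, `[[`, character(1), "source"),
    genes = vapply(dict$records, function(r) paste(r$genes, collapse = ","),
                   character(1)),
    dbd_superfamily = vapply(dict$records, `[[`, character(1),
                             "dbd_superfamily"),
    dbd_class = vapply(dict$records, `[[`, character(1), "dbd_class"),
    avg_ic = vapply(dict$records, `[[`, numeric(1), "avg_ic"),
    width = vapply(dict$records, function(r) motif_width(r$ppm), integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "provenance.jsonl"), "w")
  on.exit(close(con))
  if (nrow(dict$provenance) > 0) {
    for (i in seq_len(nrow(dict$provenance))) {
      writeLines(jsonlite::toJSON(as.list(dict$provenance[i, ]),
                                  auto_unbox = TRUE, na = "null"), con)
    }
  }
  invisible(dir)
}

#' Read a dictionary directory written by [write_dictionary()]
#' @param dir directory path.
#' @return a [motif_dictionary()].
#' @export
read_dictionary <- function(dir) {
  ppms <- parse_motifs(file.path(dir, "motifs.meme"), "meme_probs")
  idx <- utils::read.delim(file.path(dir, "index.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(motif_id = "character"))
  recs <- lapply(ppms, function(p) {
    row <- idx[idx$motif_id == p$motif_id, , drop = FALSE]
    if (nrow(row) != 1) stop("index.tsv entry missing for ", p$motif_id)
    genes <- if (is.na(row$genes) || row$genes == "") character(0) else
      strsplit(row$genes, ",", fixed = TRUE)[[1]]
    motif_record(p, source = row$source, genes = genes,
                 dbd_superfamily = as.character(row$dbd_superfamily),
                 dbd_class = as.character(row$dbd_class))
  })
  prov <- empty_provenance()
  pfile <- file.path(dir, "provenance.jsonl")
  if (file.exists(pfile)) {
    lines <- readLines(pfile)
    lines <- lines[nzchar(lines)]
    if (length(lines) > 0) {
      rows <- lapply(lines, function(l) {
        x <- jsonlite::fromJSON(l)
        data.frame(motif_id = x$motif_id, step = x$step,
                   kept_id = x$kept_id %||% NA_character_,
                   stringsAsFactors = FALSE)
      })
      prov <- do.call(rbind, rows)
    }
  }
  motif_dictionary(recs, prov)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("[ \t].*$", "", names(ss))
  seqs
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_genome_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read mask intervals from a BED file
#'
#' @param path BED3+ file.
#' @return `data.frame(chrom, start, end)` with 0-based half-open intervals.
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write mask intervals (`data.frame(chrom, start, end)`, 0-based) as BED
#' @param masks mask data.frame.
#' @param path output file.
#' @export
write_mask_bed <- function(masks, path) {
  gr <- GenomicRanges::GRanges(
    masks$chrom,
    IRanges::IRanges(start = masks$start + 1L, end = masks$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export motif matches as BED6 (score column carries psi/psi_max)
#'
#' @param matches data.frame from [scan_pwm()] plus columns `chrom` and
#'   `motif_id`.
#' @param path output file.
#' @export
write_matches_bed <- function(matches, path) {
  df <- data.frame(chrom = matches$chrom, start = matches$start,
                   end = matches$end, name = matches$motif_id,
                   score = round(matches$best_ratio, 4),
                   strand = matches$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table (`gene_id`, `chrom`, `tss`, `strand`)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_tss_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read paired expression matrices plus metadata sidecar
#'
#' `expr_path` holds a genes x samples TSV (first column gene ids);
#' `meta_path` holds sample metadata with columns `sample_id`, `patient_id`,
#' `dataset_id`, `tissue` (PP or PN).
#'
#' @param expr_path,meta_path TSV files.
#' @return a [paired_expression_set()].
#' @export
read_expression_tsv <- function(expr_path, meta_path) {
  mat <- as.matrix(utils::read.delim(expr_path, row.names = 1,
                                     check.names = FALSE))
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "patient_id", "dataset_id", "tissue")
                %in% names(meta)))
  pp_meta <- meta[meta$tissue == "PP", ]
  pn_meta <- meta[meta$tissue == "PN", ]
  pn_meta <- pn_meta[match(pp_meta$patient_id, pn_meta$patient_id), ]
  paired_expression_set(
    pp = mat[, pp_meta$sample_id, drop = FALSE],
    pn = mat[, pn_meta$sample_id, drop = FALSE],
    patients = data.frame(patient_id = pp_meta$patient_id,
                          dataset_id = pp_meta$dataset_id,
                          stringsAsFactors = FALSE))
}

#' Write a paired expression set as TSVs (expression matrix + metadata)
#' @param expr a [paired_expression_set()].
#' @param expr_path,meta_path output TSV files.
#' @export
write_expression_tsv <- function(expr, expr_path, meta_path) {
  pp <- expr$pp; pn <- expr$pn
  colnames(pp) <- paste0(expr$patients$patient_id, "_PP")
  colnames(pn) <- paste0(expr$patients$patient_id, "_PN")
  mat <- cbind(pp, pn)
  utils::write.table(data.frame(gene_id = rownames(mat), mat,
                                check.names = FALSE),
                     expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- rbind(
    data.frame(sample_id = colnames(pp), patient_id = expr$patients$patient_id,
               dataset_id = expr$patients$dataset_id, tissue = "PP"),
    data.frame(sample_id = colnames(pn), patient_id = expr$patients$patient_id,
               dataset_id = expr$patients$dataset_id, tissue = "PN"))
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}

#' Read a SNP panel from a TSV
#'
#' Expected columns: `snp_id`, `chrom`, `pos`, `risk_allele`,
#' `nonrisk_allele`, `flank`, `center`, `noncoding`, `enhancer`, `phastcons`.
#'
#' @param path TSV file.
#' @return data.frame of SNP records.
#' @export
read_snp_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
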