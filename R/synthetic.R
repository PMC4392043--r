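# Synthetic-data generators: every input the pipeline consumes, with ground
# truth, so all stages are testable offline. All generators are pure
# functions of (parameters, seed).

ic_of_q <- function(q) 2 + q * log2(q) + (1 - q) * log2((1 - q) / 3)

# consensus-base probability achieving a target per-column IC (bits), with
# the remaining mass split over the other three bases
q_for_ic <- function(target_ic) {
  stopifnot(target_ic > 0, target_ic < 2)
  stats::uniroot(function(q) ic_of_q(q) - target_ic,
                 interval = c(0.2500001, 0.9999999), tol = 1e-10)$root
}

# one PPM column preferring `base`, IC ~ target (small jitter on the three
# minor bases, rejected if it drifts out of the +/- 0.2 bit band)
synth_column <- function(base, target_ic, band = 0.2) {
  q <- q_for_ic(target_ic)
  minor <- rep((1 - q) / 3, 3)
  jit <- minor * stats::runif(3, -0.25, 0.25)
  jit <- jit - mean(jit)
  col <- rep(NA_real_, 4)
  bi <- match(base, DNA_BASES)
  col[bi] <- q
  col[-bi] <- minor + jit
  if (any(col <= 0) || abs(column_ic(col / sum(col)) - target_ic) > band) {
    col[-bi] <- minor
  }
  col / sum(col)
}

#' Generate a synthetic motif set with planted families
#'
#' Families share a core consensus word (e.g. `GAAA`), so that clustering
#' and redundancy machinery can be exercised against known labels. Column
#' probabilities are synthesized to hit a per-column information-content
#' band (+/- 0.2 bits). Optionally appends exact duplicates (for collapse
#' tests).
#'
#' @param n number of motifs (`>= n_families`).
#' @param width_range motif widths sampled uniformly from this range
#'   (default 6-14).
#' @param ic_per_column_range per-column IC band in bits (default 1.0-1.8).
#' @param n_families number of planted families (default 2).
#' @param family_cores optional character vector of core words; defaults to
#'   `GAAA`, `TGACT` then random 4-mers.
#' @param n_duplicates number of exact duplicate records appended.
#' @param seed RNG seed.
#' @return list with `records` (list of [motif_record()]s) and `truth`
#'   (`data.frame(motif_id, family, core, consensus, width)`).
#' @export
generate_motifs <- function(n, width_range = c(6, 14),
                            ic_per_column_range = c(1.0, 1.8),
                            n_families = 2, family_cores = NULL,
                            n_duplicates = 0, seed = 1) {
  stopifnot(n >= n_families, n_families >= 1)
  if (ic_per_column_range[1] <= 0 || ic_per_column_range[2] >= 2 ||
      diff(ic_per_column_range) < 0) {
    stop("infeasible per-column IC band")
  }
  with_seed(seed, {
    cores <- family_cores %||% c("GAAA", "TGACT")
    while (length(cores) < n_families) {
      cores <- c(cores, paste(sample(DNA_BASES, 4, replace = TRUE),
                              collapse = ""))
    }
    cores <- toupper(cores[seq_len(n_families)])
    fam <- rep(seq_len(n_families), length.out = n)
    records <- list()
    truth <- list()
    for (i in seq_len(n)) {
      core <- cores[fam[i]]
      k <- nchar(core)
      w <- sample(seq(max(width_range[1], k), width_range[2]), 1)
      off <- sample(seq_len(w - k + 1), 1)
      letters <- sample(DNA_BASES, w, replace = TRUE)
      letters[off:(off + k - 1)] <- strsplit(core, "")[[1]]
      ics <- stats::runif(w, ic_per_column_range[1], ic_per_column_range[2])
      probs <- vapply(seq_len(w), function(j) synth_column(letters[j], ics[j]),
                      numeric(4))
      id <- sprintf("synM%03d", i)
      ppm <- new_ppm(id, probs)
      records[[i]] <- motif_record(
        ppm, source = "synthetic", genes = sprintf("TF%03d", i),
        dbd_superfamily = paste0("family", fam[i]),
        dbd_class = paste0("class", fam[i]))
      truth[[i]] <- data.frame(motif_id = id, family = fam[i], core = core,
                               consensus = ppm_consensus(ppm), width = w,
                               stringsAsFactors = FALSE)
    }
    if (n_duplicates > 0) {
      for (d in seq_len(min(n_duplicates, n))) {
        src <- records[[d]]
        id <- paste0(src$motif_id, "dup")
        records[[length(records) + 1]] <- motif_record(
          new_ppm(id, ppm_probs(src$ppm)), source = "synthetic",
          genes = src$genes, dbd_superfamily = src$dbd_superfamily,
          dbd_class = src$dbd_class)
        truth[[length(truth) + 1]] <- within(truth[[d]], motif_id <- id)
      }
    }
    list(records = records, truth = do.call(rbind, truth))
  })
}

overlaps_any <- function(start, end, occupied) {
  # 1-based closed intervals
  if (length(occupied) == 0) return(FALSE)
  for (iv in occupied) if (start <= iv[2] && end >= iv[1]) return(TRUE)
  FALSE
}

#' Generate promoter sequences with planted motif instances
#'
#' Each gene gets its own contig: a `length`-bp i.i.d. background sequence
#' (base probabilities `base_probs`) representing the 5 kb upstream / 500 bp
#' downstream TSS window. For every motif, `Poisson(rate)` copies of its
#' most-preferred sequence are planted at uniform non-overlapping positions
#' and random strands; motifs in `planted_motif_ids` use `rate_deg` in DEG
#' genes and `rate_bg` elsewhere, all other motifs use `rate_bg` everywhere.
#' A mask interval covering `mask_fraction` of each promoter is placed clear
#' of planted instances.
#'
#' @param motifs list of `motif_record`s (or a dictionary).
#' @param n_genes number of genes.
#' @param length promoter length in bp (default 5500 = 5000 upstream + 500
#'   downstream).
#' @param base_probs background base probabilities (default the empirical
#'   promoter composition A 0.247, C 0.251, G 0.254, T 0.248).
#' @param deg_fraction fraction of genes labelled DEG (default 0.2).
#' @param rate_deg,rate_bg Poisson planting rates per gene x motif
#'   (defaults 2 and 1).
#' @param planted_motif_ids motifs elevated in DEG genes (default: all).
#' @param mask_fraction fraction of each promoter masked (default 0.10).
#' @param seed RNG seed.
#' @param max_tries placement attempts before declaring the planting density
#'   infeasible (default 200).
#' @return list with `regions`, `genome`, `tss_table`, `masks` (BED-style
#'   data.frame), `deg_ids`, `truth` (instance data.frame) and `base_probs`.
#' @export
generate_promoters <- function(motifs, n_genes = 200, length = 5500,
                               base_probs = c(A = 0.247, C = 0.251,
                                              G = 0.254, T = 0.248),
                               deg_fraction = 0.2, rate_deg = 2, rate_bg = 1,
                               planted_motif_ids = NULL, mask_fraction = 0.10,
                               seed = 1, max_tries = 200) {
  if (inherits(motifs, "motif_dictionary")) motifs <- motifs$records
  stopifnot(rate_deg >= 0, rate_bg >= 0, n_genes >= 1)
  ids <- vapply(motifs, `[[`, character(1), "motif_id")
  planted_motif_ids <- planted_motif_ids %||% ids
  with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    n_deg <- ceiling(deg_fraction * n_genes)
    deg_ids <- gene_ids[seq_len(n_deg)]
    consensi <- vapply(motifs, function(r) ppm_consensus(r$ppm), character(1))
    genome <- character(n_genes)
    names(genome) <- gene_ids
    masks <- NULL
    truth <- list()
    regions <- vector("list", n_genes)
    for (gi in seq_len(n_genes)) {
      g <- gene_ids[gi]
      seq <- paste(sample(DNA_BASES, length, replace = TRUE,
                          prob = base_probs), collapse = "")
      occupied <- list()
      for (mi in seq_along(motifs)) {
        rate <- if (ids[mi] %in% planted_motif_ids && g %in% deg_ids)
          rate_deg else rate_bg
        k <- stats::rpois(1, rate)
        if (k == 0) next
        cons <- consensi[mi]
        m <- nchar(cons)
        for (inst in seq_len(k)) {
          placed <- FALSE
          for (try in seq_len(max_tries)) {
            pos <- sample.int(length - m + 1, 1)
            if (!overlaps_any(pos, pos + m - 1, occupied)) {
              strand <- sample(c("+", "-"), 1)
              ins <- if (strand == "+") cons else revcomp(cons)
              substr(seq, pos, pos + m - 1) <- ins
              occupied[[base::length(occupied) + 1]] <- c(pos, pos + m - 1)
              truth[[base::length(truth) + 1]] <- data.frame(
                gene_id = g, motif_id = ids[mi], start = pos - 1L,
                end = pos + m - 1L, strand = strand, stringsAsFactors = FALSE)
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            stop("planting density too high to avoid overlaps (gene ", g, ")")
          }
        }
      }
      mask_iv <- NULL
      mask_len <- round(mask_fraction * length)
      if (mask_len > 0) {
        for (try in seq_len(max_tries)) {
          s <- sample.int(length - mask_len + 1, 1)
          if (!overlaps_any(s, s + mask_len - 1, occupied)) {
            mask_iv <- matrix(c(s - 1L, s + mask_len - 1L), ncol = 2)
            masks <- rbind(masks, data.frame(chrom = g, start = s - 1L,
                                             end = s + mask_len - 1L,
                                             stringsAsFactors = FALSE))
            break
          }
        }
        if (is.null(mask_iv)) {
          warning("could not place mask clear of instances in ", g)
        }
      }
      genome[g] <- seq
      regions[[gi]] <- promoter_region(g, g, tss = length - 500 + 1,
                                       strand = "+", sequence = seq,
                                       mask_intervals = mask_iv)
    }
    names(regions) <- gene_ids
    truth <- if (base::length(truth) > 0) do.call(rbind, truth) else
      data.frame(gene_id = character(0), motif_id = character(0),
                 start = integer(0), end = integer(0), strand = character(0))
    list(regions = regions, genome = genome,
         tss_table = data.frame(gene_id = gene_ids, chrom = gene_ids,
                                tss = length - 500 + 1, strand = "+",
                                stringsAsFactors = FALSE),
         masks = masks %||% data.frame(chrom = character(0),
                                       start = integer(0), end = integer(0)),
         deg_ids = deg_ids, truth = truth, base_probs = base_probs)
  })
}

#' Generate paired PP/PN expression with planted DEGs, outliers and swaps
#'
#' Emulates a multi-dataset paired lesional/uninvolved design: per gene,
#' PN values are `baseline + Normal(0, sd)` and PP values add `log2(FC)`
#' (plus noise) for planted DEGs. `n_outliers` samples (one per affected
#' patient) get an extreme QC metric; `n_swaps` patients get their PP/PN
#' columns exchanged. Defaults mirror a 248-patient, 9-dataset cohort with
#' 1027 up / 796 down planted DEGs among 16117 genes; tests use smaller
#' explicit arguments.
#'
#' @param n_genes number of genes.
#' @param n_up,n_down planted DEG counts (first genes up, next down).
#' @param n_patients,n_datasets cohort structure (patients split as evenly
#'   as possible across datasets).
#' @param fc_up,fc_down planted fold changes on the ratio scale (2.0, 0.5).
#' @param sd within-patient noise SD on the log2 scale (default 0.5).
#' @param baseline_mean,baseline_sd per-gene baseline intensity distribution.
#' @param n_outliers QC-outlier samples (default 9).
#' @param n_swaps label-swapped patients (default 2).
#' @param seed RNG seed.
#' @return list with `expr` (a [paired_expression_set()] including outlier
#'   and swapped patients), `qc_metrics` and `truth`.
#' @export
generate_expression <- function(n_genes = 16117, n_up = 1027, n_down = 796,
                                n_patients = 248, n_datasets = 9,
                                fc_up = 2.0, fc_down = 0.5, sd = 0.5,
                                baseline_mean = 7, baseline_sd = 2,
                                n_outliers = 9, n_swaps = 2, seed = 1) {
  stopifnot(n_up + n_down <= n_genes,
            n_outliers + n_swaps <= n_patients,
            n_patients >= n_datasets)
  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    lfc <- rep(0, n_genes)
    lfc[seq_len(n_up)] <- log2(fc_up)
    if (n_down > 0) lfc[n_up + seq_len(n_down)] <- log2(fc_down)
    sizes <- rep(n_patients %/% n_datasets, n_datasets)
    extra <- n_patients %% n_datasets
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    dataset <- rep(sprintf("ds%02d", seq_len(n_datasets)), sizes)
    patients <- data.frame(patient_id = sprintf("pt%04d",
                                                seq_len(n_patients)),
                           dataset_id = dataset, stringsAsFactors = FALSE)
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    pn <- baseline +
      matrix(stats::rnorm(n_genes * n_patients, 0, sd), n_genes)
    pp <- pn + lfc +
      matrix(stats::rnorm(n_genes * n_patients, 0, sd), n_genes)
    rownames(pp) <- rownames(pn) <- genes
    affected <- sample(patients$patient_id, n_outliers + n_swaps)
    outlier_patients <- affected[seq_len(n_outliers)]
    swap_patients <- setdiff(affected, outlier_patients)
    for (p in swap_patients) {
      j <- which(patients$patient_id == p)
      tmp <- pp[, j]
      pp[, j] <- pn[, j]
      pn[, j] <- tmp
    }
    qc <- rbind(
      data.frame(sample_id = paste0(patients$patient_id, "_PP"),
                 patient_id = patients$patient_id,
                 dataset_id = patients$dataset_id, stringsAsFactors = FALSE),
      data.frame(sample_id = paste0(patients$patient_id, "_PN"),
                 patient_id = patients$patient_id,
                 dataset_id = patients$dataset_id, stringsAsFactors = FALSE))
    for (mc in c("avg_background", "scale_factor", "nuse_median",
                 "rle_median")) {
      qc[[mc]] <- stats::rnorm(nrow(qc))
    }
    # spread outliers over distinct metrics within a dataset (two extremes in
    # the same dataset x metric cell would mask each other: the within-cell
    # Z-score of duplicated extremes is bounded below 3.5), alternating sign
    # as a second guard
    metrics <- c("avg_background", "scale_factor", "nuse_median",
                 "rle_median")
    outlier_samples <- character(0)
    ds_counter <- list()
    for (p in outlier_patients) {
      tissue <- sample(c("_PP", "_PN"), 1)
      sid <- paste0(p, tissue)
      ds <- patients$dataset_id[patients$patient_id == p]
      k <- (ds_counter[[ds]] %||% 0L)
      ds_counter[[ds]] <- k + 1L
      metric <- metrics[(k %% 4L) + 1L]
      qc[[metric]][qc$sample_id == sid] <-
        if (k %/% 4L %% 2L == 0L) 50 else -50  # far beyond any |Z| = 3.5
      outlier_samples <- c(outlier_samples, sid)
    }
    expr <- paired_expression_set(pp, pn, patients)
    truth <- list(
      deg = data.frame(
        gene_id = genes[lfc != 0],
        direction = ifelse(lfc[lfc != 0] > 0, "up", "down"),
        fc = 2^lfc[lfc != 0], stringsAsFactors = FALSE),
      outlier_patients = outlier_patients,
      outlier_samples = outlier_samples,
      swap_patients = swap_patients)
    list(expr = expr, qc_metrics = qc, truth = truth)
  })
}

worst_base_index <- function(probs_col) which.min(probs_col)

#' Generate a SNP panel with planted binding-change truth
#'
#' Disrupt-SNPs sit inside planted motif instances and change the
#' highest-information base away from the consensus (risk allele breaks the
#' match); engender-SNPs sit at freshly planted near-miss sites where the
#' risk allele completes the match; neutral SNPs fall in background sequence
#' with a random alternate allele. Enhancer flags and conservation scores
#' are assigned at the stated fractions.
#'
#' @param promoters output of [generate_promoters()] (its sequences are
#'   updated in place for the planted near-miss sites and returned).
#' @param motifs the motif records used for planting.
#' @param n_snps panel size (default 572: 36 lead + 536 linked loci).
#' @param fractions named vector `c(disrupt=, engender=, neutral=)` summing
#'   to 1 (default 0.10 / 0.05 / 0.85).
#' @param enhancer_fraction fraction flagged as enhancer SNPs
#'   (default 53/572).
#' @param conserved_fraction fraction with phastcons >= 0.5 (default 0.3).
#' @param seed RNG seed.
#' @return list with `snps` (list of [snp_record()]s), `table`
#'   (serializable data.frame), `truth` and the updated `promoters`.
#' @export
generate_snp_panel <- function(promoters, motifs, n_snps = 572,
                               fractions = c(disrupt = 0.10,
                                             engender = 0.05,
                                             neutral = 0.85),
                               enhancer_fraction = 53 / 572,
                               conserved_fraction = 0.3, seed = 1) {
  if (inherits(motifs, "motif_dictionary")) motifs <- motifs$records
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  ids <- vapply(motifs, `[[`, character(1), "motif_id")
  names(motifs) <- ids
  m_max <- max(vapply(motifs, function(r) motif_width(r$ppm), integer(1)))
  half <- m_max + 1L
  n_dis <- round(fractions[["disrupt"]] * n_snps)
  n_eng <- round(fractions[["engender"]] * n_snps)
  n_neu <- n_snps - n_dis - n_eng
  genome <- promoters$genome
  plen <- nchar(genome[[1]])
  with_seed(seed, {
    inst <- promoters$truth
    usable <- inst[inst$start + 1 - half >= 1 &
                   inst$end + half <= plen, , drop = FALSE]
    if (n_dis > nrow(usable)) {
      stop("insufficient planted instances for ", n_dis, " disrupt-SNPs")
    }
    snps <- list()
    truth <- list()
    add_snp <- function(gene, pos, risk, nonrisk, type, motif_id) {
      i <- base::length(snps) + 1L
      flank <- substr(genome[[gene]], pos - half, pos + half)
      rec <- snp_record(sprintf("snp%04d", i), chrom = gene, pos = pos,
                        risk_allele = risk, nonrisk_allele = nonrisk,
                        flank = flank, center = half + 1L)
      snps[[i]] <<- rec
      truth[[i]] <<- data.frame(snp_id = rec$snp_id, type = type,
                                motif_id = motif_id, gene_id = gene,
                                pos = pos, stringsAsFactors = FALSE)
    }
    # disrupt: break the strongest column of a planted instance
    pick <- usable[sample.int(nrow(usable), n_dis), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      rec <- motifs[[pick$motif_id[r]]]
      p <- ppm_probs(rec$ppm)
      m <- ncol(p)
      j <- which.max(ppm_column_ics(rec$ppm))
      pos <- if (pick$strand[r] == "+") pick$start[r] + j
             else pick$start[r] + (m - j + 1)
      nonrisk <- substr(genome[[pick$gene_id[r]]], pos, pos)
      worst <- DNA_BASES[worst_base_index(p[, j])]
      risk <- if (pick$strand[r] == "+") worst else revcomp(worst)
      if (risk == nonrisk) {
        ord <- DNA_BASES[order(p[, j])]
        if (pick$strand[r] == "-") ord <- revcomp(ord)
        risk <- setdiff(ord, nonrisk)[1]
      }
      add_snp(pick$gene_id[r], pos, risk, nonrisk, "disrupt",
              pick$motif_id[r])
    }
    # engender: plant a near-miss and let the risk allele complete it
    occupied_by_gene <- split(
      lapply(seq_len(nrow(inst)), function(i) c(inst$start[i] + 1,
                                                inst$end[i])),
      inst$gene_id)
    genes <- names(genome)
    for (e in seq_len(n_eng)) {
      rec <- motifs[[sample(ids, 1)]]
      p <- ppm_probs(rec$ppm)
      m <- ncol(p)
      j <- which.max(ppm_column_ics(rec$ppm))
      cons <- ppm_consensus(rec$ppm)
      worst <- DNA_BASES[worst_base_index(p[, j])]
      broken <- cons
      substr(broken, j, j) <- worst
      placed <- FALSE
      for (try in seq_len(500)) {
        g <- sample(genes, 1)
        start <- sample(seq(half + 1, plen - half - m), 1)
        occ <- occupied_by_gene[[g]] %||% list()
        if (!overlaps_any(start, start + m - 1, occ)) {
          s <- genome[[g]]
          substr(s, start, start + m - 1) <- broken
          genome[[g]] <- s
          occupied_by_gene[[g]] <- c(occ, list(c(start, start + m - 1)))
          add_snp(g, start + j - 1, substr(cons, j, j), worst, "engender",
                  rec$motif_id)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place engender site ", e)
    }
    # neutral: background positions, random alternate allele
    for (u in seq_len(n_neu)) {
      for (try in seq_len(500)) {
        g <- sample(genes, 1)
        pos <- sample(seq(half + 1, plen - half), 1)
        occ <- occupied_by_gene[[g]] %||% list()
        if (!overlaps_any(pos, pos, occ)) {
          nonrisk <- substr(genome[[g]], pos, pos)
          risk <- sample(setdiff(DNA_BASES, nonrisk), 1)
          add_snp(g, pos, risk, nonrisk, "neutral", NA_character_)
          break
        }
        if (try == 500) stop("could not place neutral SNP")
      }
    }
    truth <- do.call(rbind, truth)
    n <- base::length(snps)
    enh <- rep(FALSE, n)
    enh[sample.int(n, round(enhancer_fraction * n))] <- TRUE
    cons_flag <- stats::runif(n) < conserved_fraction
    phast <- ifelse(cons_flag, stats::runif(n, 0.5, 1),
                    stats::runif(n, 0, 0.5))
    for (i in seq_len(n)) {
      snps[[i]]$enhancer <- enh[i]
      snps[[i]]$phastcons <- phast[i]
    }
    tab <- do.call(rbind, lapply(snps, function(s) {
      data.frame(snp_id = s$snp_id, chrom = s$chrom, pos = s$pos,
                 risk_allele = s$risk_allele,
                 nonrisk_allele = s$nonrisk_allele, flank = s$flank,
                 center = s$center, noncoding = s$noncoding,
                 enhancer = s$enhancer, phastcons = s$phastcons,
                 stringsAsFactors = FALSE)
    }))
    prom <- promoters
    prom$genome <- genome
    for (g in names(prom$regions)) {
      prom$regions[[g]]$sequence <- genome[[g]]
    }
    list(snps = snps, table = tab, truth = truth, promoters = prom)
  })
}

#' Convert a serialized SNP table back to records
#' @param tab data.frame as produced in [generate_snp_panel()]'s `table`.
#' @return list of [snp_record()]s.
#' @export
snp_table_to_records <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    snp_record(tab$snp_id[i], tab$chrom[i], tab$pos[i], tab$risk_allele[i],
               tab$nonrisk_allele[i], tab$flank[i], tab$center[i],
               noncoding = tab$noncoding[i], enhancer = tab$enhancer[i],
               phastcons = tab$phastcons[i])
  })
}

#' Null SNP sampler over a synthetic promoter set
#'
#' Returns a `function(n, seed)` that draws SNPs uniformly over promoter
#' positions (flank-valid), with the current base as the non-risk allele and
#' a uniformly random alternate as the risk allele — the resampling pool for
#' [simulation_null()].
#'
#' @param promoters output of [generate_promoters()].
#' @param flank_half half-width of the flank to attach (must cover the
#'   widest scored motif minus one).
#' @return sampler function.
#' @export
make_null_snp_sampler <- function(promoters, flank_half) {
  genome <- promoters$genome
  genes <- names(genome)
  plen <- nchar(genome[[1]])
  function(n, seed) {
    with_seed(seed, {
      lapply(seq_len(n), function(i) {
        g <- sample(genes, 1)
        pos <- sample(seq(flank_half + 1, plen - flank_half), 1)
        nonrisk <- substr(genome[[g]], pos, pos)
        risk <- sample(setdiff(DNA_BASES, nonrisk), 1)
        snp_record(sprintf("null%04d", i), g, pos, risk, nonrisk,
                   substr(genome[[g]], pos - flank_half, pos + flank_half),
                   center = flank_half + 1)
      })
    })
  }
}
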