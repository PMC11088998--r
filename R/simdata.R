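## Synthetic-data generator. Emulates the statistical structure the pipeline
## assumes -- a 2 condition x 2 bait x input/pulldown factorial with negative
## binomial counts, region-structured footprints with planted uORF/CDS
## coupling classes, motif-dependent CLIP tags and log-normal protein
## intensities with MNAR dropout -- plus a truth table, so every downstream
## stage is testable without raw data. Each output draws from its own RNG
## stream (seed + fixed per-output offset) so regenerating one file never
## perturbs the others.

.SEED_OFFSETS <- c(transcriptome = 11L, rna = 22L, ribo = 33L,
                   clip = 44L, ms = 55L)

#' Simulation parameters
#'
#' Replicate numbers default to the design of the emulated experiments: four
#' biological replicates for PL-CLIP, three for PL-Ribo-seq and five for
#' PL-MS. Planted-class fractions and effect sizes define the "stated world"
#' under each preset: `"strong"` plants clearly detectable effects (2 log2
#' units of dendritic enrichment and uORF/CDS translational change, 1.5 for
#' CLIP binding), `"paperlike"` halves them, and `"null"` sets every effect
#' to zero while keeping the class labels (for calibration tests).
#'
#' @param preset `"strong"`, `"null"` or `"paperlike"`.
#' @param n_genes number of genes (one transcript per gene).
#' @param seed integer seed; every output stream derives from it.
#' @param ... overrides for individual parameters (see the returned list).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(preset = c("strong", "null", "paperlike"),
                       n_genes = 2000L, seed = 42L, ...) {
  preset <- match.arg(preset)
  p <- list(
    preset = preset, n_genes = as.integer(n_genes), seed = as.integer(seed),
    n_reps_rna = 4L, n_reps_ribo = 3L, n_reps_ms = 5L,
    frac_dendritic = 0.2, frac_uorf = 0.15,
    frac_uorf_up = 0.06, frac_cds_up = 0.025, frac_cds_down = 0.025,
    frac_bound = 0.15, motif_coupling = 0.9,
    motif_fg_prob = 0.8, motif_bg_prob = 0.1,
    enrich_log2fc = 2, uorf_log2fc = 2, clip_log2fc = 1.5, ms_log2fc = 3,
    nb_dispersion = 0.05, clip_dispersion = 0,
    batch_sd = 0.1, size_sd = 0.15,
    mean_log_expression = log(80), sd_log_expression = 1,
    motif_seqs = c(eIF4G2 = "CGCGGC"),
    ms_missing_rate = 0.15, ms_frac_deenriched = 0.25, n_proteins = 1000L)
  if (preset == "null") {
    p$enrich_log2fc <- p$uorf_log2fc <- p$clip_log2fc <- p$ms_log2fc <- 0
  } else if (preset == "paperlike") {
    p$enrich_log2fc <- 1; p$uorf_log2fc <- 1; p$clip_log2fc <- 0.8
    p$ms_log2fc <- 1.5; p$nb_dispersion <- 0.1
  }
  override <- list(...)
  unknown <- setdiff(names(override), names(p))
  if (length(unknown) > 0L) stop("unknown parameters: ",
                                 paste(unknown, collapse = ", "))
  p[names(override)] <- override
  with(p, {
    stopifnot(frac_uorf_up <= frac_uorf,
              frac_cds_up + frac_cds_down <= frac_uorf_up,
              all(c(frac_dendritic, frac_uorf, frac_bound,
                    ms_missing_rate) >= 0),
              nb_dispersion >= 0)
  })
  structure(p, class = "sim_params")
}

## NB draws with variance mu + alpha mu^2; Poisson limit at alpha = 0.
.rnb <- function(n, mu, alpha) {
  if (alpha < 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate a transcriptome with planted classes
#'
#' Draws per-transcript region lengths from log-normals (dendritic genes
#' shifted longer in 5'UTR and CDS), writes random 5'UTR sequences with the
#' consensus motif inserted for `has_motif` genes and a frame-consistent
#' uORF (ATG ... stop) for uORF genes, and assigns every planted class:
#' dendritic localization, uORF/CDS coupling class, motif presence and
#' eIF4G2 binding (coupled to motif presence by `motif_coupling`; at full
#' coupling every bound gene carries the motif).
#'
#' @param params a [sim_params()] list.
#' @return list with `models` (transcript table incl. `utr5_seq`,
#'   `gc_frac`), `orfs` (ORF records incl. low-score decoys) and `truth`
#'   (per-gene planted flags and effect sizes).
#' @export
simulate_transcriptome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + .SEED_OFFSETS[["transcriptome"]])
  n <- params$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  tx_id <- sprintf("TX%05d", seq_len(n))

  dendritic <- seq_len(n) %in% sample.int(n, round(params$frac_dendritic * n))
  uorf_genes <- sample.int(n, round(params$frac_uorf * n))
  uorf_up <- uorf_genes[seq_len(round(params$frac_uorf_up * n))]
  n_up <- round(params$frac_cds_up * n)
  n_dn <- round(params$frac_cds_down * n)
  cds_up <- uorf_up[seq_len(n_up)]
  cds_down <- uorf_up[n_up + seq_len(n_dn)]
  uorf_class <- rep("none", n)
  uorf_class[uorf_up] <- "uORF-up+CDS-flat"
  uorf_class[cds_up] <- "uORF-up+CDS-up"
  uorf_class[cds_down] <- "uORF-up+CDS-down"
  has_uorf <- seq_len(n) %in% uorf_genes

  p_motif <- ifelse(uorf_class == "uORF-up+CDS-up",
                    params$motif_fg_prob, params$motif_bg_prob)
  has_motif <- rbinom(n, 1, p_motif) == 1
  c0 <- params$motif_coupling
  p_bound <- ifelse(has_motif,
                    params$frac_bound + c0 * (0.6 - params$frac_bound),
                    params$frac_bound * (1 - c0))
  bound <- rbinom(n, 1, p_bound) == 1

  motif <- params$motif_seqs[[1]]
  mlen <- nchar(motif)
  # uORF span (nt, incl. stop), multiple of 3, strictly > 9
  uorf_len <- ifelse(has_uorf, 3L * sample(4:12, n, replace = TRUE), 0L)
  min_u5 <- 10L + uorf_len + ifelse(has_motif, mlen + 4L, 0L)

  len_shift <- ifelse(dendritic, 1.4, 1)
  utr5_len <- round(rlnorm(n, log(150), 0.5) * len_shift)
  short <- which(utr5_len < min_u5)
  tries <- 0L
  while (length(short) > 0L && tries < 25L) {
    utr5_len[short] <- round(rlnorm(length(short), log(150), 0.5) *
                               len_shift[short])
    short <- which(utr5_len < min_u5)
    tries <- tries + 1L
  }
  if (length(short) > 0L) {
    message(length(short), " 5'UTR length(s) raised to host planted uORF/motif")
    utr5_len[short] <- min_u5[short]
  }
  cds_len <- 3L * pmax(30L, round(rlnorm(n, log(130), 0.5) * len_shift))
  utr3_len <- round(rlnorm(n, log(300), 0.6) * ifelse(dendritic, 1.5, 1))

  bases <- c("A", "C", "G", "T")
  utr5_seq <- vapply(seq_len(n), function(i) {
    gc <- runif(1, 0.35, 0.65)
    pr <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    s <- sample(bases, utr5_len[i], replace = TRUE, prob = pr)
    if (has_motif[i]) {   # plant motif near the 3' end, clear of the uORF
      at <- utr5_len[i] - mlen - 1L
      s[at + seq_len(mlen)] <- strsplit(motif, "")[[1]]
    }
    if (has_uorf[i]) {    # ATG ... in-frame stop, 0-based start at 3
      s[4:6] <- c("A", "T", "G")
      s[3L + uorf_len[i] - 2:0] <- c("T", "A", "A")
    }
    paste(s, collapse = "")
  }, "")

  models <- data.frame(gene_id = gene_id, tx_id = tx_id,
                       utr5_len = utr5_len, cds_len = cds_len,
                       utr3_len = utr3_len, utr5_seq = utr5_seq,
                       gc_frac = gc_fraction(utr5_seq),
                       stringsAsFactors = FALSE)
  validate_transcript_models(models)

  # real uORFs plus decoys that must fall to the length / score filters
  real <- which(has_uorf)
  orfs <- data.frame(tx_id = tx_id[real], start = rep(3L, length(real)),
                     end = 3L + uorf_len[real],
                     start_codon = rep("ATG", length(real)),
                     orf_class = rep("uORF", length(real)),
                     score = runif(length(real), 0.75, 0.99),
                     stringsAsFactors = FALSE)
  if (params$frac_uorf > 0) {
    dec <- sample.int(n, max(1L, round(0.1 * n)))
    decoys <- data.frame(tx_id = tx_id[dec], start = 0L,
                         end = ifelse(runif(length(dec)) < 0.5, 9L, 12L),
                         start_codon = sample(c("ATG", "CTG", "GTG"),
                                              length(dec), replace = TRUE),
                         orf_class = "uORF",
                         score = runif(length(dec), 0, 0.65),
                         stringsAsFactors = FALSE)
    orfs <- rbind(orfs, decoys)
  }

  eff <- params$uorf_log2fc
  truth <- data.frame(
    gene_id = gene_id, tx_id = tx_id,
    is_dendritic_rest = dendritic, is_dendritic_dep = dendritic,
    has_uorf = has_uorf, uorf_class = uorf_class,
    has_motif = has_motif, is_eif4g2_bound = bound,
    eff_enrich = ifelse(dendritic, params$enrich_log2fc, 0),
    eff_utr5 = ifelse(uorf_class != "none", eff, 0),
    eff_cds = ifelse(uorf_class == "uORF-up+CDS-up", eff,
                     ifelse(uorf_class == "uORF-up+CDS-down", -eff, 0)),
    eff_clip = ifelse(bound, params$clip_log2fc, 0),
    eff_protein = ifelse(dendritic, params$ms_log2fc, 0),
    stringsAsFactors = FALSE)

  list(models = models, orfs = orfs, truth = truth)
}

.make_meta <- function(assay, conditions, baits, fractions, biotins, n_reps) {
  g <- expand.grid(replicate = seq_len(n_reps), biotin = biotins,
                   fraction = fractions, bait = baits,
                   condition = conditions, stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_%s_%s_%s_r%d", assay, g$condition, g$bait,
                         g$fraction, g$biotin, g$replicate)
  g$batch <- paste0("b", g$replicate)
  validate_sample_meta(g)
  g[c("sample_id", "condition", "bait", "fraction", "biotin",
      "replicate", "batch")]
}

#' Simulate the PL-CLIP RNA count design
#'
#' Negative binomial counts over the full factorial (2 conditions x 2 baits
#' x input/pulldown x `n_reps_rna` replicates). Dendritic genes gain
#' `eff_enrich` log2 units in PSD95 pulldown samples of conditions where
#' their dendritic flag is set; replicate-wise batch offsets and heterogeneous
#' library-size factors are applied to all genes.
#'
#' @param params,models,truth outputs of [sim_params()] /
#'   [simulate_transcriptome()].
#' @return list with `counts` (a [count_matrix()]) and `meta`.
#' @export
simulate_rna_counts <- function(params, models, truth) {
  set.seed(params$seed + .SEED_OFFSETS[["rna"]])
  meta <- .make_meta("rna", c("rest", "dep"), c("Pan", "PSD95"),
                     c("input", "pulldown"), "plus", params$n_reps_rna)
  n <- nrow(models)
  mu0 <- rlnorm(n, params$mean_log_expression, params$sd_log_expression)
  size_fac <- rlnorm(nrow(meta), 0, params$size_sd)
  batch_off <- setNames(rnorm(params$n_reps_rna, 0, params$batch_sd),
                        paste0("b", seq_len(params$n_reps_rna)))
  counts <- matrix(0L, n, nrow(meta),
                   dimnames = list(models$tx_id, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    s <- meta[j, ]
    dend <- if (s$condition == "rest") truth$is_dendritic_rest else
      truth$is_dendritic_dep
    lfc <- ifelse(dend & s$bait == "PSD95" & s$fraction == "pulldown",
                  truth$eff_enrich, 0)
    mu <- mu0 * 2^(lfc + batch_off[[s$batch]]) * size_fac[j]
    counts[, j] <- .rnb(n, mu, params$nb_dispersion)
  }
  list(counts = count_matrix(counts), meta = meta)
}

#' Simulate region-resolved ribosome footprints
#'
#' Region counts (`tx:utr5`, `tx:cds`) over the PL-Ribo-seq design (2
#' conditions x 2 baits x input/pulldown x `n_reps_ribo`). Dendritic genes
#' are enriched in PSD95 pulldowns in both conditions; planted translation
#' classes act only in depolarized PSD95 pulldowns: uORF-up classes gain
#' `eff_utr5` on the 5'UTR, CDS-up/down gain the signed `eff_cds` on the
#' CDS. RNA-level means are untouched for these genes, so planted changes
#' are translation-only by construction.
#'
#' @inheritParams simulate_rna_counts
#' @return list with `counts` (regions x samples [count_matrix()]), `meta`,
#'   and `region_info` (tx, region, length per row).
#' @export
simulate_footprints <- function(params, models, truth) {
  set.seed(params$seed + .SEED_OFFSETS[["ribo"]])
  meta <- .make_meta("ribo", c("rest", "dep"), c("Pan", "PSD95"),
                     c("input", "pulldown"), "plus", params$n_reps_ribo)
  coding <- models$cds_len > 0 & models$utr5_len > 0
  m <- models[coding, , drop = FALSE]
  tr <- truth[match(m$tx_id, truth$tx_id), , drop = FALSE]
  n <- nrow(m)
  dens <- rlnorm(n, log(600), params$sd_log_expression)  # footprints per kb
  mu_u5 <- dens * (m$utr5_len / 1000) * 0.3
  mu_cds <- dens * (m$cds_len / 1000)
  size_fac <- rlnorm(nrow(meta), 0, params$size_sd)
  feat <- c(paste0(m$tx_id, ":utr5"), paste0(m$tx_id, ":cds"))
  counts <- matrix(0L, 2L * n, nrow(meta),
                   dimnames = list(feat, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    s <- meta[j, ]
    is_pd95 <- s$bait == "PSD95" && s$fraction == "pulldown"
    dend <- if (s$condition == "rest") tr$is_dendritic_rest else
      tr$is_dendritic_dep
    base <- if (is_pd95) ifelse(dend, tr$eff_enrich, 0) else 0
    dep_pd <- is_pd95 && s$condition == "dep"
    lfc_u5 <- base + if (dep_pd) tr$eff_utr5 else 0
    lfc_cds <- base + if (dep_pd) tr$eff_cds else 0
    counts[, j] <- .rnb(2L * n, c(mu_u5 * 2^lfc_u5, mu_cds * 2^lfc_cds) *
                          size_fac[j], params$nb_dispersion)
  }
  region_info <- data.frame(
    feature_id = feat, tx_id = rep(m$tx_id, 2L),
    region = rep(c("utr5", "cds"), each = n),
    length = c(m$utr5_len, m$cds_len), stringsAsFactors = FALSE)
  list(counts = count_matrix(counts), meta = meta, region_info = region_info)
}

#' Expand region counts of one sample into per-read 3' end positions
#'
#' Inverse of the P-site construction used by [assign_psites()]: P-sites are
#' placed uniformly within each region and read 3' ends are reported 12 nt
#' downstream, so `assign_psites()` + [count_regions()] recover the input
#' counts exactly.
#'
#' @param region_counts named integer vector (`tx:utr5` / `tx:cds`).
#' @param models transcript model table.
#' @param offset_nt 3' end to P-site offset (default 12).
#' @param seed RNG seed for the uniform placement.
#' @return data.frame with `tx_id` and `pos3` (transcript-local 3' ends).
#' @export
simulate_read_positions <- function(region_counts, models, offset_nt = 12L,
                                    seed = 1L) {
  set.seed(seed)
  parts <- strsplit(names(region_counts), ":", fixed = TRUE)
  tx <- vapply(parts, `[`, "", 1L)
  region <- vapply(parts, `[`, "", 2L)
  i <- match(tx, models$tx_id)
  if (anyNA(i)) stop("unknown transcripts: ",
                     paste(unique(tx[is.na(i)]), collapse = ", "))
  lo <- ifelse(region == "utr5", 0L, models$utr5_len[i])
  hi <- lo + ifelse(region == "utr5", models$utr5_len[i], models$cds_len[i])
  k <- as.integer(region_counts)
  psite <- unlist(lapply(seq_along(k), function(r) {
    if (k[r] == 0L) integer(0) else
      lo[r] + sample.int(hi[r] - lo[r], k[r], replace = TRUE) - 1L
  }))
  data.frame(tx_id = rep(tx, k), pos3 = psite + offset_nt,
             stringsAsFactors = FALSE)
}

#' Simulate eIF4G2 CLIP 5'UTR tag counts
#'
#' Poisson 5'UTR tag totals (dispersion configurable via
#' `clip_dispersion`) for resting and depolarized libraries at a nominal
#' depth of about one million tags each; bound genes gain `eff_clip` log2
#' units in the depolarized library. The two libraries share a common
#' nominal depth (their mean total), emulating libraries sequenced to
#' comparable depth; with Poisson sampling at this scale the downstream
#' exact binomial test is calibrated.
#'
#' @inheritParams simulate_rna_counts
#' @return A [count_matrix()] with columns `rest` and `dep`.
#' @export
simulate_clip_tags <- function(params, truth) {
  set.seed(params$seed + .SEED_OFFSETS[["clip"]])
  n <- nrow(truth)
  alpha <- if (is.null(params$clip_dispersion)) 0 else params$clip_dispersion
  mu0 <- rlnorm(n, log(1e6 / n) - 0.5, 1)
  rest <- .rnb(n, mu0, alpha)
  dep <- .rnb(n, mu0 * 2^truth$eff_clip, alpha)
  counts <- cbind(rest = rest, dep = dep)
  rownames(counts) <- truth$tx_id
  depth <- mean(colSums(counts))
  count_matrix(counts, lib_sizes = c(rest = depth, dep = depth))
}

#' Simulate proximity-proteomics intensities with MNAR dropout
#'
#' Log-normal intensities over 2 conditions x 2 baits x plus/minus biotin x
#' `n_reps_ms` replicates for the first `n_proteins` genes. Dendritic
#' proteins gain `eff_protein` log2 units in PSD95 plus-biotin samples;
#' minus-biotin samples carry background only (3 log2 units below, no
#' enrichment). Dropout is missing-not-at-random: the missing probability is
#' logistic in decreasing intensity, calibrated so that about
#' `ms_missing_rate` of entries are missing overall.
#'
#' @inheritParams simulate_rna_counts
#' @return list with `intensities` (linear scale, `NA` = missing), `meta`,
#'   `protein_truth` and `true_log2` (the pre-dropout matrix, for tests).
#' @export
simulate_proteins <- function(params, truth) {
  set.seed(params$seed + .SEED_OFFSETS[["ms"]])
  meta <- .make_meta("ms", c("rest", "dep"), c("Pan", "PSD95"),
                     "pulldown", c("plus", "minus"), params$n_reps_ms)
  np <- min(params$n_proteins, nrow(truth))
  tr <- truth[seq_len(np), , drop = FALSE]
  protein_id <- sub("^G", "P", tr$gene_id)
  base <- rnorm(np, 20, 2)
  # proteins depleted near the postsynaptic density (the pulldown design
  # sees de-enrichment as well as enrichment); drawn from non-dendritic
  # proteins so planted mass in the PSD95 columns is two-sided
  deenr <- !tr$is_dendritic_rest &
    rbinom(np, 1, min(1, params$ms_frac_deenriched /
                        max(1e-9, mean(!tr$is_dendritic_rest)))) == 1
  eff_ms <- ifelse(tr$is_dendritic_rest, tr$eff_protein,
                   ifelse(deenr, -params$ms_log2fc, 0))
  x <- matrix(NA_real_, np, nrow(meta),
              dimnames = list(protein_id, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    s <- meta[j, ]
    if (s$biotin == "minus") {
      mu <- base - 3
    } else {
      mu <- base + if (s$bait == "PSD95") eff_ms else 0
    }
    x[, j] <- rnorm(np, mu, 0.5)
  }
  if (params$ms_missing_rate > 0) {
    # per-run detection limit: each column's own intensity quantile
    obs <- x
    for (j in seq_len(ncol(x))) {
      q <- quantile(x[, j], probs = params$ms_missing_rate)
      p_miss <- stats::plogis((q - x[, j]) / 1.0)
      obs[rbinom(nrow(x), 1, p_miss) == 1, j] <- NA_real_
    }
  } else {
    obs <- x
  }
  pt <- data.frame(protein_id = protein_id, gene_id = tr$gene_id,
                   is_dendritic = tr$is_dendritic_rest,
                   is_deenriched = deenr,
                   eff_protein = eff_ms, stringsAsFactors = FALSE)
  list(intensities = 2^obs, meta = meta, protein_truth = pt, true_log2 = x)
}

#' Run the full generator and optionally write all pipeline inputs
#'
#' @param params a [sim_params()] list.
#' @param dir if non-`NULL`, write TSV/FASTA inputs for every stage there.
#' @return list with `models`, `orfs`, `truth`, `rna`, `ribo`, `clip`, `ms`.
#' @export
simulate_all <- function(params, dir = NULL) {
  tx <- simulate_transcriptome(params)
  sim <- list(models = tx$models, orfs = tx$orfs, truth = tx$truth,
              rna = simulate_rna_counts(params, tx$models, tx$truth),
              ribo = simulate_footprints(params, tx$models, tx$truth),
              clip = simulate_clip_tags(params, tx$truth),
              ms = simulate_proteins(params, tx$truth))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) write_tsv(x, file.path(dir, f))
    w(sim$models[setdiff(names(sim$models), "utr5_seq")], "models.tsv")
    write_utr_fasta(setNames(sim$models$utr5_seq, sim$models$tx_id),
                    file.path(dir, "utr5.fa"))
    w(sim$orfs, "orfs.tsv")
    w(sim$truth, "truth.tsv")
    write_counts(sim$rna$counts, file.path(dir, "rna_counts.tsv"))
    w(sim$rna$meta, "rna_samples.tsv")
    write_counts(sim$ribo$counts, file.path(dir, "region_counts.tsv"))
    w(sim$ribo$meta, "ribo_samples.tsv")
    w(sim$ribo$region_info, "region_info.tsv")
    write_counts(sim$clip, file.path(dir, "clip_tags.tsv"))
    ms_df <- data.frame(protein_id = rownames(sim$ms$intensities),
                        sim$ms$intensities, check.names = FALSE)
    w(ms_df, "protein_intensities.tsv")
    w(sim$ms$meta, "ms_samples.tsv")
  }
  sim
}
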