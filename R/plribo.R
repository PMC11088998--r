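## Region-resolved ribosome occupancy. Footprint P-sites are inferred with a
## fixed 12-nt offset from read 3' ends, counted into 5'UTR vs CDS in
## transcript-local half-open coordinates, converted to RPKM and quantile
## normalized. Dendritic translation is the log2 ratio of PSD95 pulldown to
## the mean of all inputs; significance comes from a per-transcript NB-GLM
## LRT (single conditions), a z-transform of differential log2 fold changes
## with a +/-1.96 cutoff (depolarized minus resting), and pooled permutation
## t-tests per region class.

#' Assign P-sites from read 3' end positions
#'
#' `psite = pos3 - offset`; reads whose P-site would fall before the
#' transcript start are dropped (their number is reported).
#'
#' @param pos3 integer vector of transcript-local 3' end positions.
#' @param offset_nt offset in nt (default 12).
#' @return integer vector of P-sites with attribute `n_dropped`.
#' @export
assign_psites <- function(pos3, offset_nt = 12L) {
  psite <- as.integer(pos3) - as.integer(offset_nt)
  keep <- psite >= 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) message(n_dropped, " read(s) dropped (P-site < 0)")
  structure(psite[keep], n_dropped = n_dropped)
}

#' Count P-sites into 5'UTR and CDS regions
#'
#' A P-site in `[0, utr5_len)` is 5'UTR, in `[utr5_len, utr5_len + cds_len)`
#' is CDS; anything further 3' (the 3'UTR) is discarded but counted, so
#' `utr5 + cds + discarded` equals the input read number.
#'
#' @param psites data.frame with `tx_id` and `psite` columns.
#' @param models transcript model table.
#' @return list with `counts` (named vector over `tx:utr5` / `tx:cds` for
#'   coding transcripts with both regions) and `n_discarded`.
#' @export
count_regions <- function(psites, models) {
  i <- match(psites$tx_id, models$tx_id)
  if (anyNA(i)) {
    stop("unknown transcripts: ",
         paste(unique(psites$tx_id[is.na(i)]), collapse = ", "))
  }
  u5 <- models$utr5_len[i]
  cds <- models$cds_len[i]
  in_u5 <- psites$psite >= 0 & psites$psite < u5
  in_cds <- psites$psite >= u5 & psites$psite < u5 + cds
  feat <- c(paste0(models$tx_id, ":utr5"), paste0(models$tx_id, ":cds"))
  counts <- setNames(integer(length(feat)), feat)
  t_u5 <- table(paste0(psites$tx_id[in_u5], ":utr5"))
  t_cds <- table(paste0(psites$tx_id[in_cds], ":cds"))
  counts[names(t_u5)] <- as.integer(t_u5)
  counts[names(t_cds)] <- as.integer(t_cds)
  list(counts = counts, n_discarded = sum(!in_u5 & !in_cds))
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts features x samples matrix (or vector).
#' @param lengths per-feature region lengths in nt (> 0).
#' @param lib_sizes per-sample library sizes (> 0).
#' @return RPKM matrix: `count / (length/1e3) / (lib_size/1e6)`.
#' @export
rpkm <- function(counts, lengths, lib_sizes) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("region lengths must be positive")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  t(t(counts / (lengths / 1e3)) / (lib_sizes / 1e6))
}

#' Quantile normalization
#'
#' Each column's sorted values are replaced by the across-column means of
#' sorted values; tied values receive the mean of the reference values their
#' ranks span. Complete matrices only.
#'
#' @param mat numeric matrix with >= 2 columns.
#' @return matrix with every column's empirical distribution identical.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 columns")
  if (anyNA(mat)) stop("missing values not supported")
  ref <- rowMeans(apply(mat, 2L, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(mat, 2L, function(x) {
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Dendritic translation enrichment per condition
#'
#' log2(mean PSD95-pulldown RPKM + eps) - log2(mean input RPKM + eps), the
#' inputs being the per-sample mean over all input libraries (both baits) of
#' the condition. The pseudocount eps = 0.1 matches the CLIP pseudocount.
#'
#' @param norm_rpkm features x samples matrix (normalized RPKM).
#' @param meta sample sheet covering the columns.
#' @param condition `"rest"` or `"dep"`.
#' @param eps pseudocount (default 0.1).
#' @return named numeric vector of log2 enrichments.
#' @export
dendritic_translation <- function(norm_rpkm, meta, condition, eps = 0.1) {
  m <- meta[match(colnames(norm_rpkm), meta$sample_id), , drop = FALSE]
  pd <- m$condition == condition & m$bait == "PSD95" & m$fraction == "pulldown"
  inp <- m$condition == condition & m$fraction == "input"
  if (!any(pd)) stop("no PSD95 pulldown samples for condition ", condition)
  if (!any(inp)) stop("no input samples for condition ", condition)
  log2(rowMeans(norm_rpkm[, pd, drop = FALSE]) + eps) -
    log2(rowMeans(norm_rpkm[, inp, drop = FALSE]) + eps)
}

## method-of-moments NB dispersion shared across design cells, floored
.mom_dispersion <- function(y, groups, floor = 1e-8) {
  ests <- vapply(split(y, groups), function(g) {
    if (length(g) < 2L) return(NA_real_)
    m <- mean(g)
    if (m <= 0) return(NA_real_)
    (var(g) - m) / m^2
  }, 0)
  a <- mean(ests, na.rm = TRUE)
  if (!is.finite(a)) a <- floor
  min(max(a, floor), 50)
}

#' Per-transcript NB-GLM likelihood ratio test of dendritic translation
#'
#' Within one condition, each transcript's counts are modeled with a
#' negative binomial GLM (log link, `offset(log(lib_size))`): the null model
#' is intercept-only, the alternative adds an indicator for PSD95 pulldown
#' samples. Dispersion is estimated by method of moments on the two sample
#' groups, floored at 1e-8 and shared between the fits; the LRT statistic is
#' twice the log-likelihood difference, referred to chi-squared with 1 df.
#' Only transcripts with `basemean > basemean_min` (mean depth-normalized
#' count) are tested.
#'
#' @param cm regions-or-transcripts [count_matrix()] (rows to test).
#' @param meta sample sheet covering the columns.
#' @param condition `"rest"` or `"dep"`.
#' @param basemean_min detection floor (default 1).
#' @param dispersion fixed NB dispersion; `NULL` (default) estimates it per
#'   transcript by method of moments.
#' @return data.frame `feature_id`, `log2fc` (PSD95-pulldown coefficient in
#'   log2 units), `lrt_stat`, `p`, `basemean`, `converged`.
#' @export
test_translation_lrt <- function(cm, meta, condition, basemean_min = 1,
                                 dispersion = NULL) {
  m <- meta[match(colnames(cm$counts), meta$sample_id), , drop = FALSE]
  use <- m$condition == condition
  if (sum(use) < 4L) stop("need >= 4 samples in condition ", condition)
  y <- cm$counts[, use, drop = FALSE]
  lib <- cm$lib_sizes[use]
  x <- as.integer(m$bait[use] == "PSD95" & m$fraction[use] == "pulldown")
  if (length(unique(x)) < 2L) stop("condition lacks a PSD95 pulldown group")
  norm <- t(t(y) / lib) * mean(lib)
  basemean <- rowMeans(norm)
  off <- log(lib)
  out <- data.frame(feature_id = rownames(y), log2fc = NA_real_,
                    lrt_stat = NA_real_, p = NA_real_, basemean = basemean,
                    converged = NA, stringsAsFactors = FALSE)
  for (r in which(basemean > basemean_min)) {
    yr <- y[r, ]
    alpha <- if (is.null(dispersion)) .mom_dispersion(norm[r, ], x) else
      max(dispersion, 1e-8)
    fam <- MASS::negative.binomial(theta = 1 / alpha)
    fit <- tryCatch({
      f1 <- suppressWarnings(glm(yr ~ x + offset(off), family = fam))
      f0 <- suppressWarnings(glm(yr ~ 1 + offset(off), family = fam))
      list(f1 = f1, f0 = f0, ok = f1$converged && f0$converged)
    }, error = function(e) NULL)
    if (is.null(fit) || !fit$ok) { out$converged[r] <- FALSE; next }
    ll <- function(f) sum(dnbinom(yr, size = 1 / alpha, mu = fitted(f),
                                  log = TRUE))
    stat <- max(0, 2 * (ll(fit$f1) - ll(fit$f0)))
    out$log2fc[r] <- coef(fit$f1)[["x"]] / log(2)
    out$lrt_stat[r] <- stat
    out$p[r] <- pchisq(stat, df = 1L, lower.tail = FALSE)
    out$converged[r] <- TRUE
  }
  out
}

#' z-transform differential log2 fold changes
#'
#' Centers and scales the fold changes over all admitted transcripts
#' (`z = (fc - mean) / sd`), takes two-sided p values from the standard
#' normal, and flags `|z| > 1.96` (2.5% per tail under the null, strict).
#'
#' @param fc named numeric vector of log2 fold changes (post basemean rules).
#' @param z_cut cutoff (default 1.96).
#' @return data.frame `feature_id`, `log2fc`, `z`, `p`, `significant`,
#'   `direction`.
#' @export
differential_translation_z <- function(fc, z_cut = 1.96) {
  if (is.null(names(fc))) names(fc) <- as.character(seq_along(fc))
  fc <- fc[is.finite(fc)]
  if (length(fc) < 30L) stop("need >= 30 finite fold changes")
  s <- sd(fc)
  if (s == 0) stop("degenerate input: zero fold-change dispersion")
  z <- (fc - mean(fc)) / s
  data.frame(feature_id = names(fc), log2fc = unname(fc), z = unname(z),
             p = unname(2 * pnorm(-abs(z))),
             significant = unname(abs(z) > z_cut),
             direction = unname(sign(fc)), stringsAsFactors = FALSE)
}

#' Basemean admission with highest-expressed-transcript fallback
#'
#' A transcript is admitted to the differential analysis directly when its
#' differential basemean reaches `min`. Otherwise, if its basemean reaches
#' `min` in both the resting and depolarized single-condition sets, the
#' differential value of the gene's highest-expressed transcript is
#' substituted (provenance flagged); otherwise it is excluded. 5'UTR
#' analyses use `min = 3`.
#'
#' @param diff data.frame `gene_id`, `tx_id`, `log2fc`, `basemean`.
#' @param rest,dep data.frames `tx_id`, `basemean`.
#' @param min basemean floor (default 1).
#' @return subset of `diff` with a `source` column
#'   (`"direct"`/`"substituted"`).
#' @export
apply_basemean_fallback <- function(diff, rest, dep, min = 1) {
  stopifnot(all(c("gene_id", "tx_id", "log2fc", "basemean") %in% names(diff)))
  bm_rest <- rest$basemean[match(diff$tx_id, rest$tx_id)]
  bm_dep <- dep$basemean[match(diff$tx_id, dep$tx_id)]
  direct <- !is.na(diff$basemean) & diff$basemean >= min
  eligible <- !direct & !is.na(bm_rest) & !is.na(bm_dep) &
    bm_rest >= min & bm_dep >= min
  out <- diff
  out$source <- ifelse(direct, "direct", NA_character_)
  if (any(eligible)) {
    ord <- order(diff$gene_id, -diff$basemean)
    top <- diff[ord, ][!duplicated(diff$gene_id[ord]), ]
    sub_fc <- top$log2fc[match(diff$gene_id, top$gene_id)]
    out$log2fc[eligible] <- sub_fc[eligible]
    out$source[eligible] <- "substituted"
  }
  out[direct | eligible, , drop = FALSE]
}

#' Permutation t-test (Welch statistic, label permutations)
#'
#' Exhaustive over all labelings when their number is at most
#' `max_exhaustive`, otherwise `n_perm` random permutations under `seed`.
#' The p value uses the add-one smoothing
#' `(1 + #\{|t_perm| >= |t_obs|\}) / (1 + N)`.
#'
#' @param x,y numeric vectors for the two groups.
#' @param n_perm random permutations when not exhaustive.
#' @param seed RNG seed for random mode.
#' @param max_exhaustive labeling count cap for exhaustive mode.
#' @return list `t_obs`, `p`, `n_labelings`, `exhaustive`.
#' @export
permutation_t_test <- function(x, y, n_perm = 10000L, seed = 1L,
                               max_exhaustive = 10000L) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  if (sd(c(x, y)) == 0) stop("degenerate input: all values identical")
  welch <- function(a, b) {
    (mean(a) - mean(b)) /
      sqrt(var(a) / length(a) + var(b) / length(b))
  }
  pooled <- c(x, y)
  nx <- length(x)
  t_obs <- welch(x, y)
  n_lab <- choose(length(pooled), nx)
  if (n_lab <= max_exhaustive) {
    idx <- combn(length(pooled), nx)
    tp <- apply(idx, 2L, function(i) welch(pooled[i], pooled[-i]))
    exhaustive <- TRUE
    N <- ncol(idx)
  } else {
    set.seed(seed)
    tp <- replicate(n_perm, {
      i <- sample.int(length(pooled), nx)
      welch(pooled[i], pooled[-i])
    })
    exhaustive <- FALSE
    N <- n_perm
  }
  tp <- tp[is.finite(tp)]
  p <- (1 + sum(abs(tp) >= abs(t_obs) - 1e-12)) / (1 + length(tp))
  list(t_obs = t_obs, p = min(1, p), n_labelings = N, exhaustive = exhaustive)
}

#' Pooled permutation test of region RPKM between conditions
#'
#' For each region class (5'UTR, CDS), each sample is summarized by its mean
#' RPKM over transcripts of that class; resting and depolarized summaries
#' are compared with [permutation_t_test()] and p values are Bonferroni
#' adjusted over the classes tested.
#'
#' @param rpkm_mat regions x samples RPKM matrix (rownames `tx:utr5` /
#'   `tx:cds`).
#' @param meta sample sheet covering the columns.
#' @param n_perm,seed passed to [permutation_t_test()].
#' @return data.frame per region class with `t_obs`, `p`, `p_bonf`,
#'   `exhaustive`.
#' @export
permutation_region_test <- function(rpkm_mat, meta, n_perm = 10000L,
                                    seed = 1L) {
  m <- meta[match(colnames(rpkm_mat), meta$sample_id), , drop = FALSE]
  region <- sub("^.*:", "", rownames(rpkm_mat))
  classes <- unique(region)
  res <- lapply(classes, function(cl) {
    sm <- colMeans(rpkm_mat[region == cl, , drop = FALSE])
    pt <- permutation_t_test(sm[m$condition == "rest"],
                             sm[m$condition == "dep"],
                             n_perm = n_perm, seed = seed)
    data.frame(region = cl, t_obs = pt$t_obs, p = pt$p,
               exhaustive = pt$exhaustive, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_bonf <- pmin(1, res$p * nrow(res))
  res
}

#' Filter uORFs by length and caller score
#'
#' Keeps `uORF`-class records strictly longer than 9 nt (stop codon
#' included) with score strictly above `score_min` (0.7 by default; 0.6 for
#' cross-assay intersections).
#'
#' @param orfs ORF record data.frame (see [read_orfs()]).
#' @param score_min score cutoff, strict.
#' @return filtered data.frame (start-codon class retained for reporting).
#' @export
filter_uorfs <- function(orfs, score_min = 0.7) {
  orfs[orfs$orf_class == "uORF" & (orfs$end - orfs$start) > 9 &
         orfs$score > score_min, , drop = FALSE]
}

#' Run the region-level PL-Ribo-seq differential stage
#'
#' RPKM + quantile normalization, per-condition dendritic translation,
#' differential (dep - rest) fold changes, basemean admission with fallback,
#' and the z procedure -- separately for 5'UTR (basemean floor 3) and CDS
#' (floor 1) regions.
#'
#' @param cm regions x samples [count_matrix()] (rownames `tx:utr5`,
#'   `tx:cds`).
#' @param meta sample sheet.
#' @param region_info data.frame `feature_id`, `tx_id`, `region`, `length`.
#' @param models transcript model table (for gene ids).
#' @param thresholds see [default_thresholds()].
#' @return list with per-region data.frames `utr5` and `cds` (z results
#'   joined to gene ids) and the normalized RPKM matrix.
#' @export
run_plribo <- function(cm, meta, region_info, models,
                       thresholds = default_thresholds()) {
  ri <- region_info[match(rownames(cm$counts), region_info$feature_id), ]
  rk <- rpkm(cm$counts, ri$length, cm$lib_sizes)
  nrk <- quantile_normalize(rk)
  norm_counts <- t(t(cm$counts) / cm$lib_sizes) * mean(cm$lib_sizes)
  one_region <- function(reg, bm_min) {
    rows <- ri$region == reg
    sub <- nrk[rows, , drop = FALSE]
    tx <- ri$tx_id[rows]
    fc_rest <- dendritic_translation(sub, meta, "rest",
                                     eps = thresholds$clip_pseudocount)
    fc_dep <- dendritic_translation(sub, meta, "dep",
                                    eps = thresholds$clip_pseudocount)
    bm_cond <- function(cond) {
      use <- meta$sample_id[meta$condition == cond]
      rowMeans(norm_counts[rows, use, drop = FALSE])
    }
    bm_all <- rowMeans(norm_counts[rows, , drop = FALSE])
    diff_tab <- data.frame(
      gene_id = models$gene_id[match(tx, models$tx_id)], tx_id = tx,
      log2fc = fc_dep - fc_rest, basemean = bm_all, stringsAsFactors = FALSE)
    adm <- apply_basemean_fallback(
      diff_tab,
      data.frame(tx_id = tx, basemean = bm_cond("rest")),
      data.frame(tx_id = tx, basemean = bm_cond("dep")),
      min = bm_min)
    zr <- differential_translation_z(setNames(adm$log2fc, adm$tx_id),
                                     z_cut = thresholds$z_cut)
    zr$gene_id <- adm$gene_id[match(zr$feature_id, adm$tx_id)]
    zr$basemean <- adm$basemean[match(zr$feature_id, adm$tx_id)]
    zr$source <- adm$source[match(zr$feature_id, adm$tx_id)]
    zr$fc_rest <- unname(fc_rest[match(zr$feature_id, tx)])
    zr$fc_dep <- unname(fc_dep[match(zr$feature_id, tx)])
    zr
  }
  list(utr5 = one_region("utr5", thresholds$basemean_min_utr5),
       cds = one_region("cds", thresholds$basemean_min_cds),
       norm_rpkm = nrk)
}
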