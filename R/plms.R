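## Proximity proteomics. The pipeline order is fixed and mirrors the usual
## Perseus-style workflow: log2 transform -> detection filter (two-thirds of
## replicates in at least one condition) -> downshifted-normal imputation
## (width 0.3, downshift 1.8) -> quartile-based width adjustment -> minus-
## biotin subtraction -> paired / unpaired t-tests at log2 > 0 and p < 0.05.

#' Log2-transform a protein intensity table
#'
#' @param intensities protein x sample matrix, linear scale, `NA` missing,
#'   positive where present.
#' @return log2 matrix with `NA` preserved.
#' @export
log2_intensities <- function(intensities) {
  x <- as.matrix(intensities)
  if (any(x[!is.na(x)] <= 0)) stop("intensities must be positive where present")
  log2(x)
}

#' Detection filter: two-thirds of replicates in at least one condition
#'
#' A protein is kept when, within at least one sample group (condition x
#' bait x biotin cell), it is observed in at least `ceiling(2n/3)` of the
#' group's `n` replicates ("minimum two-thirds" read as at-least, hence the
#' ceiling).
#'
#' @param mat protein x sample matrix (`NA` = missing).
#' @param meta sample sheet covering the columns.
#' @return filtered matrix.
#' @export
filter_detection <- function(mat, meta) {
  m <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  grp <- interaction(m$condition, m$bait, m$biotin, drop = TRUE)
  keep <- rep(FALSE, nrow(mat))
  for (g in levels(grp)) {
    cols <- grp == g
    need <- ceiling(2 * sum(cols) / 3)
    keep <- keep | rowSums(!is.na(mat[, cols, drop = FALSE])) >= need
  }
  mat[keep, , drop = FALSE]
}

#' Downshifted-normal imputation of missing log2 intensities
#'
#' Per sample column, missing entries are drawn from
#' `Normal(mean = m - downshift * s, sd = width * s)` where `m` and `s` are
#' the column's observed mean and standard deviation -- the standard
#' missing-not-at-random imputation for left-censored proteomics data.
#'
#' @param mat log2 protein x sample matrix.
#' @param width,downshift distribution parameters (defaults 0.3, 1.8).
#' @param seed RNG seed (deterministic imputations).
#' @return complete matrix.
#' @export
impute_downshift <- function(mat, width = 0.3, downshift = 1.8, seed = 1L) {
  set.seed(seed)
  out <- as.matrix(mat)
  for (j in seq_len(ncol(out))) {
    obs <- out[, j][!is.na(out[, j])]
    if (length(obs) < 2L) stop("column ", colnames(out)[j],
                               " has fewer than 2 observed values")
    na <- is.na(out[, j])
    if (any(na)) {
      out[na, j] <- rnorm(sum(na), mean(obs) - downshift * sd(obs),
                          width * sd(obs))
    }
  }
  out
}

#' Quartile-based width adjustment normalization
#'
#' Per column: subtract the column median, divide by the column IQR,
#' multiply by the across-column median IQR and add back the across-column
#' median of medians -- equalizing location and interquartile width across
#' samples while preserving within-column rank order. Idempotent.
#'
#' @param mat complete numeric matrix.
#' @return normalized matrix.
#' @export
width_adjust <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("width_adjust requires a complete matrix")
  med <- apply(mat, 2L, median)
  iqr <- apply(mat, 2L, function(x) diff(quantile(x, c(0.25, 0.75))))
  if (any(iqr == 0)) stop("zero IQR in column ",
                          colnames(mat)[which(iqr == 0)[1]])
  out <- sweep(sweep(mat, 2L, med), 2L, iqr, "/") * median(iqr) + median(med)
  dimnames(out) <- dimnames(mat)
  out
}

#' Subtract the minus-biotin counterpart of each plus-biotin sample
#'
#' Matched by condition, bait and replicate; the subtraction is done in log2
#' space (i.e. a ratio on the linear scale), the package default; matched
#' pairs are recorded in the attribute `pairs`.
#'
#' @param mat complete log2 protein x sample matrix.
#' @param meta sample sheet covering the columns (with a `biotin` column).
#' @return matrix over the plus-biotin samples, background-corrected.
#' @export
subtract_minus_biotin <- function(mat, meta) {
  m <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  plus <- m[m$biotin == "plus", , drop = FALSE]
  minus <- m[m$biotin == "minus", , drop = FALSE]
  key <- function(d) paste(d$condition, d$bait, d$replicate)
  j <- match(key(plus), key(minus))
  if (anyNA(j)) stop("plus-biotin sample without minus-biotin match: ",
                     paste(plus$sample_id[is.na(j)], collapse = ", "))
  out <- mat[, plus$sample_id, drop = FALSE] -
    mat[, minus$sample_id[j], drop = FALSE]
  colnames(out) <- plus$sample_id
  attr(out, "pairs") <- data.frame(plus = plus$sample_id,
                                   minus = minus$sample_id[j])
  out
}

.t_paired <- function(d) {
  n <- length(d)
  s <- sd(d)
  if (s == 0) return(list(t = 0, p = 1, zero_var = TRUE))
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), zero_var = FALSE)
}

.t_unpaired <- function(a, b) {   # classic pooled-variance Student t
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) return(list(t = 0, p = 1, zero_var = TRUE))
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2), zero_var = FALSE)
}

#' Proteomic enrichment t-tests
#'
#' Per-protein dendritic enrichment within a condition uses the two-tailed
#' paired Student t across replicates of PSD95 vs Pan background-corrected
#' values; the depolarized-minus-resting differential uses the two-tailed
#' unpaired Student t on the per-replicate PSD95 - Pan enrichments. A
#' protein is called enriched when the mean log2 difference is > 0 and
#' p < 0.05 (both strict). Zero variance yields p = 1 with flag
#' `"zero-variance"`.
#'
#' @param corrected background-corrected log2 matrix from
#'   [subtract_minus_biotin()].
#' @param meta sample sheet covering the columns.
#' @param mode `"paired"` (PSD95 vs Pan within `condition`) or
#'   `"differential"` (dep vs rest enrichments, unpaired).
#' @param condition required for mode `"paired"`.
#' @param p_cut significance cutoff (default 0.05).
#' @return a [result_table()] with the `enriched` call in `flag`.
#' @export
test_ms_enrichment <- function(corrected, meta,
                               mode = c("paired", "differential"),
                               condition = NULL, p_cut = 0.05) {
  mode <- match.arg(mode)
  m <- meta[match(colnames(corrected), meta$sample_id), , drop = FALSE]
  enr_cols <- function(cond) {
    p95 <- m$condition == cond & m$bait == "PSD95"
    pan <- m$condition == cond & m$bait == "Pan"
    j <- match(m$replicate[p95], m$replicate[pan])
    if (anyNA(j) || sum(p95) < 2L) stop("need >= 2 matched replicate pairs")
    corrected[, which(p95), drop = FALSE] -
      corrected[, which(pan)[j], drop = FALSE]
  }
  if (mode == "paired") {
    stopifnot(!is.null(condition))
    d <- enr_cols(condition)
    tt <- apply(d, 1L, .t_paired)
    est <- rowMeans(d)
  } else {
    dr <- enr_cols("rest")
    dd <- enr_cols("dep")
    tt <- lapply(seq_len(nrow(corrected)), function(r)
      .t_unpaired(dd[r, ], dr[r, ]))
    est <- rowMeans(dd) - rowMeans(dr)
  }
  tv <- vapply(tt, `[[`, 0, "t")
  pv <- vapply(tt, `[[`, 0, "p")
  zv <- vapply(tt, `[[`, TRUE, "zero_var")
  result_table(feature_id = rownames(corrected), log2fc = est, stat = tv,
               p = pv, basemean = rowMeans(corrected),
               flag = ifelse(zv, "zero-variance",
                             ifelse(est > 0 & pv < p_cut, "enriched", "ns")))
}

#' Run the full PL-MS stage
#'
#' log2 -> detection filter -> downshifted imputation -> width adjustment ->
#' minus-biotin subtraction -> enrichment tests (resting, depolarized,
#' differential). The applied order and parameters are returned alongside
#' the results.
#'
#' @param intensities linear-scale protein x sample matrix (`NA` missing).
#' @param meta sample sheet.
#' @param thresholds see [default_thresholds()].
#' @param seed imputation seed.
#' @return list with `rest`, `dep`, `differential` result tables, the
#'   `corrected` matrix and a `log` record of the steps.
#' @export
run_plms <- function(intensities, meta, thresholds = default_thresholds(),
                     seed = 7L) {
  x <- log2_intensities(intensities)
  x <- filter_detection(x, meta)
  x <- impute_downshift(x, width = thresholds$ms_impute_width,
                        downshift = thresholds$ms_impute_downshift,
                        seed = seed)
  x <- width_adjust(x)
  corrected <- subtract_minus_biotin(x, meta)
  res <- list(
    rest = test_ms_enrichment(corrected, meta, "paired", "rest",
                              p_cut = thresholds$ms_p),
    dep = test_ms_enrichment(corrected, meta, "paired", "dep",
                             p_cut = thresholds$ms_p),
    differential = test_ms_enrichment(corrected, meta, "differential",
                                      p_cut = thresholds$ms_p))
  res$corrected <- corrected
  res$log <- sprintf(
    "order=log2,filter,impute(width=%g,downshift=%g,seed=%d),width_adjust,subtract,test",
    thresholds$ms_impute_width, thresholds$ms_impute_downshift, seed)
  res
}
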