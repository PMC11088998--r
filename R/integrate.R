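## Threshold-coded integration across assays. All printed boundaries are
## strict exactly as stated (>, <): translational calls require log2 > 0 (or
## < 0) with p < 0.05, and are guarded by the differential PL-CLIP t
## statistic (t < 2 for up, t > -2 for down) so that RNA-level changes
## cannot masquerade as translational ones.

#' Classify genes by 5'UTR and CDS translational change
#'
#' `utr5_up` requires 5'UTR log2fc > 0 and p < 0.05 (basemean >= 3 applied
#' upstream). CDS class `up` requires CDS log2fc > 0, p < 0.05 and
#' differential PL-CLIP t < 2; `down` requires log2fc < 0, p < 0.05 and
#' t > -2; otherwise `flat`. `final_class` combines the two axes.
#'
#' @param utr5,cds data.frames keyed by `gene_id` with `log2fc` and `p`.
#' @param plclip_diff data.frame keyed by `feature_id` (gene) with `stat`
#'   (the differential PL-CLIP t statistic).
#' @param thresholds see [default_thresholds()].
#' @return data.frame with flags, `cds_class` and `final_class` per gene.
#' @export
classify_uorf_cds <- function(utr5, cds, plclip_diff,
                              thresholds = default_thresholds()) {
  genes <- intersect(utr5$gene_id, cds$gene_id)
  if (length(genes) == 0L) {
    stop("no shared genes between 5'UTR (", nrow(utr5), ") and CDS (",
         nrow(cds), ") tables")
  }
  u <- utr5[match(genes, utr5$gene_id), , drop = FALSE]
  k <- cds[match(genes, cds$gene_id), , drop = FALSE]
  t_diff <- plclip_diff$stat[match(genes, plclip_diff$feature_id)]
  p_cut <- thresholds$p_cds
  utr5_up <- u$log2fc > 0 & u$p < p_cut
  guard_up <- !is.na(t_diff) & t_diff < thresholds$guard_t_up
  guard_dn <- !is.na(t_diff) & t_diff > thresholds$guard_t_down
  cds_class <- ifelse(k$log2fc > 0 & k$p < p_cut & guard_up, "up",
               ifelse(k$log2fc < 0 & k$p < p_cut & guard_dn, "down", "flat"))
  final <- ifelse(!utr5_up, "none",
           ifelse(cds_class == "up", "uORF-up+CDS-up",
           ifelse(cds_class == "down", "uORF-up+CDS-down",
                  "uORF-up+CDS-flat")))
  data.frame(gene_id = genes, utr5_up = utr5_up, cds_class = cds_class,
             plclip_guard_pass = ifelse(cds_class == "up", guard_up,
                                 ifelse(cds_class == "down", guard_dn, NA)),
             final_class = final, stringsAsFactors = FALSE)
}

#' Intersect eIF4G2-bound transcripts with translation classes
#'
#' Builds the bound-and-uORF-bearing subsets of the translational classes:
#' bound genes intersected with genes carrying a filtered uORF and, per
#' class, with the CDS-up / CDS-down calls (CLIP side uses fold change > 1,
#' i.e. `call_bound(mode = "intersect")`, and the relaxed uORF score 0.6
#' upstream).
#'
#' @param classes output of [classify_uorf_cds()].
#' @param bound_genes character vector of bound gene ids.
#' @param uorf_genes character vector of gene ids with retained uORFs.
#' @return list of gene-id vectors `bound_uorf_cds_up`,
#'   `bound_uorf_cds_down`, `bound_utr5_up`, plus `sizes`.
#' @export
intersect_eif4g2 <- function(classes, bound_genes, uorf_genes) {
  up <- classes$gene_id[classes$final_class == "uORF-up+CDS-up"]
  down <- classes$gene_id[classes$final_class == "uORF-up+CDS-down"]
  u5 <- classes$gene_id[classes$utr5_up]
  sets <- list(
    bound_uorf_cds_up = intersect(intersect(up, bound_genes), uorf_genes),
    bound_uorf_cds_down = intersect(intersect(down, bound_genes), uorf_genes),
    bound_utr5_up = intersect(u5, bound_genes))
  sets$sizes <- lengths(sets)
  sets
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided D statistic and asymptotic p; used e.g. to compare the CDS
#' translation distribution of the eIF4G2-bound set against all genes.
#'
#' @param values_a,values_b numeric vectors (>= 1 value each).
#' @return list `D`, `p`, `n_a`, `n_b`.
#' @export
ks_compare <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1L, length(values_b) >= 1L)
  kt <- suppressWarnings(ks.test(values_a, values_b,
                                 alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(values_a), n_b = length(values_b))
}

#' Correlate two per-gene datasets on shared keys
#'
#' Pearson correlation on matched (log-scale) values, with Spearman always
#' co-reported.
#'
#' @param table_a,table_b data.frames with a key column and a value column.
#' @param key,value column names (shared by both tables).
#' @return list `r_pearson`, `p_pearson`, `r_spearman`, `n`.
#' @export
correlate_datasets <- function(table_a, table_b, key = "gene_id",
                               value = "log2fc") {
  shared <- intersect(table_a[[key]], table_b[[key]])
  if (length(shared) < 3L) stop("fewer than 3 shared keys")
  a <- table_a[[value]][match(shared, table_a[[key]])]
  b <- table_b[[value]][match(shared, table_b[[key]])]
  ok <- is.finite(a) & is.finite(b)
  ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
  list(r_pearson = unname(ct$estimate), p_pearson = ct$p.value,
       r_spearman = cor(a[ok], b[ok], method = "spearman"), n = sum(ok))
}

#' Reporter fold change (depolarized over resting, actin-normalized)
#'
#' `(flag_dep / actin_dep) / (flag_rest / actin_rest)` per replicate; with
#' replicate vectors, reports mean, sd and (when a reference construct's
#' fold changes are supplied) a two-tailed paired t test against it.
#'
#' @param flag_dep,actin_dep,flag_rest,actin_rest positive numerics
#'   (replicate vectors of equal length).
#' @param reference optional fold-change vector of a control construct.
#' @return list `fold_changes`, `mean`, `sd`, and `t`, `p` vs reference.
#' @export
reporter_fold_change <- function(flag_dep, actin_dep, flag_rest, actin_rest,
                                 reference = NULL) {
  if (any(c(flag_dep, actin_dep, flag_rest, actin_rest) <= 0)) {
    stop("all reporter inputs must be positive")
  }
  fc <- (flag_dep / actin_dep) / (flag_rest / actin_rest)
  out <- list(fold_changes = fc, mean = mean(fc), sd = sd(fc))
  if (!is.null(reference)) {
    stopifnot(length(reference) == length(fc))
    tt <- .t_paired(fc - reference)
    out$t <- tt$t
    out$p <- tt$p
  }
  out
}

#' Compare transcript features between two gene sets
#'
#' Two-sided Wilcoxon rank-sum tests of 5'UTR, CDS and 3'UTR lengths and
#' 5'UTR GC fraction between the transcripts of two sets, with medians and
#' effect direction.
#'
#' @param set_a,set_b character vectors of `tx_id`s.
#' @param models transcript model table.
#' @return data.frame, one row per feature.
#' @export
compare_transcript_features <- function(set_a, set_b, models) {
  stopifnot(length(set_a) > 0L, length(set_b) > 0L)
  a <- models[match(set_a, models$tx_id), , drop = FALSE]
  b <- models[match(set_b, models$tx_id), , drop = FALSE]
  if (anyNA(a$tx_id) || anyNA(b$tx_id)) stop("unknown tx ids in input sets")
  feats <- c("utr5_len", "cds_len", "utr3_len")
  if ("gc_frac" %in% names(models)) feats <- c(feats, "gc_frac")
  do.call(rbind, lapply(feats, function(f) {
    va <- a[[f]]; vb <- b[[f]]
    w <- suppressWarnings(wilcox.test(va, vb, alternative = "two.sided"))
    data.frame(feature = f, median_a = median(va, na.rm = TRUE),
               median_b = median(vb, na.rm = TRUE),
               direction = sign(median(va, na.rm = TRUE) -
                                  median(vb, na.rm = TRUE)),
               p = w$p.value, stringsAsFactors = FALSE)
  }))
}
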