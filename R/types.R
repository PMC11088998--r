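## Lightweight S3 containers shared by all stages. Following the DGEList /
## SummarizedExperiment idiom at desk scale: a count_matrix is a list with a
## counts matrix plus per-sample library sizes; annotation tables are plain
## data.frames validated on construction.

#' Construct a count matrix with library sizes
#'
#' @param counts numeric matrix of nonnegative counts, features x samples,
#'   with rownames (feature ids) and colnames (sample ids).
#' @param lib_sizes optional per-sample library sizes; defaults to column
#'   sums. A warning is emitted for empty (zero-sum) libraries.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `lib_sizes`.
#' @export
count_matrix <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have rownames (features) and colnames (samples)")
  }
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative and complete")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  storage.mode(counts) <- "double"
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- setNames(as.numeric(lib_sizes), colnames(counts))
  if (length(lib_sizes) != ncol(counts)) stop("one library size per sample required")
  if (any(lib_sizes == 0)) warning("empty library (zero column sum): ",
    paste(colnames(counts)[lib_sizes == 0], collapse = ", "))
  structure(list(counts = counts, lib_sizes = lib_sizes), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Validate a transcript model table
#'
#' A transcript model table holds one row per transcript with the region
#' lengths used everywhere downstream: `gene_id`, `tx_id`, `utr5_len`,
#' `cds_len`, `utr3_len` and optionally `utr5_seq` and `gc_frac`.
#' Coordinates are transcript-local, 0-based, half-open.
#'
#' @param models data.frame of transcript models.
#' @return The validated data.frame, invisibly classed `transcript_models`.
#' @export
validate_transcript_models <- function(models) {
  need <- c("gene_id", "tx_id", "utr5_len", "cds_len", "utr3_len")
  miss <- setdiff(need, names(models))
  if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(models$tx_id)) stop("tx_id must be unique")
  lens <- models[c("utr5_len", "cds_len", "utr3_len")]
  if (any(unlist(lens) < 0)) stop("region lengths must be >= 0")
  bad_cds <- models$cds_len > 0 & models$cds_len %% 3 != 0
  if (any(bad_cds)) {
    warning(sum(bad_cds), " transcript(s) with CDS length not divisible by 3")
  }
  if ("utr5_seq" %in% names(models)) {
    has <- !is.na(models$utr5_seq)
    if (any(nchar(models$utr5_seq[has]) != models$utr5_len[has])) {
      stop("utr5_seq length must equal utr5_len where present")
    }
  }
  class(models) <- unique(c("transcript_models", class(models)))
  invisible(models)
}

#' Validate a sample sheet
#'
#' @param meta data.frame with columns `sample_id`, `condition`
#'   (`rest`/`dep`), `bait` (`Pan`/`PSD95`), `fraction` (`input`/`pulldown`),
#'   `biotin` (`plus`/`minus`), `replicate`, `batch`.
#' @return The validated data.frame, invisibly.
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "condition", "bait", "fraction", "replicate", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("sample_id must be unique")
  chk <- function(col, levels) {
    if (col %in% names(meta) && !all(meta[[col]] %in% levels)) {
      stop(col, " must be one of: ", paste(levels, collapse = ", "))
    }
  }
  chk("condition", c("rest", "dep"))
  chk("bait", c("Pan", "PSD95"))
  chk("fraction", c("input", "pulldown"))
  chk("biotin", c("plus", "minus"))
  if (any(meta$replicate < 1)) stop("replicate must be a positive integer")
  invisible(meta)
}

#' Assemble a result table
#'
#' The common per-feature output of the differential stages: log2 fold
#' change, statistic (t or z), raw and BH-adjusted p value, basemean and a
#' categorical call flag.
#'
#' @param feature_id,log2fc,stat,p,basemean,flag vectors of equal length.
#' @param p_adj optional; defaults to Benjamini-Hochberg adjusted `p`.
#' @return A data.frame classed `result_table`.
#' @export
result_table <- function(feature_id, log2fc, stat, p, basemean,
                         p_adj = adjust_bh(p), flag = NA_character_) {
  out <- data.frame(feature_id = as.character(feature_id),
                    log2fc = log2fc, stat = stat, p = p, p_adj = p_adj,
                    basemean = basemean, flag = flag,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$feature_id)) stop("one row per feature required")
  ok <- !is.na(out$p)
  if (any(out$p[ok] < 0 | out$p[ok] > 1)) stop("p values must lie in [0, 1]")
  class(out) <- unique(c("result_table", class(out)))
  out
}
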