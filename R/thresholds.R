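#' Default analysis thresholds
#'
#' One configuration record housing every numeric cutoff used by the pipeline,
#' so that every stage logs and applies the same auditable constants.
#'
#' Localization calls use raw t-statistic cutoffs (`t_loc_single`,
#' `t_loc_diff`), the differential translation z procedure flags `|z| >
#' z_cut` (2.5% per tail under the null), uORFs must be strictly longer than
#' 9 nt including the stop codon with a score strictly above `orf_score`
#' (`orf_score_intersect` for cross-assay intersections), CLIP fold changes
#' use a pseudocount of `clip_pseudocount`, and proteomics imputation draws
#' from a downshifted normal (`ms_impute_width`, `ms_impute_downshift`).
#' `guard_t_up`/`guard_t_down` are the transcript-level guards that ensure
#' translational calls are not explained by RNA-level changes.
#'
#' @return A list of class `dendtrans_thresholds`.
#' @export
default_thresholds <- function() {
  structure(list(
    t_loc_single        = 1,
    t_loc_diff          = 1.25,
    z_cut               = 1.96,
    p_cds               = 0.05,
    basemean_min_cds    = 1,
    basemean_min_utr5   = 3,
    orf_min_len_nt      = 10,    # strictly > 9 nt including the stop codon
    orf_score           = 0.7,
    orf_score_intersect = 0.6,
    clip_pseudocount    = 0.1,
    clip_p              = 0.2,
    motif_min_score_frac = 0.95,
    motif_fdr           = 0.1,
    ms_impute_width     = 0.3,
    ms_impute_downshift = 1.8,
    ms_p                = 0.05,
    guard_t_up          = 2,
    guard_t_down        = -2,
    psite_offset_nt     = 12,
    pca_top_n           = 500,
    min_cpm             = 1
  ), class = "dendtrans_thresholds")
}

#' Read / write a thresholds configuration
#'
#' The configuration is a flat YAML file mirroring [default_thresholds()]
#' field for field; unknown keys are rejected so typos cannot silently fall
#' back to defaults.
#'
#' @param path file path of the YAML configuration.
#' @param thresholds a thresholds list as returned by [default_thresholds()].
#' @return `read_thresholds()` returns a `dendtrans_thresholds` list;
#'   `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  def <- default_thresholds()
  unknown <- setdiff(names(vals), names(def))
  if (length(unknown) > 0L) {
    stop("unknown threshold keys: ", paste(unknown, collapse = ", "))
  }
  def[names(vals)] <- lapply(vals, as.numeric)
  def
}

#' @rdname read_thresholds
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "dendtrans_thresholds") || is.list(thresholds))
  yaml::write_yaml(lapply(unclass(thresholds), as.numeric), path,
                   precision = 15L)
  invisible(path)
}

#' @export
print.dendtrans_thresholds <- function(x, ...) {
  cat("dendtrans thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
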