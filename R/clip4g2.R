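## eIF4G2 CLIP 5'UTR binding statistics: tags per 5'UTR are depth
## normalized, fold changes use a 0.1 pseudocount, and the depolarized vs
## resting comparison is an exact two-sided binomial test on the rounded
## normalized tags at null proportion 0.5 (two-sided by the
## minimum-likelihood rule, which is well defined for asymmetric cases).

#' Depth-normalize CLIP tag counts
#'
#' @param tags numeric vector/matrix of raw tag counts.
#' @param lib_sizes library size(s), > 0 (recycled across columns for a
#'   matrix).
#' @return tags per million: `tags * 1e6 / lib_size`.
#' @export
normalize_depth <- function(tags, lib_sizes) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (is.matrix(tags)) t(t(tags) * 1e6 / lib_sizes) else tags * 1e6 / lib_sizes
}

#' CLIP log2 fold change with pseudocount
#'
#' `log2((dep + pseudocount) / (rest + pseudocount))`.
#'
#' @param norm_dep,norm_rest normalized tag values (>= 0).
#' @param pseudocount default 0.1.
#' @return numeric vector of log2 fold changes.
#' @export
clip_log2fc <- function(norm_dep, norm_rest, pseudocount = 0.1) {
  stopifnot(all(norm_dep >= 0), all(norm_rest >= 0))
  log2((norm_dep + pseudocount) / (norm_rest + pseudocount))
}

#' Exact two-sided binomial test on normalized CLIP tags
#'
#' Rounds the normalized values to `k = round(dep)` successes out of
#' `n = round(dep + rest)` trials and computes the exact two-sided p value
#' at null proportion 0.5 by summing the probabilities of all outcomes no
#' more likely than the observed one. `n = 0` gives p = 1.
#'
#' @param norm_dep,norm_rest normalized tag values (vectors).
#' @return numeric vector of p values.
#' @export
clip_binomial_test <- function(norm_dep, norm_rest) {
  k <- round(norm_dep)
  n <- round(norm_dep + norm_rest)
  vapply(seq_along(k), function(i) {
    if (n[i] == 0) return(1)
    pmf <- dbinom(0:n[i], n[i], 0.5)
    min(1, sum(pmf[pmf <= pmf[k[i] + 1] * (1 + 1e-7)]))
  }, 0)
}

#' Build the 5'UTR tag table for the eIF4G2 CLIP stage
#'
#' @param cm [count_matrix()] with columns `rest` and `dep` (raw 5'UTR
#'   tags).
#' @param pseudocount passed to [clip_log2fc()].
#' @return data.frame with raw and normalized tags, `log2fc` and `p_binom`.
#' @export
clip_utr_table <- function(cm, pseudocount = 0.1) {
  stopifnot(all(c("rest", "dep") %in% colnames(cm$counts)))
  rest <- cm$counts[, "rest"]
  dep <- cm$counts[, "dep"]
  nr <- normalize_depth(rest, cm$lib_sizes[["rest"]])
  nd <- normalize_depth(dep, cm$lib_sizes[["dep"]])
  data.frame(tx_id = rownames(cm$counts),
             tags_rest = rest, tags_dep = dep,
             norm_rest = nr, norm_dep = nd,
             log2fc = clip_log2fc(nd, nr, pseudocount),
             p_binom = clip_binomial_test(nd, nr),
             stringsAsFactors = FALSE)
}

#' Call eIF4G2-bound transcripts
#'
#' Mode `"bound"`: `log2fc > 0` and `p < clip_p` (default 0.2), the
#' permissive call used for target characterization. Mode `"intersect"`:
#' fold change > 1 (`log2fc > 0`) with no p filter, the rule used when
#' intersecting with translation gene sets.
#'
#' @param table output of [clip_utr_table()].
#' @param mode `"bound"` or `"intersect"`.
#' @param clip_p p cutoff for mode `"bound"`.
#' @return character vector of bound `tx_id`s.
#' @export
call_bound <- function(table, mode = c("bound", "intersect"), clip_p = 0.2) {
  mode <- match.arg(mode)
  keep <- switch(mode,
    bound = table$log2fc > 0 & table$p_binom < clip_p,
    intersect = table$log2fc > 0)
  table$tx_id[keep]
}
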