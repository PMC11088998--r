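## PWM scanning of 5'UTR sequences and hypergeometric motif enrichment.
## Scoring is log-probability with a 1e-6 floor; a window hits when its
## score reaches min + frac * (max - min) of the achievable range (the
## "minimum score = 95%" convention). 5'UTRs are single-stranded RNA, so
## only the sense strand is scanned. Enrichment is at the transcript level
## (>= 1 hit) against an expressed background.

#' Build a PWM from a 4 x L probability matrix or a consensus string
#'
#' @param matrix 4 x L matrix of column probabilities, rows A, C, G, U/T.
#' @param motif_id,rbp_name identifiers.
#' @return list of class `pwm` with elements `motif_id`, `rbp_name`,
#'   `matrix`.
#' @export
pwm <- function(matrix, motif_id, rbp_name = motif_id) {
  matrix <- as.matrix(matrix)
  rn <- toupper(rownames(matrix))
  rn[rn == "U"] <- "T"
  if (is.null(rownames(matrix)) || !setequal(rn, c("A", "C", "G", "T"))) {
    stop("PWM rows must be A, C, G, U/T")
  }
  rownames(matrix) <- rn
  matrix <- matrix[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(matrix) < 3L) stop("PWM must have length >= 3")
  if (any(abs(colSums(matrix) - 1) > 1e-6)) stop("PWM columns must sum to 1")
  structure(list(motif_id = motif_id, rbp_name = rbp_name, matrix = matrix),
            class = "pwm")
}

#' @rdname pwm
#' @param consensus A/C/G/T(/U) string; each position gets probability 0.97
#'   on the consensus base and 0.01 elsewhere. Useful for packaging
#'   consensus-derived matrices (clearly synthetic stand-ins for curated
#'   PWMs).
#' @export
pwm_from_consensus <- function(consensus, motif_id, rbp_name = motif_id) {
  b <- strsplit(toupper(gsub("U", "T", consensus)), "")[[1]]
  stopifnot(all(b %in% c("A", "C", "G", "T")))
  m <- matrix(0.01, 4L, length(b), dimnames = list(c("A", "C", "G", "T")))
  m[cbind(match(b, rownames(m)), seq_along(b))] <- 0.97
  pwm(m, motif_id, rbp_name)
}

#' Read PWMs from a manifest
#'
#' The manifest is a TSV with columns `motif_id`, `rbp_name`, `file`
#' (paths relative to the manifest). Each PWM file has 4 whitespace-
#' separated rows labeled A/C/G/U(or T) followed by the column
#' probabilities.
#'
#' @param manifest_path manifest TSV.
#' @return named list of [pwm()] objects.
#' @export
read_pwms <- function(manifest_path) {
  man <- read.delim(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("motif_id", "rbp_name", "file") %in% names(man)))
  base <- dirname(manifest_path)
  out <- lapply(seq_len(nrow(man)), function(i) {
    lines <- readLines(file.path(base, man$file[i]))
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    m <- do.call(rbind, lapply(parts, function(x) as.numeric(x[-1])))
    rownames(m) <- vapply(parts, `[`, "", 1L)
    pwm(m, man$motif_id[i], man$rbp_name[i])
  })
  setNames(out, man$motif_id)
}

#' Count PWM hits in a sequence
#'
#' Scores every sense-strand window with the summed log probabilities
#' (floored at 1e-6) and counts windows whose score reaches
#' `min + min_score_frac * (max - min)` of the achievable score range.
#' Windows containing ambiguous bases are skipped. A degenerate PWM with no
#' score range triggers a warning and every window hits.
#'
#' @param seq A/C/G/T string (U mapped to T).
#' @param pwm a [pwm()] object.
#' @param min_score_frac threshold fraction (default 0.95).
#' @return integer hit count (attribute `n_skipped`: ambiguous windows).
#' @export
scan_pwm <- function(seq, pwm, min_score_frac = 0.95) {
  stopifnot(inherits(pwm, "pwm"))
  logm <- log(pwm$matrix + 1e-6)
  L <- ncol(logm)
  lo <- sum(apply(logm, 2L, min))
  hi <- sum(apply(logm, 2L, max))
  if (hi - lo < 1e-12) warning("degenerate PWM: every window hits")
  thr <- lo + min_score_frac * (hi - lo)
  s <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  if (length(s) < L) return(structure(0L, n_skipped = 0L))
  code <- match(s, c("A", "C", "G", "T"))      # NA for ambiguous bases
  n_win <- length(s) - L + 1L
  score <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    cj <- code[j:(j + n_win - 1L)]
    valid <- valid & !is.na(cj)
    score <- score + logm[cbind(ifelse(is.na(cj), 1L, cj), j)]
  }
  structure(sum(valid & score >= thr - 1e-12),
            n_skipped = sum(!valid))
}

#' Transcript x motif presence matrix
#'
#' @param seqs named character vector of 5'UTR sequences.
#' @param pwms list of [pwm()] objects.
#' @param min_score_frac passed to [scan_pwm()].
#' @return binary integer matrix, transcripts x motifs (1 = >= 1 hit).
#' @export
presence_matrix <- function(seqs, pwms, min_score_frac = 0.95) {
  ids <- vapply(pwms, `[[`, "", "motif_id")
  out <- matrix(0L, length(seqs), length(pwms),
                dimnames = list(names(seqs), ids))
  for (k in seq_along(pwms)) {
    out[, k] <- vapply(seqs, function(s)
      as.integer(scan_pwm(s, pwms[[k]], min_score_frac) >= 1L), 0L)
  }
  out
}

#' Hypergeometric motif enrichment of a foreground versus background
#'
#' For each motif, p = P(X >= fg_hits) with population `bg_total`,
#' `bg_hits` successes and `fg_total` draws; BH-adjusted across motifs,
#' enriched when `fdr < fdr_cut` (default 0.1). The background should be the
#' expressed set (longest transcript per gene); the foreground must be a
#' subset of it.
#'
#' @param fg,bg character vectors of transcript ids, `fg` a subset of `bg`.
#' @param presence output of [presence_matrix()] covering `bg`.
#' @param fdr_cut FDR threshold for the `enriched` flag.
#' @return data.frame per motif with hit counts, `p_hyper`, `fdr`,
#'   `enriched`.
#' @export
hypergeom_enrichment <- function(fg, bg, presence, fdr_cut = 0.1) {
  out_of_bg <- setdiff(fg, bg)
  if (length(out_of_bg) > 0L) {
    stop("foreground ids not in background: ",
         paste(head(out_of_bg, 5L), collapse = ", "))
  }
  miss <- setdiff(bg, rownames(presence))
  if (length(miss) > 0L) stop("background ids without presence rows: ",
                              paste(head(miss, 5L), collapse = ", "))
  pf <- presence[fg, , drop = FALSE]
  pb <- presence[bg, , drop = FALSE]
  fg_hits <- colSums(pf)
  bg_hits <- colSums(pb)
  fg_total <- length(fg)
  bg_total <- length(bg)
  p <- ifelse(bg_hits == 0, 1,
              phyper(fg_hits - 1, bg_hits, bg_total - bg_hits, fg_total,
                     lower.tail = FALSE))
  data.frame(motif_id = colnames(presence),
             fg_hits = fg_hits, fg_total = fg_total,
             bg_hits = bg_hits, bg_total = bg_total,
             p_hyper = p, fdr = adjust_bh(p),
             enriched = adjust_bh(p) < fdr_cut,
             row.names = NULL, stringsAsFactors = FALSE)
}
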