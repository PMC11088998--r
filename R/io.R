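## Readers/writers for the plain-text formats shared by all stages.
## Annotation is reduced at parse time to transcript-local region lengths;
## everything downstream works in 0-based half-open transcript coordinates.

#' Read transcript annotation (BED12 or minimal GTF)
#'
#' Derives per-transcript 5'UTR / CDS / 3'UTR lengths from block structure,
#' respecting strand. For BED12, the `name` field may be either `tx_id` or
#' `gene_id|tx_id`; rows with `thickStart == thickEnd` are non-coding and get
#' all region lengths 0 (they are excluded from region-level analyses). For
#' GTF, `exon` and `CDS` features with `transcript_id`/`gene_id` attributes
#' are used.
#'
#' @param path annotation file.
#' @param format `"bed12"` or `"gtf"`.
#' @return A transcript model data.frame (see [validate_transcript_models()]).
#' @export
read_annotation <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  models <- switch(format,
    bed12 = .parse_bed12(path),
    gtf   = .parse_min_gtf(path))
  validate_transcript_models(models)
  models
}

.parse_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) {
      stop("malformed BED12 line ", i, ": expected 12 fields, got ", length(f))
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    thick_start <- suppressWarnings(as.numeric(f[7]))
    thick_end <- suppressWarnings(as.numeric(f[8]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(as.numeric(strsplit(f[11], ",")[[1]]))
    offs <- suppressWarnings(as.numeric(strsplit(f[12], ",")[[1]]))
    if (anyNA(c(start, end, thick_start, thick_end, n_blocks, sizes, offs)) ||
        length(sizes) != n_blocks || length(offs) != n_blocks) {
      stop("malformed BED12 line ", i, ": bad numeric or block fields")
    }
    strand <- f[6]
    if (!strand %in% c("+", "-")) stop("malformed BED12 line ", i, ": strand")
    name <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    gene_id <- if (length(name) == 2L) name[1] else name[1]
    tx_id <- if (length(name) == 2L) name[2] else name[1]
    ex_start <- start + offs              # genomic, 0-based half-open
    ex_end <- ex_start + sizes
    total <- sum(sizes)
    if (thick_start == thick_end) {       # non-coding: excluded downstream
      u5 <- cds <- u3 <- 0
    } else {
      cds <- sum(pmax(0, pmin(ex_end, thick_end) - pmax(ex_start, thick_start)))
      left <- sum(pmax(0, pmin(ex_end, thick_start) - ex_start))
      right <- total - cds - left
      if (strand == "+") { u5 <- left; u3 <- right } else { u5 <- right; u3 <- left }
    }
    recs[[i]] <- data.frame(gene_id = gene_id, tx_id = tx_id,
                            utr5_len = u5, cds_len = cds, utr3_len = u3,
                            exon_len = total, stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

.parse_min_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 9L)
  if (length(bad) > 0L) stop("malformed GTF line ", bad[1])
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]+)"'), a))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }
  df <- data.frame(
    type = vapply(f, `[`, "", 3L),
    start = as.numeric(vapply(f, `[`, "", 4L)) - 1,  # to 0-based half-open
    end = as.numeric(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L),
    tx_id = vapply(f, function(x) attr_get(x[9], "transcript_id"), ""),
    gene_id = vapply(f, function(x) attr_get(x[9], "gene_id"), ""),
    stringsAsFactors = FALSE)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (anyNA(df$tx_id)) stop("GTF record without transcript_id attribute")
  out <- lapply(split(df, df$tx_id), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    total <- sum(ex$end - ex$start)
    cds_len <- sum(cds$end - cds$start)
    if (cds_len == 0) {
      u5 <- u3 <- cds_len <- 0
    } else {
      cds_lo <- min(cds$start); cds_hi <- max(cds$end)
      left <- sum(pmax(0, pmin(ex$end, cds_lo) - ex$start))
      right <- total - cds_len - left
      if (ex$strand[1] == "+") { u5 <- left; u3 <- right } else { u5 <- right; u3 <- left }
    }
    data.frame(gene_id = d$gene_id[1], tx_id = d$tx_id[1],
               utr5_len = u5, cds_len = cds_len, utr3_len = u3,
               exon_len = total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Keep the longest transcript per gene
#'
#' All gene-level analyses use a single representative transcript per gene:
#' the one maximizing total exonic length (`utr5 + cds + utr3`), ties broken
#' by the lexicographically smallest `tx_id`.
#'
#' @param models transcript model data.frame.
#' @return Subset of `models`, one row per `gene_id`.
#' @export
select_longest_transcript <- function(models) {
  stopifnot(all(c("gene_id", "tx_id") %in% names(models)))
  len <- models$utr5_len + models$cds_len + models$utr3_len
  ord <- order(models$gene_id, -len, models$tx_id)
  m <- models[ord, , drop = FALSE]
  m <- m[!duplicated(m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Read a feature x sample count table
#'
#' @param path TSV with a feature-id first column and one column per sample.
#' @param meta sample sheet; every count column must be declared there.
#' @return A [count_matrix()] with `lib_sizes` set to column sums.
#' @export
read_counts <- function(path, meta) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  extra <- setdiff(colnames(m), meta$sample_id)
  if (length(extra) > 0L) {
    stop("count columns absent from the sample sheet: ",
         paste(extra, collapse = ", "))
  }
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  if (any(m < 0) || any(abs(m - round(m)) > 1e-8)) {
    stop("counts must be nonnegative integers")
  }
  rownames(m) <- ids
  count_matrix(m)
}

#' @rdname read_counts
#' @param cm a `count_matrix`.
#' @param feature_col name for the feature-id column on write.
#' @export
write_counts <- function(cm, path, feature_col = "feature_id") {
  df <- data.frame(rownames(cm$counts), cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write result tables and sample sheets as TSV
#' @param path TSV file path.
#' @return `read_result_table()` a `result_table` data.frame;
#'   `read_sample_sheet()` a validated sample sheet.
#' @export
read_result_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- unique(c("result_table", class(df)))
  df
}

#' @rdname read_result_table
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_result_table
#' @export
read_sample_sheet <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  validate_sample_meta(meta)
  meta
}

#' Read an ORF table
#'
#' Expects ORF-caller-style columns `tx_id`, `start`, `end` (0-based,
#' half-open, transcript-local, stop codon included), `start_codon`,
#' `orf_class` (`uORF`, `start_overlap`, `other`) and `score`.
#'
#' @param path TSV file.
#' @return data.frame of ORF records.
#' @export
read_orfs <- function(path) {
  orfs <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tx_id", "start", "end", "start_codon", "orf_class", "score")
  miss <- setdiff(need, names(orfs))
  if (length(miss) > 0L) stop("missing ORF columns: ", paste(miss, collapse = ", "))
  if (any(orfs$end <= orfs$start)) stop("ORF end must exceed start")
  orfs
}

#' Read/write 5'UTR sequences as FASTA
#' @param path FASTA file.
#' @return `read_utr_fasta()`: named character vector of A/C/G/T sequences
#'   (U is mapped to T).
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  gsub("U", "T", seqs, fixed = TRUE)
}

#' @rdname read_utr_fasta
#' @param seqs named character vector of sequences.
#' @export
write_utr_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Fraction of G/C bases in a sequence
#' @param seq character vector of A/C/G/T sequences.
#' @return numeric vector of GC fractions in `[0, 1]` (NA for empty strings).
#' @export
gc_fraction <- function(seq) {
  n <- nchar(seq)
  gc <- vapply(gregexpr("[GC]", seq), function(m) sum(m > 0), 0L)
  ifelse(n > 0, gc / n, NA_real_)
}
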