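test_that("sim_params validates presets and overrides", {
  p <- sim_params("strong", n_genes = 500)
  expect_s3_class(p, "sim_params")
  expect_true(p$frac_cds_up + p$frac_cds_down <= p$frac_uorf_up)
  pn <- sim_params("null")
  expect_equal(pn$enrich_log2fc, 0)
  expect_equal(pn$clip_log2fc, 0)
  expect_error(sim_params("strong", nonsense = 1), "unknown parameters")
  expect_error(sim_params("strong", frac_cds_up = 0.2, frac_cds_down = 0.2,
                          frac_uorf_up = 0.1))
})

test_that("generator is deterministic and streams are independent", {
  p <- sim_params("strong", n_genes = 150, seed = 7)
  a <- simulate_transcriptome(p)
  b <- simulate_transcriptome(p)
  expect_identical(a$models$utr5_seq, b$models$utr5_seq)  # byte-identical
  expect_identical(a$truth, b$truth)

  # regenerating one output never perturbs another: interleave a clip draw
  r1 <- simulate_rna_counts(p, a$models, a$truth)
  invisible(simulate_clip_tags(p, a$truth))
  r2 <- simulate_rna_counts(p, a$models, a$truth)
  expect_identical(r1$counts$counts, r2$counts$counts)
})

test_that("planted class fractions land within 3 binomial SDs", {
  p <- sim_params("strong", n_genes = 2000, seed = 2)
  tx <- simulate_transcriptome(p)
  n <- p$n_genes
  band <- function(frac) 3 * sqrt(frac * (1 - frac) / n)
  expect_lt(abs(mean(tx$truth$is_dendritic_rest) - p$frac_dendritic),
            band(p$frac_dendritic) + 1e-9)
  expect_lt(abs(mean(tx$truth$uorf_class != "none") - p$frac_uorf_up),
            band(p$frac_uorf_up) + 1e-9)
  # motif fraction: planted at motif_fg_prob within the CDS-up class
  cds_up <- tx$truth$uorf_class == "uORF-up+CDS-up"
  expect_lt(abs(mean(tx$truth$has_motif[cds_up]) - p$motif_fg_prob),
            3 * sqrt(p$motif_fg_prob * 0.2 / sum(cds_up)))
})

test_that("transcriptome honors uORF and motif constraints", {
  p <- sim_params("strong", n_genes = 300, seed = 5)
  tx <- simulate_transcriptome(p)
  real <- tx$orfs[tx$orfs$score > 0.7, ]
  expect_true(all((real$end - real$start) %% 3 == 0))
  expect_true(all(real$end - real$start > 9))
  # uORFs sit inside their hosts' 5'UTRs and spell ATG ... stop
  u5 <- tx$models$utr5_len[match(real$tx_id, tx$models$tx_id)]
  expect_true(all(real$end <= u5))
  seqs <- tx$models$utr5_seq[match(real$tx_id, tx$models$tx_id)]
  expect_true(all(substr(seqs, real$start + 1, real$start + 3) == "ATG"))
  # planted motif present in sequence for has_motif genes
  with_m <- tx$truth$has_motif
  expect_true(all(grepl("CGCGGC",
                        tx$models$utr5_seq[with_m], fixed = TRUE)))
  # frac_uorf = 0 -> empty ORF set
  p0 <- sim_params("strong", n_genes = 100, frac_uorf = 0,
                   frac_uorf_up = 0, frac_cds_up = 0, frac_cds_down = 0)
  expect_equal(nrow(simulate_transcriptome(p0)$orfs), 0)
})

test_that("NB counts approach Poisson as dispersion vanishes", {
  p0 <- sim_params("null", n_genes = 800, seed = 3, nb_dispersion = 0,
                   batch_sd = 0, size_sd = 0)
  tx <- simulate_transcriptome(p0)
  rna <- simulate_rna_counts(p0, tx$models, tx$truth)
  cell <- rna$meta$sample_id[rna$meta$condition == "rest" &
                               rna$meta$bait == "Pan" &
                               rna$meta$fraction == "input"]
  y <- rna$counts$counts[, cell]
  ratio <- apply(y, 1, var) / pmax(rowMeans(y), 1e-9)
  expect_lt(abs(mean(ratio) - 1), 0.15)   # var/mean unbiased at 1

  p1 <- sim_params("null", n_genes = 800, seed = 3, nb_dispersion = 0.5,
                   batch_sd = 0, size_sd = 0)
  rna1 <- simulate_rna_counts(p1, tx$models, tx$truth)
  y1 <- rna1$counts$counts[, cell]
  ratio1 <- apply(y1, 1, var) / pmax(rowMeans(y1), 1e-9)
  expect_gt(mean(ratio1), 2)  # overdispersed world clearly separated
})

test_that("per-read positions invert the P-site construction exactly", {
  sim <- cached_sim("strong", 300, 1)
  counts1 <- sim$ribo$counts$counts[, 1]
  reads <- simulate_read_positions(counts1, sim$models, seed = 4)
  psites <- assign_psites(reads$pos3)
  expect_equal(attr(psites, "n_dropped"), 0)
  rc <- count_regions(data.frame(tx_id = reads$tx_id, psite = psites),
                      sim$models)
  expect_equal(rc$n_discarded, 0)
  expect_equal(rc$counts[names(counts1)], counts1[names(counts1)],
               ignore_attr = TRUE)
})

test_that("clip coupling spans independence to full nesting", {
  p_ind <- sim_params("strong", n_genes = 3000, seed = 8,
                      motif_coupling = 0)
  t_ind <- simulate_transcriptome(p_ind)$truth
  tab <- table(t_ind$has_motif, t_ind$is_eif4g2_bound)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_lt(abs(log(or)), 0.5)   # odds ratio near 1

  p_full <- sim_params("strong", n_genes = 2000, seed = 8,
                       motif_coupling = 1)
  t_full <- simulate_transcriptome(p_full)$truth
  expect_true(all(t_full$has_motif[t_full$is_eif4g2_bound]))
})

test_that("clip tags recover the planted fold change", {
  sim <- cached_sim("strong", 2000, 1)
  ct <- clip_utr_table(sim$clip)
  bound <- sim$truth$is_eif4g2_bound
  expect_lt(abs(median(ct$log2fc[bound]) - 1.5), 0.3)
  expect_lt(abs(median(ct$log2fc[!bound])), 0.1)
})

test_that("protein dropout is missing-not-at-random", {
  p <- sim_params("strong", n_genes = 1500, seed = 6)
  tx <- simulate_transcriptome(p)
  ms <- simulate_proteins(p, tx$truth)
  obs <- log2(ms$intensities)
  mask <- is.na(obs)
  expect_gt(mean(mask), 0.05)
  # true (pre-dropout) values of missing entries are lower than observed
  expect_lt(mean(ms$true_log2[mask]), mean(ms$true_log2[!mask]) - 1)
  # ms_missing_rate = 0 -> complete table
  p0 <- sim_params("strong", n_genes = 200, seed = 6, ms_missing_rate = 0,
                   n_proteins = 100)
  ms0 <- simulate_proteins(p0, simulate_transcriptome(p0)$truth)
  expect_false(anyNA(ms0$intensities))
})

test_that("simulate_all writes the full set of stage inputs", {
  dir <- withr::local_tempdir()
  p <- sim_params("strong", n_genes = 80, seed = 2, n_proteins = 50)
  sim <- simulate_all(p, dir = dir)
  files <- c("models.tsv", "utr5.fa", "orfs.tsv", "truth.tsv",
             "rna_counts.tsv", "rna_samples.tsv", "region_counts.tsv",
             "ribo_samples.tsv", "region_info.tsv", "clip_tags.tsv",
             "protein_intensities.tsv", "ms_samples.tsv")
  expect_true(all(file.exists(file.path(dir, files))))
  back <- read_counts(file.path(dir, "rna_counts.tsv"), sim$rna$meta)
  expect_identical(back$counts, sim$rna$counts$counts)
})
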