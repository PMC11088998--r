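test_that("filter_low_expression applies the cpm-in-k-samples rule", {
  meta <- make_pulldown_meta(2)   # 4 groups of 2 -> k = 2
  ids <- meta$sample_id
  counts <- rbind(
    allzero = rep(0L, 8),
    high = rep(100L, 8),                      # cpm >> 1 everywhere
    boundary = c(2L, rep(0L, 7)))             # cpm >= 1 in exactly k-1 = 1
  colnames(counts) <- ids
  cm <- count_matrix(counts, lib_sizes = rep(1e6, 8))
  kept <- filter_low_expression(cm, meta, min_cpm = 1)
  expect_setequal(rownames(kept$counts), "high")
  expect_error(filter_low_expression(
    count_matrix(counts["allzero", , drop = FALSE] + 0L,
                 lib_sizes = rep(1e6, 8)), meta), "filtered")
})

test_that("log_cpm evaluates its formula", {
  cm <- count_matrix(matrix(c(0L, 1000L), 1, 2,
                            dimnames = list("g", c("a", "b"))),
                     lib_sizes = c(1e6, 1e6))
  lc <- log_cpm(cm)
  expect_equal(lc[1, "a"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  # large-count values insensitive to doubling count and library together
  cm2 <- count_matrix(matrix(c(0L, 2000L), 1, 2,
                             dimnames = list("g", c("a", "b"))),
                      lib_sizes = c(2e6, 2e6))
  expect_equal(log_cpm(cm2)[1, "b"], lc[1, "b"], tolerance = 1e-3)
})

test_that("fit_contrast matches a normal-equations oracle", {
  set.seed(42)
  meta <- make_pulldown_meta(4)
  des <- plclip_design(meta)
  X <- des$design
  y <- matrix(rnorm(20 * nrow(X)), 20,
              dimnames = list(sprintf("g%02d", 1:20), des$sample_id))
  for (cc in des$contrasts) {
    got <- fit_contrast(y, X, cc, prior_df = 0)
    xtx_inv <- solve(t(X) %*% X)
    H <- xtx_inv %*% t(X)
    for (i in 1:20) {
      beta <- H %*% y[i, ]
      res <- y[i, ] - X %*% beta
      s2 <- sum(res^2) / (nrow(X) - ncol(X))
      est <- drop(t(cc) %*% beta)
      se <- sqrt(s2 * drop(t(cc) %*% xtx_inv %*% cc))
      expect_equal(got$log2fc[i], est, tolerance = 1e-8)
      expect_equal(got$stat[i], est / se, tolerance = 1e-8)
      expect_equal(got$p[i],
                   2 * pt(-abs(est / se), nrow(X) - ncol(X)),
                   tolerance = 1e-8)
    }
  }
})

test_that("fit_contrast degenerate and symmetry cases", {
  meta <- make_pulldown_meta(3)
  des <- plclip_design(meta)
  flat <- matrix(5, 2, nrow(des$design),
                 dimnames = list(c("a", "b"), des$sample_id))
  got <- fit_contrast(flat, des$design, des$contrasts$diff)
  expect_equal(got$log2fc, c(0, 0))
  expect_equal(got$stat, c(0, 0))
  expect_equal(got$p, c(1, 1))

  # swapping rest/dep labels negates the differential estimate
  set.seed(1)
  y <- matrix(rnorm(5 * nrow(des$design)), 5,
              dimnames = list(paste0("g", 1:5), des$sample_id))
  meta_sw <- meta
  meta_sw$condition <- ifelse(meta$condition == "rest", "dep", "rest")
  des_sw <- plclip_design(meta_sw)
  y_sw <- y[, des_sw$sample_id]
  a <- fit_contrast(y, des$design, des$contrasts$diff)
  b <- fit_contrast(y_sw, des_sw$design, des_sw$contrasts$diff)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-10)

  k <- ncol(des$design)
  expect_error(fit_contrast(flat[, seq_len(k)],
                            des$design[seq_len(k), , drop = FALSE],
                            rep(1, k)), "full rank|residual")
})

test_that("adjust_bh is the step-up procedure", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance and monotonicity
  set.seed(3)
  p <- runif(50)
  o <- sample(50)
  expect_equal(adjust_bh(p)[o], adjust_bh(p[o]))
  adj <- adjust_bh(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12))
  # agreement with the reference implementation
  expect_equal(adj, p.adjust(p, "BH"))
})

test_that("localization flags use strict printed thresholds", {
  rt <- function(stat) result_table(feature_id = paste0("g", seq_along(stat)),
                                    log2fc = 0, stat = stat, p = 0.5,
                                    basemean = 10)
  calls <- call_localized(rt(c(1, 1.0001, 2)), rt(c(0.5, 3, 1)),
                          rt(c(1.25, 1.26, -2)))
  expect_equal(calls$localized_rest, c(FALSE, TRUE, TRUE))  # t = 1 fails
  expect_equal(calls$localized_dep, c(FALSE, TRUE, FALSE))
  expect_equal(calls$localized_diff, c(FALSE, TRUE, FALSE)) # 1.25 fails
})

test_that("null preset t statistics match the t-distribution tails", {
  p <- sim_params("null", n_genes = 5000, seed = 3)
  tx <- simulate_transcriptome(p)
  rna <- simulate_rna_counts(p, tx$models, tx$truth)
  f <- filter_low_expression(rna$counts, rna$meta)
  des <- plclip_design(rna$meta)
  lm2 <- log_cpm(f)[, des$sample_id]
  rt <- fit_contrast(lm2, des$design, des$contrasts$diff, prior_df = 0)
  df_res <- nrow(des$design) - ncol(des$design)
  for (cut in c(1, 1.96)) {
    expected <- pt(-cut, df_res)
    obs <- mean(rt$stat > cut)
    expect_lt(abs(obs - expected),
              3 * sqrt(expected * (1 - expected) / nrow(rt)) + 1e-9)
  }
})

test_that("pca_qc behaves on duplicates and degenerate shapes", {
  set.seed(2)
  m <- matrix(rnorm(600), 100, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  m <- cbind(m, s7 = m[, 6])    # duplicated sample
  pc <- pca_qc(m, top_n = 50)
  expect_equal(pc$coords["s6", ], pc$coords["s7", ], tolerance = 1e-9)
  expect_true(all(pc$var_explained >= 0))
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-9)
  pc2 <- pca_qc(m[, 1:2])
  expect_equal(pc2$var_explained[1], 1)   # 2 samples -> PC1 explains all
  expect_error(pca_qc(m[, 1, drop = FALSE]), "2 samples")
  expect_error(pca_qc(m[1, , drop = FALSE]), "2 features")
})
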