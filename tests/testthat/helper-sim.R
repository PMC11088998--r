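# Shared fixtures, built in code. Simulations are cached per session so
# several test files can reuse the same stated world without regenerating.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(preset = "strong", n_genes = 1000L, seed = 1L) {
  key <- paste(preset, n_genes, seed, sep = "_")
  if (!exists(key, envir = .sim_cache)) {
    assign(key, simulate_all(sim_params(preset, n_genes = n_genes,
                                        seed = seed)),
           envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# minimal pulldown-only sample sheet (two conditions x two baits x reps)
make_pulldown_meta <- function(n_reps = 4L) {
  g <- expand.grid(replicate = seq_len(n_reps), bait = c("Pan", "PSD95"),
                   condition = c("rest", "dep"), stringsAsFactors = FALSE)
  g$sample_id <- sprintf("s_%s_%s_r%d", g$condition, g$bait, g$replicate)
  g$fraction <- "pulldown"
  g$biotin <- "plus"
  g$batch <- paste0("b", g$replicate)
  g
}

mk_res <- function(gene_id, log2fc, p) {
  data.frame(gene_id = gene_id, log2fc = log2fc, p = p,
             stringsAsFactors = FALSE)
}

# Welch t written independently of the package (oracle use only)
oracle_welch_t <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

run_full_pipeline <- function(sim) {
  pc <- run_plclip(sim$rna$counts, sim$rna$meta)
  pr <- run_plribo(sim$ribo$counts, sim$ribo$meta, sim$ribo$region_info,
                   sim$models)
  plclip_diff_gene <- data.frame(
    feature_id = sim$models$gene_id[match(pc$results$diff$feature_id,
                                          sim$models$tx_id)],
    stat = pc$results$diff$stat, stringsAsFactors = FALSE)
  cls <- classify_uorf_cds(pr$utr5[, c("gene_id", "log2fc", "p")],
                           pr$cds[, c("gene_id", "log2fc", "p")],
                           plclip_diff_gene)
  ct <- clip_utr_table(sim$clip)
  list(plclip = pc, plribo = pr, classes = cls, clip_table = ct)
}
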