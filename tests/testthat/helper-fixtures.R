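# Small fixtures built in code at test time.

# A tiny reporter table: `n_psm` PSMs for one protein across the 9-channel
# layout, with the given per-channel log2 abundance profile.
make_reporter_fixture <- function(profile = rep(10, 9), n_psm = 2,
                                  protein_id = "P1", run_id = "run1",
                                  psm_offsets = seq_len(n_psm) - 1) {
  layout <- tmt9_layout()
  rows <- expand.grid(psm = seq_len(n_psm), ch = seq_len(nrow(layout)))
  data.frame(
    protein_id = protein_id,
    peptide_id = paste0(protein_id, "_pep", rows$psm),
    psm_id = paste0(protein_id, "_psm", rows$psm),
    run_id = run_id,
    channel_id = layout$channel_id[rows$ch],
    condition = layout$condition[rows$ch],
    replicate = layout$replicate[rows$ch],
    intensity = 2^(profile[rows$ch] + psm_offsets[rows$psm]),
    stringsAsFactors = FALSE)
}

# A small count matrix + design for DE tests: `n_genes` genes, full
# 8-sample-type x n_batches design, no planted effects unless `lfc` given
# (applied to gene 1, Bic vs TTX, all strata).
make_counts_fixture <- function(n_genes = 40, n_batches = 3, base_mean = 150,
                                lfc = 0, dispersion = 0.05, seed = 1) {
  set.seed(seed)
  design <- expand.grid(batch = seq_len(n_batches), chx = c(FALSE, TRUE),
                        treatment = c("TTX", "BIC"),
                        genotype = c("WT", "S71A"), stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$genotype, "_", design$treatment, "_",
                             ifelse(design$chx, "CHX", "noCHX"), "_b",
                             design$batch)
  design <- design[, c("sample_id", "genotype", "treatment", "chx", "batch")]
  base <- exp(stats::runif(n_genes, log(base_mean / 3), log(base_mean * 3)))
  counts <- sapply(seq_len(nrow(design)), function(j) {
    mu <- base * 2^(c(lfc, rep(0, n_genes - 1)) *
                      (design$treatment[j] == "BIC"))
    stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  })
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  colnames(counts) <- design$sample_id
  list(counts = counts, design = design)
}

# A hand-built stratum fold-change table for cascade tests.
make_stratum_table <- function(gene_id, W, adj_W, S = W, adj_S = adj_W,
                               W_chx = W, adj_W_chx = adj_W,
                               S_chx = S, adj_S_chx = adj_S) {
  data.frame(gene_id = gene_id,
             W = W, p_W = adj_W, adj_W = adj_W,
             S = S, p_S = adj_S, adj_S = adj_S,
             W_chx = W_chx, p_W_chx = adj_W_chx, adj_W_chx = adj_W_chx,
             S_chx = S_chx, p_S_chx = adj_S_chx, adj_S_chx = adj_S_chx,
             stringsAsFactors = FALSE)
}
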