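#' @name synthetic_data
#' @title Seeded synthetic-data generators with planted truth
#'
#' @description
#' Generators that emulate the statistical structure of the study's inputs:
#' negative-binomial RNA-seq counts over the 8 sample types x 3 replicate
#' batches with planted activity-dependent, CHX-sensitive and
#' PDCD4-dependent gene classes; log-normal PSM reporter intensities over
#' the 9-channel TMT layout with planted nuclear enrichment and activity
#' shifts; and log-normal per-cell intensities with condition-specific
#' median ratios. Every generator is a pure function of (config, seed) and
#' returns truth labels alongside the data so that recovery can be scored
#' with [evaluate_recovery()].
NULL

#' RNA-seq simulation configuration
#'
#' The default configuration is the package's standard study-condition
#' fixture: 5,000 genes, 10% activity-up and 10% activity-down (1,000
#' activity genes), half of the activity genes CHX-sensitive, 20% of the
#' activity genes PDCD4-dependent with attenuation 0.1 (true change index
#' 0.9), planted log2 effect magnitudes Normal(3, 1) floored at 1 (the
#' scale of the canonical immediate-early-gene inductions),
#' NB dispersion 0.05, three replicate batches with additive log2
#' batch effects, and library-size factors drawn uniformly from
#' `libsize_range`. PDCD4-dependent genes are drawn from the
#' CHX-insensitive activity genes, so every planted target is eligible for
#' the full classification cascade.
#'
#' @param n_genes total number of genes.
#' @param frac_up,frac_down fractions of genes with activity-dependent up-
#'   and down-regulation (Bic vs TTX).
#' @param frac_chx_sensitive fraction of activity genes whose effect is
#'   present only without CHX.
#' @param frac_pdcd4 fraction of activity genes that are PDCD4-dependent.
#' @param attenuation multiplier in `[0, 1)` applied to the activity effect
#'   of PDCD4-dependent genes in S71A strata.
#' @param effect_mean,effect_sd,effect_min log2 effect-size distribution
#'   (Normal, floored at `effect_min`).
#' @param baseline_mean,baseline_sd log2 baseline-abundance distribution.
#' @param dispersion NB dispersion (`Var = mu + dispersion * mu^2`).
#' @param batch_sd SD of the additive per-batch log2 effect (shared across
#'   genes within a batch).
#' @param libsize_range range of per-sample library-size multipliers.
#' @param n_batches number of replicate batches.
#' @return list of class `rna_sim_config`.
#' @export
rna_sim_config <- function(n_genes = 5000L, frac_up = 0.10, frac_down = 0.10,
                           frac_chx_sensitive = 0.5, frac_pdcd4 = 0.2,
                           attenuation = 0.1,
                           effect_mean = 3, effect_sd = 1, effect_min = 1,
                           baseline_mean = 7, baseline_sd = 1.5,
                           dispersion = 0.05, batch_sd = 0.15,
                           libsize_range = c(0.7, 1.3), n_batches = 3L) {
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1) {
    stop("activity fractions must be nonnegative and sum to at most 1")
  }
  if (frac_chx_sensitive < 0 || frac_chx_sensitive > 1 ||
      frac_pdcd4 < 0 || frac_pdcd4 > 1) {
    stop("within-activity fractions must lie in [0, 1]")
  }
  if (frac_chx_sensitive + frac_pdcd4 > 1) {
    stop("CHX-sensitive and PDCD4-dependent fractions must sum to at most 1 ",
         "(PDCD4-dependent genes are drawn from the CHX-insensitive genes)")
  }
  if (attenuation < 0 || attenuation >= 1) stop("attenuation must lie in [0, 1)")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(n_genes = as.integer(n_genes), frac_up = frac_up,
                 frac_down = frac_down,
                 frac_chx_sensitive = frac_chx_sensitive,
                 frac_pdcd4 = frac_pdcd4, attenuation = attenuation,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 effect_min = effect_min, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, dispersion = dispersion,
                 batch_sd = batch_sd, libsize_range = libsize_range,
                 n_batches = as.integer(n_batches)),
            class = "rna_sim_config")
}

#' Simulate an RNA-seq count matrix with planted gene classes
#'
#' Generative model on the log2 scale:
#' `log2 mu = baseline + batch effect + effect * 1[Bic]`, where the
#' activity effect is zeroed under CHX for CHX-sensitive genes and
#' multiplied by the attenuation factor in S71A samples for PDCD4-dependent
#' genes. Counts are drawn NB with the configured dispersion after scaling
#' by the per-sample library factor.
#'
#' @param cfg an [rna_sim_config()].
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return list with `counts` (gene x sample integer matrix), `design`
#'   (sample sheet with `sample_id`, `genotype`, `treatment`, `chx`,
#'   `batch`) and `truth` (data.frame with `feature_id`, `class`,
#'   `chx_sensitive`, `pdcd4_dependent`, `effect_w`, `effect_s`).
#' @export
simulate_rnaseq_counts <- function(cfg = rna_sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "rna_sim_config"))
  set.seed(seed)
  n <- cfg$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  class <- rep("null", n)
  class[seq_len(n_up)] <- "activity_up"
  class[n_up + seq_len(n_down)] <- "activity_down"

  is_act <- class != "null"
  act_idx <- which(is_act)
  n_act <- length(act_idx)
  n_chx <- round(cfg$frac_chx_sensitive * n_act)
  n_pd <- round(cfg$frac_pdcd4 * n_act)
  chx_sensitive <- rep(FALSE, n)
  pdcd4_dependent <- rep(FALSE, n)
  chx_pick <- sample(act_idx, n_chx)
  chx_sensitive[chx_pick] <- TRUE
  # planted targets must survive the CHX-insensitivity filter, so they are
  # drawn from the CHX-insensitive activity genes
  pdcd4_dependent[sample(setdiff(act_idx, chx_pick), n_pd)] <- TRUE

  effect <- rep(0, n)
  mag <- pmax(stats::rnorm(n_act, cfg$effect_mean, cfg$effect_sd),
              cfg$effect_min)
  effect[act_idx] <- mag * ifelse(class[act_idx] == "activity_up", 1, -1)
  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)

  design <- expand.grid(batch = seq_len(cfg$n_batches),
                        chx = c(FALSE, TRUE),
                        treatment = c("TTX", "BIC"),
                        genotype = c("WT", "S71A"),
                        stringsAsFactors = FALSE)
  design <- design[, c("genotype", "treatment", "chx", "batch")]
  design$sample_id <- paste0(design$genotype, "_", design$treatment, "_",
                             ifelse(design$chx, "CHX", "noCHX"),
                             "_b", design$batch)
  design <- design[, c("sample_id", "genotype", "treatment", "chx", "batch")]

  batch_eff <- stats::rnorm(cfg$n_batches, 0, cfg$batch_sd)
  libfac <- stats::runif(nrow(design), cfg$libsize_range[1L],
                         cfg$libsize_range[2L])

  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    eff_j <- effect
    if (design$chx[j]) eff_j[chx_sensitive] <- 0
    if (design$genotype[j] == "S71A") {
      eff_j[pdcd4_dependent] <- eff_j[pdcd4_dependent] * cfg$attenuation
    }
    on <- as.numeric(design$treatment[j] == "BIC")
    mu <- 2^(baseline + batch_eff[design$batch[j]] + eff_j * on) * libfac[j]
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
  }
  if (max(counts) < .Machine$integer.max) storage.mode(counts) <- "integer"
  truth <- data.frame(feature_id = gene_id, class = class,
                      chx_sensitive = chx_sensitive,
                      pdcd4_dependent = pdcd4_dependent,
                      effect_w = effect,
                      effect_s = ifelse(pdcd4_dependent,
                                        effect * cfg$attenuation, effect),
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth)
}

#' The study's 9-channel TMT layout
#'
#' One 10-plex run carrying three no-APEX, three APEX+TTX and three
#' APEX+Bic samples (channel-to-sample assignment of the original design).
#'
#' @return data.frame with `channel_id`, `condition`, `replicate`.
#' @export
tmt9_layout <- function() {
  data.frame(
    channel_id = c("TMT126", "TMT127N", "TMT127C", "TMT128N", "TMT128C",
                   "TMT129N", "TMT129C", "TMT130N", "TMT130C"),
    condition = c("NO_APEX", "APEX_BIC", "APEX_TTX", "APEX_TTX", "NO_APEX",
                  "NO_APEX", "APEX_BIC", "APEX_BIC", "APEX_TTX"),
    replicate = c(1L, 1L, 1L, 2L, 2L, 3L, 2L, 3L, 3L),
    stringsAsFactors = FALSE)
}

#' TMT simulation configuration
#'
#' Defaults match the package's standard proteomics fixture: 1,000 proteins,
#' 30% nuclear with log2 enrichment ~ Normal(4, 0.5) in APEX channels, 5%
#' of the nuclear proteins activity-regulated with a log2 Bic shift
#' ~ Normal(1, 0.25) of random sign, 3 PSMs per protein, between-PSM log2
#' offsets ~ Normal(0, 0.5) and reporter noise SD 0.3.
#'
#' @param n_proteins number of proteins.
#' @param frac_nuclear fraction with planted nuclear enrichment.
#' @param enrich_mean,enrich_sd planted log2 enrichment distribution.
#' @param frac_activity fraction of nuclear proteins with an activity shift.
#' @param shift_mean,shift_sd planted log2 activity-shift magnitude
#'   distribution (sign drawn at random).
#' @param psms_per_protein PSMs per protein.
#' @param psm_sd SD of the additive per-PSM log2 offset.
#' @param noise_sd reporter-level log2 noise SD.
#' @param baseline_mean,baseline_sd protein log2 baseline distribution.
#' @return list of class `tmt_sim_config`.
#' @export
tmt_sim_config <- function(n_proteins = 1000L, frac_nuclear = 0.3,
                           enrich_mean = 4, enrich_sd = 0.5,
                           frac_activity = 0.05,
                           shift_mean = 1, shift_sd = 0.25,
                           psms_per_protein = 3L, psm_sd = 0.5,
                           noise_sd = 0.3,
                           baseline_mean = 12, baseline_sd = 1) {
  if (frac_nuclear < 0 || frac_nuclear > 1 ||
      frac_activity < 0 || frac_activity > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (noise_sd <= 0) stop("noise SD must be positive")
  structure(list(n_proteins = as.integer(n_proteins),
                 frac_nuclear = frac_nuclear, enrich_mean = enrich_mean,
                 enrich_sd = enrich_sd, frac_activity = frac_activity,
                 shift_mean = shift_mean, shift_sd = shift_sd,
                 psms_per_protein = as.integer(psms_per_protein),
                 psm_sd = psm_sd, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "tmt_sim_config")
}

#' Simulate a PSM-level TMT reporter table with planted truth
#'
#' Log2 reporter intensity = protein baseline + per-PSM offset
#' + enrichment (APEX channels, nuclear proteins)
#' + activity shift (Bic channels, activity proteins) + Normal noise.
#'
#' @param cfg a [tmt_sim_config()].
#' @param seed integer seed.
#' @return list with `reporter_table` (tall data.frame matching the
#'   proteomics input schema) and `truth` (data.frame with `feature_id`,
#'   `nuclear`, `enrichment`, `activity_shift`).
#' @export
simulate_tmt_psms <- function(cfg = tmt_sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "tmt_sim_config"))
  set.seed(seed)
  layout <- tmt9_layout()
  n <- cfg$n_proteins
  protein_id <- sprintf("prot%05d", seq_len(n))
  nuclear <- rep(FALSE, n)
  nuclear[sample.int(n, round(cfg$frac_nuclear * n))] <- TRUE
  enrichment <- ifelse(nuclear, stats::rnorm(n, cfg$enrich_mean, cfg$enrich_sd), 0)
  activity <- rep(FALSE, n)
  nuc_idx <- which(nuclear)
  activity[sample(nuc_idx, round(cfg$frac_activity * length(nuc_idx)))] <- TRUE
  shift <- ifelse(activity,
                  stats::rnorm(n, cfg$shift_mean, cfg$shift_sd) *
                    sample(c(-1, 1), n, replace = TRUE),
                  0)
  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)

  k <- cfg$psms_per_protein
  apex <- as.numeric(layout$condition != "NO_APEX")
  bic <- as.numeric(layout$condition == "APEX_BIC")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    psm_eff <- stats::rnorm(k, 0, cfg$psm_sd)
    log2i <- outer(baseline[i] + psm_eff,
                   enrichment[i] * apex + shift[i] * bic, "+") +
      stats::rnorm(k * nrow(layout), 0, cfg$noise_sd)
    rows[[i]] <- data.frame(
      protein_id = protein_id[i],
      peptide_id = paste0(protein_id[i], "_pep", rep(seq_len(k), nrow(layout))),
      psm_id = paste0(protein_id[i], "_psm", rep(seq_len(k), nrow(layout))),
      run_id = "run1",
      channel_id = rep(layout$channel_id, each = k),
      condition = rep(layout$condition, each = k),
      replicate = rep(layout$replicate, each = k),
      intensity = 2^as.vector(log2i),
      stringsAsFactors = FALSE)
  }
  rt <- do.call(rbind, rows)
  truth <- data.frame(feature_id = protein_id, nuclear = nuclear,
                      enrichment = enrichment, activity_shift = shift,
                      stringsAsFactors = FALSE)
  list(reporter_table = rt, truth = truth)
}

#' Simulate per-cell intensities with condition-specific medians
#'
#' Draws log-normal intensities scaled so that each condition's population
#' median equals the configured ratio. The default ratios are the basal /
#' TTX / Bic preset (1.00 / 1.00 / 0.55) of the nuclear PDCD4 imaging
#' comparison.
#'
#' @param median_ratios named numeric vector of per-condition median ratios
#'   relative to the control condition.
#' @param n_cells cells per condition per replicate.
#' @param n_replicates number of experimental replicates.
#' @param sdlog log-scale spread of the log-normal draws.
#' @param compartment compartment label stored in the table.
#' @param seed integer seed.
#' @return data.frame with `cell_id`, `replicate`, `condition`,
#'   `compartment`, `mean_intensity`.
#' @export
simulate_cell_intensities <- function(median_ratios = c(basal = 1.00,
                                                        TTX = 1.00,
                                                        Bic = 0.55),
                                      n_cells = 100L, n_replicates = 3L,
                                      sdlog = 0.6,
                                      compartment = "NUCLEUS", seed = 1L) {
  if (any(median_ratios <= 0)) stop("median ratios must be positive")
  set.seed(seed)
  out <- NULL
  for (r in seq_len(n_replicates)) {
    for (cond in names(median_ratios)) {
      v <- median_ratios[[cond]] * exp(stats::rnorm(n_cells, 0, sdlog))
      out <- rbind(out, data.frame(
        cell_id = sprintf("r%d_%s_c%04d", r, cond, seq_len(n_cells)),
        replicate = r, condition = cond, compartment = compartment,
        mean_intensity = v, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Score a call set against planted truth
#'
#' Standard confusion-count ratios. With an empty call set, precision is 1
#' by convention and recall is 0 (or 1 when there are no positives).
#'
#' @param called character vector of called feature ids; every id must be
#'   present in the truth table.
#' @param truth truth data.frame containing a `feature_id` column.
#' @param label_col name of the truth column defining positives (logical, or
#'   matched against `positive`).
#' @param positive value(s) of `label_col` that count as positive; ignored
#'   when `label_col` is logical.
#' @return list with `precision`, `recall`, `fdp`, `n_called`, `n_positive`.
#' @export
evaluate_recovery <- function(called, truth, label_col = "class",
                              positive = NULL) {
  if (!"feature_id" %in% names(truth)) stop("truth must contain feature_id")
  if (!label_col %in% names(truth)) stop("unknown truth column: ", label_col)
  if (!all(called %in% truth$feature_id)) {
    stop("called feature(s) absent from the truth table")
  }
  lab <- truth[[label_col]]
  pos <- if (is.logical(lab)) truth$feature_id[lab]
         else truth$feature_id[lab %in% positive]
  called <- unique(called)
  tp <- length(intersect(called, pos))
  precision <- if (!length(called)) 1 else tp / length(called)
  recall <- if (!length(pos)) 1 else tp / length(pos)
  list(precision = precision, recall = recall, fdp = 1 - precision,
       n_called = length(called), n_positive = length(pos))
}
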