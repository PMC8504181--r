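#' @name tmt
#' @title TMT proximity-proteome workflow
#'
#' @description
#' Functions that turn PSM-level TMT reporter intensities from a
#' nucleus-targeted proximity-labeling experiment into protein-level
#' contrasts and enrichment calls. The workflow is: per-run reference-channel
#' normalization ([normalize_reference_channels()]), removal of peptides
#' shared between proteins ([drop_shared_peptides()]), protein summarization
#' by two-way median polish ([summarize_protein_medpolish()]),
#' pooled-variance t contrasts with Benjamini-Hochberg adjustment
#' ([contrast_test()]), and the two gates: enrichment above the no-APEX
#' negative control ([call_enriched_above_control()]) and
#' activity regulation between stimulated and silenced conditions
#' ([call_activity_regulated()]).
NULL

.tmt_conditions <- c("NO_APEX", "APEX_TTX", "APEX_BIC")

#' Validate a PSM-level reporter table
#'
#' Checks the column set, condition labels, intensity positivity and the
#' uniqueness of each PSM within a (run, channel) cell.
#'
#' @param rt data.frame with columns `protein_id`, `peptide_id`, `psm_id`,
#'   `run_id`, `channel_id`, `condition`, `replicate`, `intensity`.
#' @return `rt`, invisibly, after validation.
#' @export
validate_reporter_table <- function(rt) {
  need <- c("protein_id", "peptide_id", "psm_id", "run_id", "channel_id",
            "condition", "replicate", "intensity")
  miss <- setdiff(need, names(rt))
  if (length(miss)) {
    stop("reporter table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(rt$condition), .tmt_conditions)
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.tmt_conditions, collapse = ", "), ")")
  }
  if (any(!is.na(rt$intensity) & rt$intensity <= 0)) {
    stop("reporter intensities must be strictly positive when present")
  }
  key <- paste(rt$run_id, rt$channel_id, rt$psm_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("each psm_id may occur at most once per channel within a run")
  }
  map <- unique(rt[, c("run_id", "channel_id", "condition", "replicate")])
  cell <- paste(map$run_id, map$channel_id, sep = "\r")
  if (anyDuplicated(cell)) {
    stop("a (run_id, channel_id) pair maps to more than one (condition, replicate)")
  }
  invisible(rt)
}

#' Align runs on their reference-condition channels
#'
#' Applies one constant log2 offset per MS run (each chromatographic
#' fraction counts as a run) so that the median log2 intensity of the
#' reference-condition channels is identical across runs. Runs are anchored
#' to the first run in lexicographic `run_id` order, so a single-run table
#' is returned unchanged. Within-run intensity ratios are preserved exactly
#' and the operation is idempotent.
#'
#' @param rt reporter table (see [validate_reporter_table()]).
#' @param reference_condition condition whose channels anchor the runs;
#'   the silenced (`"APEX_TTX"`) channels by default.
#' @return the reporter table with rescaled intensities.
#' @export
normalize_reference_channels <- function(rt, reference_condition = "APEX_TTX") {
  validate_reporter_table(rt)
  runs <- sort(unique(rt$run_id))
  ref_median <- vapply(runs, function(r) {
    v <- rt$intensity[rt$run_id == r &
                        rt$condition == reference_condition &
                        !is.na(rt$intensity)]
    if (!length(v)) {
      stop("run '", r, "' has no observed intensities in reference condition '",
           reference_condition, "'")
    }
    stats::median(log2(v))
  }, numeric(1))
  offset <- ref_median[[1L]] - ref_median
  rt$intensity <- rt$intensity * 2^offset[match(rt$run_id, runs)]
  rt
}

#' Drop peptides shared between proteins
#'
#' Peptides whose `peptide_id` maps to more than one `protein_id` are
#' removed before summarization (uniqueness rule for protein inference).
#'
#' @param rt reporter table.
#' @return the reporter table restricted to protein-unique peptides.
#' @export
drop_shared_peptides <- function(rt) {
  n_prot <- tapply(rt$protein_id, rt$peptide_id,
                   function(p) length(unique(p)))
  shared <- names(n_prot)[n_prot > 1L]
  rt[!(rt$peptide_id %in% shared), , drop = FALSE]
}

#' Summarize PSM intensities into protein abundance by median polish
#'
#' For each protein, the log2 reporter intensities are arranged as a
#' PSM x sample two-way table (rows are PSMs, pooled across runs/fractions;
#' columns are the biological samples, i.e. unique (condition, replicate)
#' pairs) and summarized by [median_polish()]. The protein's log2 abundance
#' in a sample is the overall effect plus that sample's column effect.
#' Missing reporter values are tolerated; proteins with no observed
#' intensity are omitted with a warning.
#'
#' @param rt reporter table, normally after [normalize_reference_channels()]
#'   and [drop_shared_peptides()].
#' @return an object of class `protein_abundance`: a list with `log2_abundance`
#'   (protein x sample matrix) and `samples` (data.frame with `sample_id`,
#'   `condition`, `replicate`).
#' @export
summarize_protein_medpolish <- function(rt) {
  validate_reporter_table(rt)
  samples <- unique(rt[, c("condition", "replicate")])
  samples <- samples[order(samples$condition, samples$replicate), , drop = FALSE]
  samples$sample_id <- paste(samples$condition, samples$replicate, sep = ".")
  rownames(samples) <- NULL
  samples <- samples[, c("sample_id", "condition", "replicate")]

  rt$sample_id <- paste(rt$condition, rt$replicate, sep = ".")
  rt$psm_key <- paste(rt$run_id, rt$psm_id, sep = "\r")

  proteins <- sort(unique(rt$protein_id))
  ab <- matrix(NA_real_, nrow = length(proteins), ncol = nrow(samples),
               dimnames = list(proteins, samples$sample_id))
  dropped <- character(0)
  idx <- split(seq_len(nrow(rt)), rt$protein_id)
  for (p in proteins) {
    sub <- rt[idx[[p]], , drop = FALSE]
    if (all(is.na(sub$intensity))) {
      dropped <- c(dropped, p)
      next
    }
    rows <- unique(sub$psm_key)
    m <- matrix(NA_real_, nrow = length(rows), ncol = nrow(samples),
                dimnames = list(rows, samples$sample_id))
    m[cbind(match(sub$psm_key, rows), match(sub$sample_id, samples$sample_id))] <-
      log2(sub$intensity)
    mp <- median_polish(m)
    ab[p, ] <- mp$overall + mp$col
  }
  if (length(dropped)) {
    warning("omitted ", length(dropped),
            " protein(s) with no observed intensity: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
    ab <- ab[setdiff(proteins, dropped), , drop = FALSE]
  }
  structure(list(log2_abundance = ab, samples = samples),
            class = "protein_abundance")
}

#' Protein-level group contrast with pooled-variance t test
#'
#' For each protein, compares the mean log2 abundance between two groups of
#' samples selected by condition label. The log2 fold change is
#' `mean(group_a) - mean(group_b)`; inference uses the two-sided
#' pooled-variance t test, and p values are Benjamini-Hochberg adjusted
#' across all testable proteins within the contrast. A protein with fewer
#' than two observed values in either group is flagged untestable and
#' carries missing `p`/`adj_p`.
#'
#' @param pam `protein_abundance` object from [summarize_protein_medpolish()].
#' @param group_a,group_b character vectors of condition labels defining the
#'   two sample groups (`group_a` minus `group_b`).
#' @param label contrast label stored in the result.
#' @return data.frame with columns `protein_id`, `contrast`, `log2FC`, `SE`,
#'   `df`, `p`, `adj_p`, `testable`, ordered by `adj_p` then `protein_id`.
#' @export
contrast_test <- function(pam, group_a, group_b,
                          label = paste(paste(group_a, collapse = "+"), "vs",
                                        paste(group_b, collapse = "+"))) {
  stopifnot(inherits(pam, "protein_abundance"))
  cond <- pam$samples$condition
  a_cols <- which(cond %in% group_a)
  b_cols <- which(cond %in% group_b)
  if (!length(a_cols) || !length(b_cols)) {
    stop("contrast groups select no samples")
  }
  ab <- pam$log2_abundance
  res <- data.frame(
    protein_id = rownames(ab),
    contrast = label,
    log2FC = NA_real_, SE = NA_real_, df = NA_real_,
    p = NA_real_, adj_p = NA_real_, testable = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(ab))) {
    va <- ab[i, a_cols]; va <- va[!is.na(va)]
    vb <- ab[i, b_cols]; vb <- vb[!is.na(vb)]
    na <- length(va); nb <- length(vb)
    if (na < 2L || nb < 2L) next
    fc <- mean(va) - mean(vb)
    df <- na + nb - 2
    sp2 <- ((na - 1) * stats::var(va) + (nb - 1) * stats::var(vb)) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    if (se == 0) {
      p <- if (fc == 0) 1 else 0
    } else {
      p <- 2 * stats::pt(-abs(fc / se), df)
    }
    res$log2FC[i] <- fc
    res$SE[i] <- se
    res$df[i] <- df
    res$p[i] <- p
    res$testable[i] <- TRUE
  }
  res$adj_p[res$testable] <- stats::p.adjust(res$p[res$testable], method = "BH")
  res[order(res$adj_p, res$protein_id), , drop = FALSE]
}

#' Call proteins enriched above the no-APEX control
#'
#' Strict gate on the control contrast: `log2FC > fc_cutoff` and
#' `adj_p < adjp_cutoff` (defaults 3 and 0.05). Untestable proteins are
#' excluded.
#'
#' @param results contrast result from [contrast_test()] for the
#'   APEX-vs-no-APEX comparison.
#' @param fc_cutoff,adjp_cutoff gate thresholds.
#' @return character vector of enriched protein ids, sorted.
#' @export
call_enriched_above_control <- function(results, fc_cutoff = 3,
                                        adjp_cutoff = 0.05) {
  ok <- results$testable &
    !is.na(results$log2FC) & results$log2FC > fc_cutoff &
    !is.na(results$adj_p) & results$adj_p < adjp_cutoff
  sort(results$protein_id[ok])
}

#' Call activity-regulated proteins among the enriched set
#'
#' Applied to the stimulated-vs-silenced (Bic vs TTX) contrast, restricted
#' to proteins already enriched above the negative control. Uses the raw
#' (non-adjusted) p value: direction is `BIC_UP` if `log2FC > fc_cutoff`
#' and `p < p_cutoff`, `TTX_UP` if `log2FC < -fc_cutoff` and `p < p_cutoff`,
#' otherwise `NONE`. All inequalities are strict.
#'
#' @param results Bic-vs-TTX contrast result from [contrast_test()].
#' @param enriched character vector of enriched protein ids
#'   (from [call_enriched_above_control()]).
#' @param fc_cutoff,p_cutoff gate thresholds (defaults 0.5 and 0.05).
#' @return data.frame with `protein_id`, `enriched_above_control` (all TRUE)
#'   and `activity_direction`.
#' @export
call_activity_regulated <- function(results, enriched, fc_cutoff = 0.5,
                                    p_cutoff = 0.05) {
  res <- results[results$protein_id %in% enriched, , drop = FALSE]
  dir <- rep("NONE", nrow(res))
  sig <- res$testable & !is.na(res$p) & res$p < p_cutoff
  dir[sig & res$log2FC > fc_cutoff] <- "BIC_UP"
  dir[sig & res$log2FC < -fc_cutoff] <- "TTX_UP"
  out <- data.frame(protein_id = res$protein_id,
                    enriched_above_control = TRUE,
                    activity_direction = dir,
                    stringsAsFactors = FALSE)
  out[order(out$protein_id), , drop = FALSE]
}

#' Annotation-fraction curve over a ranked protein list
#'
#' For each cutoff N, the fraction of the top-N ranked ids whose annotation
#' contains the query term (e.g. the fraction of the most abundant proteins
#' annotated with the cellular-component term "nucleus"). Ids absent from
#' the annotation count as not containing the term.
#'
#' @param ranked_ids character vector, already ranked (best first).
#' @param annotation two-column data.frame mapping id to term
#'   (columns `id`, `term`); repeated rows allowed.
#' @param term the query term.
#' @param cutoffs integer vector of list-prefix sizes; must not exceed
#'   `length(ranked_ids)`.
#' @return data.frame with columns `cutoff` and `fraction`.
#' @export
term_fraction_curve <- function(ranked_ids, annotation, term, cutoffs) {
  cutoffs <- as.integer(cutoffs)
  if (any(cutoffs < 1L) || any(cutoffs > length(ranked_ids))) {
    stop("cutoffs must lie in [1, length(ranked_ids)]")
  }
  with_term <- unique(annotation$id[annotation$term == term])
  hit <- cumsum(ranked_ids %in% with_term)
  data.frame(cutoff = cutoffs, fraction = hit[cutoffs] / cutoffs)
}

#' Full TMT enrichment workflow
#'
#' Runs normalization, shared-peptide removal, median-polish summarization,
#' the control contrast (all APEX channels vs no-APEX), the enrichment gate,
#' the activity contrast (Bic vs TTX) on the enriched set, and the activity
#' gate.
#'
#' @param rt PSM-level reporter table.
#' @param reference_condition run-normalization anchor condition.
#' @param fc_control,adjp_control enrichment-gate thresholds.
#' @param fc_activity,p_activity activity-gate thresholds.
#' @return list with `abundance`, `control_results`, `activity_results`,
#'   `enriched` (protein ids) and `calls`
#'   (data.frame of [call_activity_regulated()]).
#' @export
tmt_enrich <- function(rt, reference_condition = "APEX_TTX",
                       fc_control = 3, adjp_control = 0.05,
                       fc_activity = 0.5, p_activity = 0.05) {
  rt <- normalize_reference_channels(rt, reference_condition)
  rt <- drop_shared_peptides(rt)
  pam <- summarize_protein_medpolish(rt)
  control <- contrast_test(pam, c("APEX_TTX", "APEX_BIC"), "NO_APEX",
                           label = "APEX vs NO_APEX")
  enriched <- call_enriched_above_control(control, fc_control, adjp_control)
  activity <- contrast_test(pam, "APEX_BIC", "APEX_TTX",
                            label = "APEX_BIC vs APEX_TTX")
  calls <- call_activity_regulated(activity, enriched, fc_activity, p_activity)
  list(abundance = pam, control_results = control,
       activity_results = activity, enriched = enriched, calls = calls)
}
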