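#' Run the end-to-end RNA-seq classification pipeline
#'
#' Differential expression on all four strata, assembly of the stratum
#' fold-change table, the classification cascade, and a report of the
#' per-stage counts. The report enforces the cascade's set-algebra
#' identities (a violation aborts): up + down = activity-dependent, the
#' CHX-insensitive / discordant / not-significant-with-CHX sets partition
#' the activity-dependent set, and putative targets are a subset of the
#' CHX-insensitive set. When planted truth is supplied, recovery metrics
#' for the activity and target calls are added.
#'
#' @param counts gene x sample raw count matrix.
#' @param design sample design sheet.
#' @param config a [target_call_config()].
#' @param truth optional truth table (from [simulate_rnaseq_counts()]).
#' @param out_dir optional directory; when given, the per-stratum DE tables,
#'   the classification table, the target list and the category-fraction
#'   table are written there as TSV with deterministic row order.
#' @return list of class `nucshift_report`: counts per stage, the category
#'   fraction table, recovery metrics (when truth is given), and the full
#'   `classification` and `de` objects.
#' @export
run_pipeline <- function(counts, design, config = target_call_config(),
                         truth = NULL, out_dir = NULL) {
  de <- run_de_all_strata(counts, design)
  tbl <- build_stratum_table(de)
  cls <- classify_genes(tbl, config)
  targets <- call_putative_targets(cls, config)

  n_up <- sum(cls$activity == "UP")
  n_down <- sum(cls$activity == "DOWN")
  n_act <- sum(cls$activity != "NONE")
  n_chx <- sum(cls$chx_insensitive)
  n_disc <- sum(cls$discordant_excluded)
  n_nonsig_chx <- sum(cls$activity != "NONE" & !cls$chx_insensitive &
                        !cls$discordant_excluded)

  stopifnot(n_up + n_down == n_act,
            n_chx + n_disc + n_nonsig_chx == n_act,
            length(targets) <= n_chx)

  report <- list(
    n_genes_classified = nrow(cls),
    n_excluded_untestable = attr(tbl, "n_excluded_untestable"),
    activity_up = n_up,
    activity_down = n_down,
    activity_total = n_act,
    chx_insensitive = n_chx,
    discordant_excluded = n_disc,
    putative_targets = length(targets),
    fractions = attr(cls, "fractions"),
    config = unclass(config)
  )
  if (!is.null(truth)) {
    report$target_recovery <- evaluate_recovery(
      targets, truth, label_col = "pdcd4_dependent")
    act_called <- cls$gene_id[cls$activity != "NONE"]
    report$activity_recovery <- evaluate_recovery(
      act_called, truth, label_col = "class",
      positive = c("activity_up", "activity_down"))
  }
  report$classification <- cls
  report$targets <- targets
  report$de <- de

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in names(de)) {
      write_de_results(de[[s]], file.path(out_dir, paste0("de_", s, ".tsv")))
    }
    write_table(cls[order(cls$gene_id), ],
                file.path(out_dir, "classification.tsv"))
    write_table(data.frame(gene_id = targets),
                file.path(out_dir, "targets.tsv"))
    write_table(report$fractions, file.path(out_dir, "fractions.tsv"))
  }
  structure(report, class = "nucshift_report")
}

#' @export
print.nucshift_report <- function(x, ...) {
  cat("nucshift pipeline report\n")
  cat(sprintf("  genes classified:       %d (untestable excluded: %d)\n",
              x$n_genes_classified, x$n_excluded_untestable))
  cat(sprintf("  activity-dependent:     %d (%d up, %d down)\n",
              x$activity_total, x$activity_up, x$activity_down))
  cat(sprintf("  CHX-insensitive:        %d (discordant excluded: %d)\n",
              x$chx_insensitive, x$discordant_excluded))
  cat(sprintf("  putative PDCD4 targets: %d\n", x$putative_targets))
  if (!is.null(x$target_recovery)) {
    cat(sprintf("  target recovery:        precision %.3f, recall %.3f\n",
                x$target_recovery$precision, x$target_recovery$recall))
  }
  invisible(x)
}
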