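#' @name target_calling
#' @title PDCD4 change-index target calling
#'
#' @description
#' The gene-classification cascade applied downstream of the stratified
#' differential expression: activity-dependent gene sets (significant
#' Bic-vs-TTX change in the WT no-CHX stratum), the cycloheximide(CHX)-
#' insensitive filter (significant, same-direction change in the WT CHX
#' stratum, with discordant genes excluded), the PDCD4 change index
#' `abs(S - W) / abs(W)` comparing the S71A and WT no-CHX fold changes,
#' putative-target calls (index above threshold), categorization of the
#' activity genes by their S71A-stratum behaviour, and hierarchical
#' clustering of fold-change profiles.
NULL

#' Configuration for the target-calling cascade
#'
#' @param alpha significance level for adjusted p values (default 0.05).
#' @param index_threshold change-index cutoff for putative targets
#'   (default 0.75; strict inequality).
#' @return list of class `target_call_config`.
#' @export
target_call_config <- function(alpha = 0.05, index_threshold = 0.75) {
  stopifnot(alpha > 0, alpha < 1, index_threshold > 0)
  structure(list(alpha = alpha, index_threshold = index_threshold),
            class = "target_call_config")
}

#' Assemble the per-gene stratum fold-change table
#'
#' Merges the four stratum DE results into one row per gene with columns
#' `W` (WT no-CHX log2FC), `S` (S71A no-CHX), `W_chx`, `S_chx` and the
#' matching `p_*` / `adj_*` columns. Genes untestable (missing p) in any
#' stratum are excluded from the table; the number excluded is attached as
#' attribute `n_excluded_untestable`.
#'
#' @param de_list named list of the four [nb_wald_stratum()] results
#'   (`W_noCHX`, `S_noCHX`, `W_CHX`, `S_CHX`), as from [run_de_all_strata()].
#' @return data.frame, one row per classifiable gene.
#' @export
build_stratum_table <- function(de_list) {
  need <- c("W_noCHX", "S_noCHX", "W_CHX", "S_CHX")
  if (!all(need %in% names(de_list))) {
    stop("de_list must contain the four strata: ", paste(need, collapse = ", "))
  }
  short <- c(W_noCHX = "W", S_noCHX = "S", W_CHX = "W_chx", S_CHX = "S_chx")
  tbl <- NULL
  for (s in need) {
    de <- de_list[[s]]
    part <- data.frame(gene_id = de$gene_id, stringsAsFactors = FALSE)
    part[[short[[s]]]] <- de$log2FC
    part[[paste0("p_", short[[s]])]] <- de$p
    part[[paste0("adj_", short[[s]])]] <- de$adj_p
    tbl <- if (is.null(tbl)) part else merge(tbl, part, by = "gene_id")
  }
  testable <- stats::complete.cases(
    tbl[, c("p_W", "p_S", "p_W_chx", "p_S_chx")])
  out <- tbl[testable, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_untestable") <- sum(!testable)
  out
}

#' Call activity-dependent genes
#'
#' A gene is activity-dependent UP if its WT no-CHX adjusted p value is
#' below `alpha` and `W > 0`, DOWN if below `alpha` and `W < 0` (strict
#' inequalities). A significant gene with `W == 0` is contradictory input
#' and raises an error.
#'
#' @param tbl stratum table from [build_stratum_table()].
#' @param cfg a [target_call_config()].
#' @return list with character vectors `up` and `down`.
#' @export
call_activity_dependent <- function(tbl, cfg = target_call_config()) {
  sig <- !is.na(tbl$adj_W) & tbl$adj_W < cfg$alpha
  if (any(sig & tbl$W == 0)) {
    stop("gene(s) significant in the WT no-CHX stratum with log2FC exactly 0: ",
         paste(utils::head(tbl$gene_id[sig & tbl$W == 0], 5L), collapse = ", "))
  }
  list(up = tbl$gene_id[sig & tbl$W > 0],
       down = tbl$gene_id[sig & tbl$W < 0])
}

#' Filter activity-dependent genes for CHX insensitivity
#'
#' A gene is kept (CHX-insensitive) if the WT CHX-stratum adjusted p value
#' is below `alpha` and the CHX-stratum fold change has the same sign as
#' the no-CHX fold change. Genes significant in both strata but with
#' opposite signs are returned separately as discordant exclusions.
#'
#' @param tbl stratum table.
#' @param activity_set character vector of activity-dependent gene ids.
#' @param cfg a [target_call_config()].
#' @return list with character vectors `kept` and `discordant`.
#' @export
filter_chx_insensitive <- function(tbl, activity_set,
                                   cfg = target_call_config()) {
  sub <- tbl[tbl$gene_id %in% activity_set, , drop = FALSE]
  sig_chx <- !is.na(sub$adj_W_chx) & sub$adj_W_chx < cfg$alpha
  same_sign <- sign(sub$W_chx) == sign(sub$W)
  list(kept = sub$gene_id[sig_chx & same_sign],
       discordant = sub$gene_id[sig_chx & !same_sign])
}

#' PDCD4 change index
#'
#' `abs(S - W) / abs(W)`, where `W` and `S` are the Bic-vs-TTX log2 fold
#' changes in the PDCD4 WT and S71A no-CHX strata. The index is 0 when the
#' mutant reproduces the WT response, 1 when the response is abolished, and
#' `1 - a` when the response is attenuated by a factor `a`. Undefined for
#' `W == 0`.
#'
#' @param W,S numeric vectors of WT and S71A log2 fold changes.
#' @return nonnegative numeric vector.
#' @export
pdcd4_change_index <- function(W, S) {
  if (any(W == 0)) stop("change index undefined for W == 0")
  abs(S - W) / abs(W)
}

#' Categorize activity genes by their S71A-stratum behaviour
#'
#' Each activity-dependent gene is labelled by its S71A no-CHX result:
#' `UP` if the adjusted p value is below `alpha` and `S > 0`, `DOWN` if
#' below `alpha` and `S < 0`, otherwise `NONE` (no significant
#' activity-dependent change in the mutant). The fraction table reports,
#' per activity direction, the percentage of genes in each category,
#' rounded to the nearest integer (half away from zero).
#'
#' @param tbl stratum table.
#' @param activity_up,activity_down character vectors of activity gene ids.
#' @param cfg a [target_call_config()].
#' @return list with `categories` (data.frame `gene_id`, `direction`,
#'   `s71a_category`) and `fractions` (data.frame `direction`,
#'   `s71a_category`, `n`, `pct`).
#' @export
categorize_s71a <- function(tbl, activity_up, activity_down,
                            cfg = target_call_config()) {
  genes <- c(activity_up, activity_down)
  direction <- rep(c("UP", "DOWN"),
                   c(length(activity_up), length(activity_down)))
  idx <- match(genes, tbl$gene_id)
  if (anyNA(idx)) stop("activity gene(s) missing from the stratum table")
  sig <- !is.na(tbl$adj_S[idx]) & tbl$adj_S[idx] < cfg$alpha
  cat <- rep("NONE", length(genes))
  cat[sig & tbl$S[idx] > 0] <- "UP"
  cat[sig & tbl$S[idx] < 0] <- "DOWN"
  categories <- data.frame(gene_id = genes, direction = direction,
                           s71a_category = cat, stringsAsFactors = FALSE)
  fr <- NULL
  for (d in c("UP", "DOWN")) {
    n_dir <- sum(direction == d)
    if (n_dir == 0L) next
    for (k in c("UP", "NONE", "DOWN")) {
      n <- sum(direction == d & cat == k)
      fr <- rbind(fr, data.frame(direction = d, s71a_category = k, n = n,
                                 pct = round_half_away(100 * n / n_dir),
                                 stringsAsFactors = FALSE))
    }
  }
  if (is.null(fr)) {
    fr <- data.frame(direction = character(0), s71a_category = character(0),
                     n = integer(0), pct = numeric(0))
  }
  list(categories = categories, fractions = fr)
}

# round to nearest integer, halves away from zero (not banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Run the full classification cascade
#'
#' Combines [call_activity_dependent()], [filter_chx_insensitive()],
#' [pdcd4_change_index()] and the putative-target cutoff into one per-gene
#' classification table satisfying the cascade's set identities:
#' a putative target is CHX-insensitive and activity-dependent; the change
#' index is present exactly for the CHX-insensitive genes; discordant
#' exclusion implies not CHX-insensitive.
#'
#' @param tbl stratum table from [build_stratum_table()].
#' @param cfg a [target_call_config()].
#' @return data.frame with one row per gene: `gene_id`, `activity`
#'   (`UP`/`DOWN`/`NONE`), `chx_insensitive`, `discordant_excluded`,
#'   `change_index`, `putative_target`, `s71a_category`.
#' @export
classify_genes <- function(tbl, cfg = target_call_config()) {
  act <- call_activity_dependent(tbl, cfg)
  chx <- filter_chx_insensitive(tbl, c(act$up, act$down), cfg)
  s71a <- categorize_s71a(tbl, act$up, act$down, cfg)

  out <- data.frame(gene_id = tbl$gene_id,
                    activity = "NONE",
                    chx_insensitive = FALSE,
                    discordant_excluded = FALSE,
                    change_index = NA_real_,
                    putative_target = FALSE,
                    s71a_category = NA_character_,
                    stringsAsFactors = FALSE)
  out$activity[out$gene_id %in% act$up] <- "UP"
  out$activity[out$gene_id %in% act$down] <- "DOWN"
  out$chx_insensitive <- out$gene_id %in% chx$kept
  out$discordant_excluded <- out$gene_id %in% chx$discordant
  ci <- out$chx_insensitive
  out$change_index[ci] <- pdcd4_change_index(tbl$W[ci], tbl$S[ci])
  out$putative_target <- ci & !is.na(out$change_index) &
    out$change_index > cfg$index_threshold
  out$s71a_category[match(s71a$categories$gene_id, out$gene_id)] <-
    s71a$categories$s71a_category

  # cascade identities are structural; violation is a defect, not a warning
  stopifnot(all(!out$putative_target | (out$chx_insensitive & out$activity != "NONE")),
            all(!out$discordant_excluded | !out$chx_insensitive),
            all(is.na(out$change_index) == !out$chx_insensitive))
  attr(out, "fractions") <- s71a$fractions
  out
}

#' Putative PDCD4 target genes
#'
#' CHX-insensitive activity-dependent genes whose change index strictly
#' exceeds the threshold.
#'
#' @param classification result of [classify_genes()].
#' @param cfg a [target_call_config()].
#' @return sorted character vector of gene ids.
#' @export
call_putative_targets <- function(classification, cfg = target_call_config()) {
  ok <- classification$chx_insensitive &
    !is.na(classification$change_index) &
    classification$change_index > cfg$index_threshold
  sort(classification$gene_id[ok])
}

#' Cluster genes by their fold-change profiles
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) of the gene x stratum log2 fold-change matrix, as used to order
#' the rows of fold-change heatmaps. Rows are pre-sorted by gene id so the
#' leaf order is deterministic; with fewer than two rows the identity
#' ordering is returned.
#'
#' @param fc_matrix numeric matrix (genes in rows, named) without missing
#'   values.
#' @param method linkage method passed to [stats::hclust()].
#' @return list with `order` (gene ids in leaf order) and `hclust` (the
#'   clustering object, or `NULL` for degenerate input).
#' @export
cluster_fc_profiles <- function(fc_matrix, method = "average") {
  fc_matrix <- as.matrix(fc_matrix)
  if (anyNA(fc_matrix)) stop("fold-change matrix must not contain missing values")
  if (is.null(rownames(fc_matrix))) {
    rownames(fc_matrix) <- sprintf("row%05d", seq_len(nrow(fc_matrix)))
  }
  fc_matrix <- fc_matrix[order(rownames(fc_matrix)), , drop = FALSE]
  if (nrow(fc_matrix) < 2L) {
    return(list(order = rownames(fc_matrix), hclust = NULL))
  }
  hc <- stats::hclust(stats::dist(fc_matrix), method = method)
  list(order = rownames(fc_matrix)[hc$order], hclust = hc)
}
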