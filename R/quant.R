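#' @name quant_stats
#' @title Auxiliary quantification statistics
#'
#' @description
#' The small exact-arithmetic statistics that accompany the imaging, Western
#' blot and qPCR experiments: normalization of per-cell intensities to the
#' control-condition median, normalization to a cotransfection marker,
#' Western band ratios to a loading control and basal sample, qPCR relative
#' expression by the efficiency-power-delta-Ct method with geometric-mean
#' housekeeping normalization, and the two-sided Mann-Whitney U test with
#' Bonferroni correction for planned comparisons.
NULL

#' Normalize values to the control-condition median
#'
#' Every value is divided by the median of the control values, so the
#' normalized control median is exactly 1.
#'
#' @param values numeric vector to normalize.
#' @param control_values numeric vector of control-condition values.
#' @return normalized numeric vector.
#' @export
normalize_to_control_median <- function(values, control_values) {
  if (!length(control_values)) stop("control group is empty")
  m <- stats::median(control_values)
  if (!is.finite(m) || m <= 0) stop("control median must be positive")
  values / m
}

#' Normalize a per-cell measurement table within replicates
#'
#' Applies [normalize_to_control_median()] separately within each
#' experimental replicate, using that replicate's control-condition cells,
#' before the replicates are pooled.
#'
#' @param cells data.frame with columns `cell_id`, `replicate`, `condition`,
#'   `mean_intensity` (and optionally `compartment`, `marker_intensity`).
#' @param control_condition label of the control condition (e.g. "basal").
#' @return `cells` with an added `normalized_intensity` column.
#' @export
normalize_cells <- function(cells, control_condition = "basal") {
  need <- c("cell_id", "replicate", "condition", "mean_intensity")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cells$normalized_intensity <- NA_real_
  for (r in unique(cells$replicate)) {
    in_rep <- cells$replicate == r
    ctrl <- cells$mean_intensity[in_rep & cells$condition == control_condition]
    if (!length(ctrl)) {
      stop("replicate '", r, "' has no cells in control condition '",
           control_condition, "'")
    }
    cells$normalized_intensity[in_rep] <-
      normalize_to_control_median(cells$mean_intensity[in_rep], ctrl)
  }
  cells
}

#' Normalize per-cell values to a cotransfection marker
#'
#' Elementwise ratio of the measured intensity to the marker intensity
#' (e.g. nuclear GFP), correcting for transfection-efficiency differences
#' between cells. Cells with missing or non-positive marker are excluded
#' with a warning.
#'
#' @param values numeric vector of measured intensities.
#' @param marker_values numeric vector of marker intensities, same length.
#' @return numeric vector of ratios, `NA` for excluded cells.
#' @export
normalize_to_marker <- function(values, marker_values) {
  stopifnot(length(values) == length(marker_values))
  bad <- is.na(marker_values) | marker_values <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) excluded: missing or non-positive marker")
  }
  out <- values / marker_values
  out[bad] <- NA_real_
  out
}

#' Western band ratio to loading control and basal sample
#'
#' `(band / loading_band) / basal_ratio`: the band intensity is first
#' normalized to the loading-control band, then to the basal sample's
#' loading-normalized ratio within the same experiment. The basal sample
#' itself maps to exactly 1.
#'
#' @param band,loading_band numeric band intensities.
#' @param basal_ratio the basal sample's `band / loading_band` ratio.
#' @return numeric normalized ratios.
#' @export
ratio_to_loading_control <- function(band, loading_band, basal_ratio) {
  if (any(loading_band <= 0) || any(basal_ratio <= 0)) {
    stop("loading_band and basal_ratio must be positive")
  }
  (band / loading_band) / basal_ratio
}

#' qPCR relative expression with housekeeping normalization
#'
#' Relative quantity per (sample, gene) is `E^dCt` with
#' `dCt = Ct(calibrator) - Ct(sample)` (so higher expression gives a larger
#' quantity; set `delta_ct = "sample_minus_calibrator"` to flip). Relative
#' expression of a target gene in a sample is its relative quantity divided
#' by the geometric mean of the housekeeping genes' relative quantities in
#' that sample; the calibrator sample therefore maps to exactly 1.
#' Technical replicates (repeated (sample, gene) rows) are collapsed by
#' mean Ct before the calculation.
#'
#' @param records data.frame with columns `sample`, `gene`, `role`
#'   (`TARGET` or `HOUSEKEEPING`), `Ct`, `efficiency`.
#' @param calibrator name of the calibrator sample.
#' @param delta_ct Ct-difference convention.
#' @return data.frame with `sample`, `gene`, `relative_expression` for every
#'   target gene in every sample.
#' @export
qpcr_relative_expression <- function(records, calibrator,
                                     delta_ct = c("calibrator_minus_sample",
                                                  "sample_minus_calibrator")) {
  delta_ct <- match.arg(delta_ct)
  need <- c("sample", "gene", "role", "Ct", "efficiency")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(records$role %in% c("TARGET", "HOUSEKEEPING"))) {
    stop("role must be TARGET or HOUSEKEEPING")
  }
  if (any(records$efficiency <= 1 | records$efficiency > 2.2)) {
    stop("amplification efficiency must lie in (1, 2.2]")
  }
  if (any(records$Ct <= 0)) stop("Ct values must be positive")

  # collapse technical replicates: mean Ct per (sample, gene)
  agg <- stats::aggregate(Ct ~ sample + gene, data = records, FUN = mean)
  meta <- unique(records[, c("gene", "role", "efficiency")])
  if (anyDuplicated(meta$gene)) {
    stop("a gene must have a single role and efficiency")
  }
  agg <- merge(agg, meta, by = "gene")
  if (!calibrator %in% agg$sample) stop("calibrator sample not found")

  cal_ct <- agg$Ct[agg$sample == calibrator]
  names(cal_ct) <- agg$gene[agg$sample == calibrator]
  if (!all(agg$gene %in% names(cal_ct))) {
    stop("calibrator sample lacks measurements for gene(s): ",
         paste(setdiff(unique(agg$gene), names(cal_ct)), collapse = ", "))
  }
  dct <- cal_ct[agg$gene] - agg$Ct
  if (delta_ct == "sample_minus_calibrator") dct <- -dct
  agg$rq <- agg$efficiency^dct

  hk_genes <- unique(agg$gene[agg$role == "HOUSEKEEPING"])
  if (!length(hk_genes)) stop("at least one housekeeping gene is required")
  targets <- agg[agg$role == "TARGET", , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(targets))) {
    s <- targets$sample[i]
    hk <- agg$rq[agg$sample == s & agg$gene %in% hk_genes]
    if (length(hk) != length(hk_genes)) {
      stop("sample '", s, "' is missing a housekeeping measurement")
    }
    out <- rbind(out, data.frame(
      sample = s, gene = targets$gene[i],
      relative_expression = targets$rq[i] / exp(mean(log(hk))),
      stringsAsFactors = FALSE))
  }
  out[order(out$gene, out$sample), , drop = FALSE]
}

#' Two-sided Mann-Whitney U test
#'
#' The U statistic counts pairs where a value of `a` exceeds a value of `b`
#' (ties count one half). The two-sided p value uses the exact null
#' distribution when both groups have at most `exact_max` observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b numeric vectors (each nonempty).
#' @param exact_max largest group size for the exact branch (default 8).
#' @return list with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mwu_test <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  n1 <- length(a); n2 <- length(b)
  comb <- c(a, b)
  rk <- rank(comb)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(comb) > 0L
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p_low <- stats::pwilcox(U, n1, n2)
    p_high <- 1 - if (U >= 1) stats::pwilcox(U - 1, n1, n2) else 0
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    n <- n1 + n2
    tie_counts <- table(comb)
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Mann-Whitney U tests with Bonferroni correction
#'
#' Runs [mwu_test()] for each planned comparison and multiplies each raw p
#' value by the number of planned comparisons (capped at 1).
#'
#' @param groups named list of numeric vectors.
#' @param comparisons list of length-2 character vectors, or strings
#'   `"groupA:groupB"`, naming the planned comparisons.
#' @return data.frame with `comparison`, `U`, `p`, `bonferroni_p`,
#'   `median_a`, `median_b`, `n_a`, `n_b`, `method`.
#' @export
mwu_bonferroni <- function(groups, comparisons) {
  if (is.character(comparisons)) comparisons <- as.list(comparisons)
  comparisons <- lapply(comparisons, function(cp) {
    if (length(cp) == 1L) strsplit(cp, ":", fixed = TRUE)[[1L]] else cp
  })
  k <- length(comparisons)
  if (!k) stop("no planned comparisons")
  out <- NULL
  for (cp in comparisons) {
    if (length(cp) != 2L || !all(cp %in% names(groups))) {
      stop("each comparison must name two groups present in `groups`")
    }
    a <- groups[[cp[1L]]]; b <- groups[[cp[2L]]]
    t <- mwu_test(a, b)
    out <- rbind(out, data.frame(
      comparison = paste(cp, collapse = " vs "),
      U = t$U, p = t$p, bonferroni_p = min(1, k * t$p),
      median_a = stats::median(a), median_b = stats::median(b),
      n_a = length(a), n_b = length(b), method = t$method,
      stringsAsFactors = FALSE))
  }
  out
}
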