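#' @name rnaseq_de
#' @title Stratified negative-binomial differential expression
#'
#' @description
#' Bic-vs-TTX differential expression within each of the four sample-type
#' strata of the design (PDCD4 WT / S71A, with / without cycloheximide),
#' with replicate-batch correction. Per gene, a negative-binomial log-link
#' regression with a size-factor offset and additive batch + treatment terms
#' is fit by iteratively reweighted least squares, and the treatment
#' coefficient is tested with a Wald test. Size factors use the
#' median-of-ratios estimator; dispersions use a method-of-moments estimate
#' on normalized counts. Each stratum is fit and BH-adjusted independently.
NULL

.strata <- c("W_noCHX", "S_noCHX", "W_CHX", "S_CHX")

#' Validate a sample design sheet
#'
#' @param design data.frame with columns `sample_id`, `genotype`
#'   (`WT`/`S71A`), `treatment` (`TTX`/`BIC`), `chx` (logical), `batch`.
#' @return `design`, invisibly.
#' @export
validate_sample_design <- function(design) {
  need <- c("sample_id", "genotype", "treatment", "chx", "batch")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("sample design is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (!all(design$genotype %in% c("WT", "S71A"))) {
    stop("genotype must be WT or S71A")
  }
  if (!all(design$treatment %in% c("TTX", "BIC"))) {
    stop("treatment must be TTX or BIC")
  }
  if (!is.logical(design$chx)) stop("chx must be logical")
  invisible(design)
}

#' Select the samples belonging to a stratum
#'
#' Strata are the four genotype x cycloheximide sample types:
#' `W_noCHX` (WT, no CHX), `S_noCHX` (S71A, no CHX), `W_CHX` (WT, CHX),
#' `S_CHX` (S71A, CHX).
#'
#' @param design sample design sheet.
#' @param stratum one of `"W_noCHX"`, `"S_noCHX"`, `"W_CHX"`, `"S_CHX"`.
#' @return character vector of sample ids.
#' @export
stratum_samples <- function(design, stratum) {
  stratum <- match.arg(stratum, .strata)
  genotype <- if (startsWith(stratum, "W")) "WT" else "S71A"
  chx <- endsWith(stratum, "_CHX")
  design$sample_id[design$genotype == genotype & design$chx == chx]
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors estimated as the median, across reference
#' genes, of the ratio of the sample's count to the per-gene geometric mean.
#' Genes containing any zero (or missing) count are excluded from the
#' reference set.
#'
#' @param counts gene x sample matrix of raw nonnegative integer counts.
#' @return named numeric vector of strictly positive size factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  ref <- rowSums(is.na(counts) | counts == 0) == 0L
  if (!any(ref)) stop("no gene with all-positive counts; cannot estimate size factors")
  lc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- apply(lc, 2L, function(col) exp(stats::median(col - loggeo)))
  if (any(sf <= 0)) stop("non-positive size factor estimated")
  sf
}

#' Method-of-moments dispersion estimates
#'
#' Per-gene negative-binomial dispersion (`Var = mu + alpha * mu^2`)
#' estimated from factor-normalized counts, pooling the within-group moment
#' equations over the condition groups:
#' `alpha = sum_g (n_g - 1)(s2_g - m_g) / sum_g (n_g - 1) m_g^2`,
#' floored at `1e-8`.
#'
#' @param counts gene x sample count matrix (raw counts).
#' @param factors per-sample size factors (same order as columns).
#' @param groups factor or vector of condition-group labels per sample.
#' @param floor lower bound for the estimate.
#' @return named numeric vector of dispersions, one per gene, with attribute
#'   `df` (the pooled moment degrees of freedom, `sum(n_g - 1)`) used
#'   downstream as the reference-distribution df of the Wald test.
#' @export
estimate_dispersions <- function(counts, factors, groups, floor = 1e-8) {
  counts <- as.matrix(counts)
  stopifnot(length(factors) == ncol(counts), length(groups) == ncol(counts))
  y <- sweep(counts, 2L, factors, "/")
  groups <- as.factor(groups)
  num <- rep(0, nrow(counts))
  den <- rep(0, nrow(counts))
  for (g in levels(groups)) {
    cols <- which(groups == g)
    n <- length(cols)
    if (n < 2L) next
    yg <- y[, cols, drop = FALSE]
    m <- rowMeans(yg)
    v <- rowSums((yg - m)^2) / (n - 1)
    num <- num + (n - 1) * (v - m)
    den <- den + (n - 1) * m^2
  }
  alpha <- ifelse(den > 0, num / den, floor)
  alpha <- pmax(alpha, floor)
  names(alpha) <- rownames(counts)
  attr(alpha, "df") <- sum(pmax(table(groups) - 1L, 0L))
  alpha
}

# One negative-binomial IRLS fit with log link, fixed dispersion and offset.
# Returns coef, se of the last coefficient, and convergence flag.
nb_irls <- function(y, X, offset, alpha, tol = 1e-8, max_iter = 100L) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtwx <- crossprod(X, X * w)
    ch <- tryCatch(chol(xtwx), error = function(e) NULL)
    if (is.null(ch)) return(list(converged = FALSE))
    beta_new <- backsolve(ch, forwardsolve(t(ch), crossprod(X * w, z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      eta <- pmin(drop(X %*% beta) + offset, 30)
      break
    }
    beta <- beta_new
    eta <- pmin(drop(X %*% beta) + offset, 30)
  }
  if (!converged) return(list(converged = FALSE))
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  cov <- chol2inv(chol(crossprod(X, X * w)))
  list(converged = TRUE, beta = drop(beta), se = sqrt(diag(cov)))
}

#' Negative-binomial Wald differential expression within one stratum
#'
#' Per gene, fits `log mu = log(size factor) + batch + treatment` by IRLS
#' (convergence tolerance `1e-8`, at most 100 iterations) with the gene's
#' dispersion held fixed, and Wald-tests the treatment (Bic vs TTX)
#' coefficient. When the dispersions carry a `df` attribute (the pooled
#' moment degrees of freedom from [estimate_dispersions()]), the Wald
#' statistic is referred to a t distribution with that many df, which keeps
#' the test at its nominal level despite the plug-in dispersion; externally
#' supplied dispersions without a `df` attribute are treated as known and
#' referred to the normal. p values are BH-adjusted across all genes with nonzero
#' counts in the stratum; all-zero genes are reported with `log2FC = 0` and
#' missing p, and non-convergent fits are flagged and excluded from the
#' adjustment denominator.
#'
#' @param counts gene x sample raw count matrix (all samples; the stratum
#'   columns are selected internally).
#' @param design sample design sheet covering the columns of `counts`.
#' @param stratum stratum name (see [stratum_samples()]).
#' @param factors optional per-sample size factors for the stratum samples;
#'   estimated from the stratum submatrix when `NULL`.
#' @param dispersions optional per-gene dispersions (e.g. externally
#'   computed). When `NULL`, [estimate_dispersions()] is run on the full
#'   count matrix with the design's genotype x treatment x CHX cells as the
#'   condition groups, pooling the moment equations over all groups: the
#'   dispersion describes the measurement, not the contrast, and the pooled
#'   estimate carries far more degrees of freedom than the 3-vs-3 stratum
#'   alone, which keeps the plug-in Wald test close to its nominal level.
#' @return data.frame with columns `gene_id`, `stratum`, `base_mean`,
#'   `log2FC`, `SE`, `wald_stat`, `p`, `adj_p`, `converged`, in input gene
#'   order. Use [write_de_results()] for the deterministically sorted
#'   on-disk form.
#' @export
nb_wald_stratum <- function(counts, design, stratum, factors = NULL,
                            dispersions = NULL) {
  validate_sample_design(design)
  counts <- as.matrix(counts)
  ids <- stratum_samples(design, stratum)
  if (!all(ids %in% colnames(counts))) {
    stop("stratum samples missing from the count matrix")
  }
  sub <- counts[, ids, drop = FALSE]
  d <- design[match(ids, design$sample_id), , drop = FALSE]
  for (tr in c("TTX", "BIC")) {
    if (length(unique(d$batch[d$treatment == tr])) < 2L) {
      stop("stratum ", stratum, " needs treatment ", tr,
           " in at least 2 batches")
    }
  }
  if (is.null(factors)) factors <- size_factors_median_of_ratios(sub)
  if (is.null(dispersions)) {
    all_in <- all(design$sample_id %in% colnames(counts))
    full <- if (all_in) counts[, design$sample_id, drop = FALSE] else sub
    dd <- if (all_in) design else d
    groups <- interaction(dd$genotype, dd$treatment, dd$chx, drop = TRUE)
    dispersions <- estimate_dispersions(
      full, size_factors_median_of_ratios(full), groups)
  }
  trt <- factor(d$treatment, levels = c("TTX", "BIC"))
  batch <- factor(d$batch)
  X <- if (nlevels(batch) > 1L) {
    stats::model.matrix(~ batch + trt)
  } else {
    stats::model.matrix(~ trt)
  }
  offset <- log(factors)
  norm_counts <- sweep(sub, 2L, factors, "/")

  n_genes <- nrow(sub)
  res <- data.frame(
    gene_id = rownames(sub),
    stratum = stratum,
    base_mean = rowMeans(norm_counts),
    log2FC = 0, SE = NA_real_, wald_stat = NA_real_,
    p = NA_real_, adj_p = NA_real_, converged = NA,
    stringsAsFactors = FALSE
  )
  coef_idx <- ncol(X)
  wald_df <- attr(dispersions, "df")
  if (is.null(wald_df)) wald_df <- Inf
  for (i in seq_len(n_genes)) {
    y <- sub[i, ]
    if (all(y == 0)) next  # all-zero gene: log2FC 0, p missing
    fit <- nb_irls(y, X, offset, dispersions[i])
    res$converged[i] <- fit$converged
    if (!fit$converged) next
    b <- fit$beta[coef_idx]
    se <- fit$se[coef_idx]
    res$log2FC[i] <- b / log(2)
    res$SE[i] <- se / log(2)
    res$wald_stat[i] <- b / se
    res$p[i] <- 2 * stats::pt(-abs(b / se), df = wald_df)
  }
  tested <- !is.na(res$p)
  res$adj_p[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res
}

#' Run differential expression on all four strata
#'
#' @param counts gene x sample raw count matrix.
#' @param design sample design sheet.
#' @param dispersions optional per-gene dispersions reused for every stratum.
#' @return named list of four [nb_wald_stratum()] results
#'   (`W_noCHX`, `S_noCHX`, `W_CHX`, `S_CHX`).
#' @export
run_de_all_strata <- function(counts, design, dispersions = NULL) {
  if (is.null(dispersions)) {
    validate_sample_design(design)
    counts <- as.matrix(counts)
    full <- counts[, design$sample_id, drop = FALSE]
    groups <- interaction(design$genotype, design$treatment, design$chx,
                          drop = TRUE)
    dispersions <- estimate_dispersions(
      full, size_factors_median_of_ratios(full), groups)
  }
  out <- lapply(.strata, function(s) {
    nb_wald_stratum(counts, design, s, dispersions = dispersions)
  })
  names(out) <- .strata
  out
}

#' Write a DE result table with deterministic ordering
#'
#' Rows are ordered by `adj_p` then `gene_id` (missing `adj_p` last).
#'
#' @param res result of [nb_wald_stratum()].
#' @param path output TSV path.
#' @return the sorted data.frame, invisibly.
#' @export
write_de_results <- function(res, path) {
  res <- res[order(res$adj_p, res$gene_id), , drop = FALSE]
  write_table(res, path)
  invisible(res)
}
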