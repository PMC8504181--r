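#' Two-way median polish
#'
#' Fits the additive model `x[i, j] = overall + row[i] + col[j] + residual`
#' by Tukey's median polish: alternately sweep row and column medians out of
#' the table until the sweeps become negligible. Missing entries are
#' tolerated; medians are taken over the observed values only.
#'
#' The sweep order (rows first, then columns, redistributing the median of
#' the accumulated effects into the overall term after each sweep) follows
#' the classical algorithm, so results are directly comparable with other
#' median-polish implementations run to the same tolerance.
#'
#' @param x numeric matrix, possibly containing `NA`.
#' @param tol convergence tolerance on the largest absolute median swept in
#'   one full iteration.
#' @param max_iter maximum number of full row+column iterations.
#' @return list with components `overall` (scalar), `row` and `col` (effect
#'   vectors), `residuals` (matrix), `converged` (logical) and `iterations`.
#' @examples
#' mp <- median_polish(outer(1:4, c(0, 2, 5), "+"))
#' mp$overall + mp$col  # column profile
#' @export
median_polish <- function(x, tol = 1e-10, max_iter = 100L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be a numeric matrix")
  if (all(is.na(x))) stop("`x` has no observed values")
  z <- x
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  overall <- 0
  converged <- FALSE
  iter <- 0L
  med0 <- function(v) {
    m <- stats::median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }
  for (iter in seq_len(max_iter)) {
    rdelta <- apply(z, 1L, med0)
    z <- z - rdelta
    row_eff <- row_eff + rdelta
    delta <- med0(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta

    cdelta <- apply(z, 2L, med0)
    z <- sweep(z, 2L, cdelta)
    col_eff <- col_eff + cdelta
    delta <- med0(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta

    if (max(abs(c(rdelta, cdelta))) < tol) {
      converged <- TRUE
      break
    }
  }
  # columns with no observed data carry no information: effect is undefined
  col_eff[colSums(!is.na(x)) == 0L] <- NA_real_
  list(overall = overall, row = row_eff, col = col_eff,
       residuals = z, converged = converged, iterations = iter)
}
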