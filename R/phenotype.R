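#' Per-voxel slopes of longitudinal change
#'
#' For every subject and voxel, fits by ordinary least squares a line with
#' intercept of voxel value against follow-up time and returns the slope.
#' Values are change relative to baseline; slopes are in value units per unit
#' time (per month when `times` is in months — see [slope_report_units()] for
#' the reporting convention).
#'
#' @param values N x Q x T numeric array: subjects x voxels x timepoints.
#' @param times length-T numeric vector of follow-up times, strictly
#'   increasing (e.g. `c(6, 12, 24)` months).
#' @return An N x Q matrix of slopes.
#' @export
fit_voxel_slopes <- function(values, times) {
  d <- dim(values)
  if (length(d) != 3) stop("`values` must be an N x Q x T array.")
  if (length(times) != d[3]) stop("`times` must have one entry per timepoint.")
  if (d[3] < 2) stop("At least two timepoints are required to fit a slope.")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing.")
  ct <- times - mean(times)
  denom <- sum(ct^2)
  if (denom == 0) stop("singular design: timepoints are constant.")
  slopes <- matrix(0, d[1], d[2])
  for (t in seq_len(d[3])) slopes <- slopes + values[, , t] * ct[t]
  slopes / denom
}

#' Convert per-month slopes to reporting units
#'
#' Reporting convention for percent-change values measured at monthly visits:
#' slopes are displayed as 10 x percent volume change per year, so a
#' per-month slope of 0.1 (0.1 %/month = 1.2 %/year) is reported as 12.
#'
#' @param slopes per-month slopes of percent change.
#' @return Slopes scaled by 120.
#' @export
slope_report_units <- function(slopes) slopes * 120

#' ANCOVA screening of voxels for diagnosis effect
#'
#' Per voxel, tests the diagnosis term in the linear model
#' `slope ~ diagnosis + age + sex` with a partial F-test (full model against
#' the age+sex+intercept reduced model), and selects voxels whose p-value
#' falls strictly below the Bonferroni threshold `alpha / Q*`, where `Q*` is
#' the number of voxels tested.
#'
#' @param slopes N x Q* slope matrix from [fit_voxel_slopes()].
#' @param covariates tibble with columns `age`, `sex`, `diagnosis`
#'   (rows aligned with `slopes`).
#' @param alpha family-wise significance level (default 0.05).
#' @return An object of class `voxel_selection`: list with `p_values`,
#'   `f_statistics`, `alpha`, `q_star`, `threshold`, `mask`, `n_selected`.
#' @export
ancova_screen <- function(slopes, covariates, alpha = 0.05) {
  slopes <- as.matrix(slopes)
  n <- nrow(slopes)
  if (nrow(covariates) != n) {
    stop("`covariates` must have one row per slope-matrix row.")
  }
  diag_ind <- as.numeric(covariates$diagnosis == "AD")
  if (length(unique(diag_ind)) < 2) {
    stop("Both diagnosis groups (AD and CN) must be present.")
  }
  x_red <- cbind(1, covariates$age, covariates$sex)
  x_full <- cbind(x_red, diag_ind)
  qr_red <- qr(x_red)
  qr_full <- qr(x_full)
  df_full <- n - qr_full$rank
  df_num <- qr_full$rank - qr_red$rank
  if (df_num < 1) stop("Diagnosis is collinear with the covariates.")
  rss_red <- colSums(qr.resid(qr_red, slopes)^2)
  rss_full <- colSums(qr.resid(qr_full, slopes)^2)
  f_stat <- ((rss_red - rss_full) / df_num) / (rss_full / df_full)
  p <- pf(f_stat, df_num, df_full, lower.tail = FALSE)
  q_star <- ncol(slopes)
  threshold <- alpha / q_star
  mask <- p < threshold
  structure(
    list(
      p_values = p, f_statistics = f_stat, alpha = alpha, q_star = q_star,
      threshold = threshold, mask = mask, n_selected = sum(mask)
    ),
    class = "voxel_selection"
  )
}

#' @export
print.voxel_selection <- function(x, ...) {
  cat(sprintf(
    "<voxel_selection> %d / %d voxels below alpha/Q* = %.3g (-log10 = %.1f)\n",
    x$n_selected, x$q_star, x$threshold, -log10(x$threshold)
  ))
  invisible(x)
}

#' Residualise selected voxel slopes on age and sex
#'
#' For each selected voxel, replaces slopes by the residuals of an OLS
#' regression on intercept, age and sex. The intercept makes every column of
#' the result mean-centred, and residuals are orthogonal to both covariates.
#'
#' @param slopes N x Q* slope matrix.
#' @param selection a [ancova_screen()] result, or a logical/integer voxel
#'   mask.
#' @param covariates tibble with columns `age`, `sex`, rows aligned with
#'   `slopes`.
#' @return N x Q matrix of residualised slopes (the multivariate phenotype
#'   `Y`), with attribute `selected_voxels` giving the original column
#'   indices.
#' @export
residualize_slopes <- function(slopes, selection, covariates) {
  slopes <- as.matrix(slopes)
  mask <- if (inherits(selection, "voxel_selection")) selection$mask else selection
  cols <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (!length(cols)) stop("No voxels selected; nothing to residualise.")
  z <- cbind(1, covariates$age, covariates$sex)
  qz <- qr(z)
  if (qz$rank < ncol(z)) stop("Covariate design (intercept, age, sex) is rank deficient.")
  y <- qr.resid(qz, slopes[, cols, drop = FALSE])
  attr(y, "selected_voxels") <- cols
  y
}
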