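# Reporting statistics: Spearman rank correlation between measured and
# ECD-calculated totals, one-sample t-test of the per-reconstruction VSSA
# values against the 60 m^2/cm^3 nanostructure threshold, and mean +/- SEM
# summaries.

#' Spearman rank-order correlation coefficient
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal lengths")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

#' One-sample t-test
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with a two-sided p-value from the t
#' distribution with `n - 1` degrees of freedom.
#'
#' @param values numeric vector, n >= 2, nonzero sample sd.
#' @param mu0 null-hypothesis mean.
#' @return `list(t, p)`.
#' @export
one_sample_t <- function(values, mu0) {
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  s <- sd(values)
  if (s == 0) stop("zero sample standard deviation")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector, n >= 2.
#' @return `list(mean, sem)` with `sem = sd / sqrt(n)` (n-1 denominator sd).
#' @export
mean_sem <- function(values) {
  if (length(values) < 2) stop("need at least 2 observations")
  list(mean = mean(values), sem = sd(values) / sqrt(length(values)))
}

#' Assemble a material summary report
#'
#' Summarizes per-reconstruction VSSA values (mean +/- SEM, one-sample
#' t-test against the 60 m^2/cm^3 threshold, nanostructure classification)
#' and, when measured and ECD-calculated totals are present, the Spearman
#' correlations validating the tomographic measurements (per-reconstruction
#' totals, matching reconstructions of one to several particles each).
#' Statistics that cannot be computed (n too small, zero variance) are
#' omitted with the reason recorded in `notes`.
#'
#' @param metrics data frame with one row per reconstruction; column `vssa`
#'   required, columns `measured_area`, `measured_volume`, `calc_area`,
#'   `calc_volume` optional.
#' @param material material name.
#' @param alpha significance level (default 0.05, two-sided).
#' @return An object of class `material_summary`.
#' @export
build_report <- function(metrics, material = "material", alpha = 0.05) {
  stopifnot(is.data.frame(metrics), "vssa" %in% names(metrics))
  vssa <- metrics$vssa
  n <- length(vssa)
  notes <- character(0)
  mean_v <- mean(vssa)
  sem_v <- if (n >= 2) sd(vssa) / sqrt(n) else NA_real_
  t_stat <- p_value <- NA_real_
  if (n < 2) {
    notes <- c(notes, "t-test omitted: fewer than 2 reconstructions")
  } else if (sd(vssa) == 0) {
    notes <- c(notes, "t-test omitted: zero variance in VSSA values")
  } else {
    tt <- one_sample_t(vssa, VSSA_THRESHOLD)
    t_stat <- tt$t
    p_value <- tt$p
  }
  rho_area <- rho_volume <- NA_real_
  has_valid <- all(c("measured_area", "measured_volume",
                     "calc_area", "calc_volume") %in% names(metrics))
  if (!has_valid) {
    notes <- c(notes, "validation correlations omitted: no ECD-calculated totals")
  } else if (n < 3) {
    notes <- c(notes, "validation correlations omitted: fewer than 3 reconstructions")
  } else {
    rho_area <- spearman_rho(metrics$measured_area, metrics$calc_area)
    rho_volume <- spearman_rho(metrics$measured_volume, metrics$calc_volume)
  }
  structure(list(material = material, n = n, vssa_values = vssa,
                 mean = mean_v, sem = sem_v, t_stat = t_stat,
                 p_value = p_value,
                 classified_nano = isTRUE(mean_v > VSSA_THRESHOLD &&
                                          !is.na(p_value) && p_value < alpha),
                 rho_area = rho_area, rho_volume = rho_volume,
                 alpha = alpha, notes = notes),
            class = "material_summary")
}

#' @export
print.material_summary <- function(x, ...) {
  cat(sprintf("<material_summary> %s (n = %d reconstructions)\n", x$material, x$n))
  cat(sprintf("  VSSA: %.1f +/- %.1f m^2/cm^3 (mean +/- SEM)\n", x$mean, x$sem))
  if (!is.na(x$t_stat))
    cat(sprintf("  t = %.2f vs %g m^2/cm^3, p = %.3g -> %s\n",
                x$t_stat, VSSA_THRESHOLD, x$p_value,
                if (x$classified_nano) "nanostructured" else "not classified nanostructured"))
  if (!is.na(x$rho_area))
    cat(sprintf("  Spearman rho (measured vs ECD-calculated): area %.3f, volume %.3f\n",
                x$rho_area, x$rho_volume))
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}
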