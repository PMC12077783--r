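#' Estimate the ensemble-mean centre-of-mass speed
#'
#' Fits an ordinary least-squares slope to each replicate's centre-of-mass
#' series against time and reports the mean slope and the standard error of
#' the mean across replicates, in both radii per timestep and mr/tau
#' (1e-3 radii per timestep).
#'
#' @param ensemble a [run_ensemble()] result (or a list of equal-length
#'   `cohesim_trajectory` objects).
#' @param burn_in number of initial timesteps to discard before fitting
#'   (default 0: the full trajectory is used).
#' @return an object of class `speed_estimate`: list with `slope` (mean
#'   slope, radii/timestep), `stderr`, `mean_mr_per_tau`,
#'   `stderr_mr_per_tau`, `slopes` (per replicate) and `n_replicates`.
#' @export
estimate_speed <- function(ensemble, burn_in = 0) {
  com <- ensemble_com(ensemble)
  nt <- nrow(com)
  if (burn_in >= nt - 1L) stop("'burn_in' leaves fewer than 2 timepoints")
  tt <- seq_len(nt) - 1L
  keep <- tt >= burn_in
  tk <- tt[keep]
  tc <- tk - mean(tk)
  # per-replicate OLS slope: cov(t, com) / var(t)
  slopes <- as.numeric(crossprod(tc, com[keep, , drop = FALSE])) / sum(tc^2)
  m <- mean(slopes)
  se <- stats::sd(slopes) / sqrt(length(slopes))
  structure(list(slope = m, stderr = se,
                 mean_mr_per_tau = 1000 * m,
                 stderr_mr_per_tau = 1000 * se,
                 slopes = slopes,
                 n_replicates = length(slopes)),
            class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf("mean COM speed: %.2f +- %.2f mr/tau (%d replicates)\n",
              x$mean_mr_per_tau, x$stderr_mr_per_tau, x$n_replicates))
  invisible(x)
}

#' Ensemble mean-squared displacement of the centre of mass
#'
#' `MSD(t) = mean over replicates of (com(t) - com(0))^2`.  A diffusive
#' (unbiased random walk) ensemble gives a linear MSD; persistent directed
#' motion gives a quadratic (ballistic) MSD.
#'
#' @inheritParams estimate_speed
#' @return an object of class `msd_result`: list with `lags` (0-based
#'   timesteps), `msd`, `n_replicates`; fit fields are filled in by
#'   [fit_msd()].
#' @export
compute_msd <- function(ensemble) {
  com <- ensemble_com(ensemble)
  disp <- sweep(com, 2L, com[1L, ])
  structure(list(lags = seq_len(nrow(com)) - 1L,
                 msd = rowMeans(disp^2),
                 n_replicates = ncol(com),
                 fit_order = NULL, coefficients = NULL,
                 r_squared = NULL),
            class = "msd_result")
}

#' Through-origin polynomial fit of an MSD curve
#'
#' Fits `msd = a * t` (order 1) or `msd = a * t + b * t^2` (order 2) by
#' least squares constrained through the origin (lag 0 is excluded from the
#' fit; the model has no intercept, and R-squared is computed against the
#' uncentred total sum of squares accordingly).  For reference, the
#' R-squared of the same polynomial fitted with a free intercept is also
#' reported.
#'
#' @param msd an [compute_msd()] result.
#' @param order 1 (linear) or 2 (quadratic).
#' @return the `msd_result` with `fit_order`, `coefficients` (named `a`,
#'   and `b` for order 2), `coef_se` (their standard errors), `r_squared`
#'   (through-origin) and `r_squared_intercept` filled in.
#' @export
fit_msd <- function(msd, order = 1) {
  stopifnot(inherits(msd, "msd_result"), order %in% c(1, 2))
  keep <- msd$lags > 0
  t1 <- msd$lags[keep]
  y <- msd$msd[keep]
  if (length(unique(t1)) < order + 1)
    stop("need at least ", order + 1, " distinct positive lags")
  fit <- if (order == 1) lm(y ~ 0 + t1) else lm(y ~ 0 + t1 + I(t1^2))
  fit_i <- if (order == 1) lm(y ~ t1) else lm(y ~ t1 + I(t1^2))
  cf <- coef(fit)
  names(cf) <- c("a", "b")[seq_len(order)]
  sm <- summary(fit)
  msd$fit_order <- order
  msd$coefficients <- cf
  msd$coef_se <- sm$coefficients[, "Std. Error"]
  msd$r_squared <- sm$r.squared          # uncentred TSS for no-intercept fit
  msd$r_squared_intercept <- summary(fit_i)$r.squared
  msd
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("ensemble MSD over %d replicates, %d lags\n",
              x$n_replicates, length(x$lags)))
  if (!is.null(x$fit_order)) {
    cat(sprintf("  order-%d through-origin fit: %s; R^2 = %.4f\n",
                x$fit_order,
                paste(sprintf("%s = %.3e", names(x$coefficients),
                              x$coefficients), collapse = ", "),
                x$r_squared))
  }
  invisible(x)
}

#' Chemotactic index of a path
#'
#' `CI = (net displacement along the gradient axis) / (total path length)`,
#' in `[-1, 1]`; positive values indicate motion up the gradient and values
#' above 0.5 are conventionally read as directional migration.
#'
#' @param x numeric vector of positions along the gradient axis, or a
#'   `cohesim_trajectory` (its centre-of-mass series is used).
#' @return the chemotactic index, or `NA` (with a warning) for a path of
#'   zero length.
#' @export
chemotactic_index <- function(x) {
  if (inherits(x, "cohesim_trajectory")) x <- x$com
  path <- sum(abs(diff(x)))
  if (path == 0) {
    warning("zero path length: chemotactic index undefined")
    return(NA_real_)
  }
  (x[length(x)] - x[1L]) / path
}

# Extract the COM matrix (timesteps x replicates) from an ensemble or a
# list of trajectories, enforcing equal lengths and >= 2 replicates.
ensemble_com <- function(ensemble) {
  if (inherits(ensemble, "cohesim_ensemble")) return(ensemble$com)
  if (is.list(ensemble) && length(ensemble) &&
      all(vapply(ensemble, inherits, logical(1), "cohesim_trajectory"))) {
    lens <- vapply(ensemble, function(tr) length(tr$com), integer(1))
    if (length(ensemble) < 2L) stop("need at least 2 replicates")
    if (length(unique(lens)) != 1L)
      stop("replicate trajectories have unequal lengths")
    return(vapply(ensemble, `[[`, numeric(lens[1L]), "com"))
  }
  stop("'ensemble' must be a cohesim_ensemble or list of trajectories")
}
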