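# 15N relaxation analysis: mono-exponential R1/R2 decay fitting with
# duplicate-delay error propagation, heteronuclear NOE ratios, and the
# apparent rotational correlation time from R2/R1.

# 15N/1H gyromagnetic frequency ratio: nu_N = this * nu_H.
N15_FREQ_RATIO <- 0.10136905

#' Construct a relaxation decay series
#'
#' @param delay Relaxation delays in seconds (>= 4 distinct values;
#'   duplicated delays are permitted and drive the error estimate).
#' @param intensity Peak intensities (arbitrary units).
#' @param residue Residue id.
#' @param experiment "R1" or "R2".
#' @return data.frame of class \code{relaxation_series}.
#' @export
relaxation_series <- function(delay, intensity, residue = NA_integer_,
                              experiment = c("R1", "R2")) {
  experiment <- match.arg(experiment)
  if (any(delay < 0)) stopf("delays must be non-negative")
  if (length(unique(delay)) < 4L) stopf("need >= 4 distinct delays")
  s <- data.frame(delay = delay, intensity = intensity)
  attr(s, "residue") <- as.integer(residue)
  attr(s, "experiment") <- experiment
  class(s) <- c("relaxation_series", "data.frame")
  s
}

# Pooled intensity noise from duplicated delays: sd of a difference of
# two equal-noise measurements is sigma*sqrt(2).
duplicate_noise_sd <- function(series_list) {
  if (inherits(series_list, "data.frame")) series_list <- list(series_list)
  sq <- unlist(lapply(series_list, function(s) {
    dup <- s$delay[duplicated(s$delay)]
    unlist(lapply(unique(dup), function(d) {
      v <- s$intensity[s$delay == d]
      (diff(v[1:2]))^2 / 2
    }))
  }))
  if (length(sq) == 0L) return(NA_real_)
  sqrt(mean(sq))
}

#' Fit a mono-exponential relaxation decay
#'
#' Nonlinear least squares of I(t) = I0 * exp(-R * t).  The rate error
#' is obtained by propagating the duplicate-delay noise estimate (when
#' duplicated delays are present) through the fit covariance; otherwise
#' the residual variance is used.
#'
#' @param series A \code{relaxation_series} (or data.frame with delay
#'   and intensity columns).
#' @param noise_sd Optional externally pooled intensity noise; overrides
#'   the in-series duplicate estimate.
#' @param offset If TRUE, fit an additive baseline term as well.
#' @return Object of class \code{relax_fit} with elements rate,
#'   rate_err (1/s), i0, i0_err, residue, sigma and fitted values.
#' @export
fit_exponential <- function(series, noise_sd = NULL, offset = FALSE) {
  t <- series$delay; y <- series$intensity
  check_finite(y, "intensities")
  if (diff(range(y)) == 0) stopf("all intensities equal: nothing to fit")
  i0_0 <- max(abs(y))
  half <- t[which.min(abs(abs(y) - i0_0 / 2))]
  r0 <- if (half > 0) log(2) / half else 1
  model <- if (offset) {
    function(p, t) p[1] * exp(-p[2] * t) + p[3]
  } else {
    function(p, t) p[1] * exp(-p[2] * t)
  }
  resid_fn <- function(p) y - model(p, t)
  starts <- list(c(i0_0, r0), c(i0_0, r0 * 3), c(i0_0, max(r0 / 3, 1e-3)))
  best <- NULL
  for (s0 in starts) {
    p0 <- if (offset) c(s0, 0) else s0
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (fit$deviance < 1e-20 * sum(y^2)) break
  }
  if (is.null(best)) stopf("exponential fit failed to converge")
  p <- best$par
  if (p[2] <= 0) stopf("fitted rate is non-positive: data do not decay")
  # parameter covariance: sigma^2 * (J'J)^-1
  sigma <- noise_sd %||% duplicate_noise_sd(series)
  dof <- max(length(y) - length(p), 1L)
  if (is.na(sigma)) sigma <- sqrt(best$deviance / dof)
  jtj <- best$hessian / 2  # nls.lm hessian = 2 J'J at optimum
  cv <- tryCatch(solve(jtj) * sigma^2, error = function(e)
    matrix(NA_real_, length(p), length(p)))
  out <- list(rate = p[2], rate_err = sqrt(abs(cv[2, 2])),
              i0 = p[1], i0_err = sqrt(abs(cv[1, 1])),
              offset = if (offset) p[3] else 0,
              sigma = sigma, residue = attr(series, "residue"),
              experiment = attr(series, "experiment"),
              fitted = model(p, t), data = data.frame(delay = t, intensity = y))
  class(out) <- "relax_fit"
  out
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("relax_fit (%s%s): rate %.4g +/- %.3g 1/s, I0 %.4g\n",
              x$experiment %||% "?",
              if (is.na(x$residue)) "" else sprintf(", residue %d", x$residue),
              x$rate, x$rate_err, x$i0))
  invisible(x)
}

#' @export
coef.relax_fit <- function(object, ...) {
  c(rate = object$rate, i0 = object$i0)
}

#' Heteronuclear NOE ratio with error propagation
#'
#' noe = saturated/unsaturated; the error combines the spectral noise
#' of both measurements in quadrature:
#' err = |noe| * sqrt((sd/sat)^2 + (sd/unsat)^2).
#'
#' @param saturated,unsaturated Peak intensities from the saturated and
#'   reference experiments.
#' @param noise_sd Spectral noise (intensity units).
#' @param residue Optional residue id.
#' @return data.frame with residue, noe and noe_err; negative ratios
#'   (flexible residues) are preserved, never clipped.
#' @export
het_noe <- function(saturated, unsaturated, noise_sd, residue = NA_integer_) {
  if (any(unsaturated == 0)) stopf("unsaturated intensity is zero: missing reference peak")
  noe <- saturated / unsaturated
  err <- abs(noe) * sqrt((noise_sd / saturated)^2 + (noise_sd / unsaturated)^2)
  data.frame(residue = as.integer(residue), noe = noe, noe_err = abs(err))
}

#' Apparent rotational correlation time from R2/R1
#'
#' tau_c = (1 / (4 pi nu_N)) * sqrt(6 R2/R1 - 7), with nu_N the 15N
#' Larmor frequency derived from the 1H field.  Valid outside the
#' extreme-narrowing breakdown, i.e. when 6 R2/R1 > 7.
#'
#' @param r1,r2 Longitudinal and transverse rates (1/s); vectors are
#'   averaged with \code{average} before the ratio is formed.
#' @param field_1h 1H spectrometer frequency in MHz.
#' @param average "mean" or "trimmed" (10 percent trimmed mean) for
#'   vector inputs.
#' @return Correlation time in nanoseconds.
#' @export
estimate_tauc <- function(r1, r2, field_1h, average = c("mean", "trimmed")) {
  average <- match.arg(average)
  avg <- function(x) if (average == "mean") mean(x) else mean(x, trim = 0.1)
  ratio <- avg(r2) / avg(r1)
  if (6 * ratio <= 7) {
    stopf("R2/R1 = %.3f is inside the extreme-narrowing regime (6*R2/R1 <= 7)",
          ratio)
  }
  nu_n <- N15_FREQ_RATIO * field_1h * 1e6  # Hz
  tau_s <- sqrt(6 * ratio - 7) / (4 * pi * nu_n)
  tau_s * 1e9
}
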