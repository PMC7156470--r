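## bragg_termination: self-gating of Bragg diffraction.  Crystalline disorder
## grows during the probe pulse as an effective B-factor increasing with the
## third power of time; reference intensities are damped accordingly at each
## time point and averaged over the pulse.  Wilson-plot and cumulative
## intensity (N(z)) diagnostics quantify the apparent damage.

#' Bragg-termination configuration
#'
#' @param b_end effective B-factor at the end of the pulse, A^2 (125 for a
#'   native protein crystal, 500 for a heavy-atom-doped one)
#' @param pulse_length probe pulse length, fs (default 100)
#' @param n_steps number of time points averaged over the pulse (default 100)
#' @return object of class `bragg_config`; the time exponent is fixed at 3
#' @export
bragg_config <- function(b_end = 125, pulse_length = 100, n_steps = 100) {
  stopifnot(b_end >= 0, pulse_length > 0, n_steps >= 2)
  out <- list(b_end = b_end, pulse_length = pulse_length,
              n_steps = as.integer(n_steps), exponent = 3)
  class(out) <- "bragg_config"
  out
}

#' Effective B-factor at time t
#'
#' Grows with the third power of time from 0 at the start of the pulse to
#' `b_end` at its end: `b_eff(t) = b_end (t / pulse_length)^3`.
#'
#' @param t time, fs, within `[0, pulse_length]` (vectorized)
#' @param config a [bragg_config()]
#' @return B_eff in A^2
#' @export
b_eff <- function(t, config) {
  stopifnot(inherits(config, "bragg_config"),
            all(t >= 0), all(t <= config$pulse_length))
  config$b_end * (t / config$pulse_length)^config$exponent
}

#' Apply Bragg-termination damping to a reflection set
#'
#' For each of `n_steps` uniformly spaced time points t_p over the pulse, the
#' input intensities are damped by the Debye-Waller factor
#' `exp(-2 B_eff(t_p) s^2)` (intensity convention, s = sin(theta)/lambda);
#' the damped intensities are averaged over the time points.
#'
#' @param reflections a `reflection_set`
#' @param config a [bragg_config()]
#' @return a `reflection_set` with attenuated intensities (elementwise never
#'   exceeding the input)
#' @export
attenuate <- function(reflections, config) {
  stopifnot(inherits(reflections, "reflection_set"),
            inherits(config, "bragg_config"))
  tp <- seq(0, config$pulse_length, length.out = config$n_steps)
  B <- b_eff(tp, config)
  fac <- rowMeans(exp(-2 * outer(reflections$s^2, B)))
  out <- reflections
  out$intensity <- reflections$intensity * fac
  attr(out, "b_end") <- config$b_end
  out
}

## equal-volume resolution bins (uniform in s^3); returns bin index per record
.s3_bins <- function(s, n_bins) {
  br <- seq(min(s^3) - 1e-12, max(s^3) + 1e-12, length.out = n_bins + 1)
  findInterval(s^3, br, rightmost.closed = TRUE)
}

#' Wilson fit of a reflection set
#'
#' Least-squares fit of `ln <I>` versus `s^2` over equal-volume resolution
#' bins; the Wilson B-factor is `-slope / 2`.
#'
#' @param reflections a `reflection_set`
#' @param n_bins number of equal-volume (in s^3) resolution bins (default 20)
#' @return object of class `wilson_fit` with fields `wilson_b` (A^2), `scale`,
#'   and the binned table
#' @export
wilson_fit <- function(reflections, n_bins = 20) {
  stopifnot(inherits(reflections, "reflection_set"))
  b <- .s3_bins(reflections$s, n_bins)
  tab <- do.call(rbind, lapply(split(seq_along(b), b), function(idx) {
    data.frame(s2 = mean(reflections$s[idx]^2),
               mean_i = mean(reflections$intensity[idx]),
               n = length(idx))
  }))
  tab <- tab[tab$n > 0 & tab$mean_i > 0, ]
  if (nrow(tab) < 2) stop("fewer than 2 usable resolution bins for the Wilson fit")
  fit <- stats::lm(log(mean_i) ~ s2, data = tab, weights = tab$n)
  out <- list(wilson_b = -unname(coef(fit)[2]) / 2,
              scale = exp(unname(coef(fit)[1])), bins = tab)
  class(out) <- "wilson_fit"
  out
}

#' @export
print.wilson_fit <- function(x, ...) {
  cat(sprintf("<wilson_fit> B = %.3f A^2, scale = %.4g (%d bins)\n",
              x$wilson_b, x$scale, nrow(x$bins)))
  invisible(x)
}

#' @export
coef.wilson_fit <- function(object, ...) {
  c(wilson_b = object$wilson_b, scale = object$scale)
}

#' Cumulative distribution of normalized intensities
#'
#' Normalizes intensities by their resolution-bin mean and returns the
#' empirical fraction N(z) of normalized intensities below z, together with
#' the ideal acentric curve `1 - exp(-z)`.
#'
#' @param reflections a `reflection_set`
#' @param n_z number of z grid points (default 100, grid 0..z_max)
#' @param z_max upper end of the z grid (default 5)
#' @param n_bins resolution bins used for normalization (default 20)
#' @return data.frame with columns `z`, `N` (empirical, non-decreasing) and
#'   `N_acentric`
#' @export
cumulative_intensity_distribution <- function(reflections, n_z = 100,
                                              z_max = 5, n_bins = 20) {
  stopifnot(inherits(reflections, "reflection_set"), n_z >= 2)
  b <- .s3_bins(reflections$s, n_bins)
  mu <- stats::ave(reflections$intensity, b)
  z_val <- reflections$intensity / mu
  z <- seq(0, z_max, length.out = n_z)
  N <- vapply(z, function(zz) mean(z_val <= zz), numeric(1))
  data.frame(z = z, N = N, N_acentric = 1 - exp(-z))
}
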