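## pump_probe: double-Gaussian pulse model, the full experiment driver
## (rate equations -> charge sampling -> screened ion dynamics per trajectory),
## ensemble observables and jackknife statistics.

#' Define an X-ray pump / X-ray probe pulse pair
#'
#' Two Gaussian temporal profiles of equal FWHM separated by `delay`, sharing
#' `total_fluence` according to `split`.  The pump is centred at `pump_center`
#' so that essentially the whole pump Gaussian lies inside the simulation
#' window starting at t = 0.
#'
#' @param total_fluence total pump+probe fluence, photons/A^2 (see
#'   [fluence_per_A2()] and [fluence_cases()] for the experimental values)
#' @param delay pump-probe delay, fs
#' @param photon_energy photon energy, keV (default 7.14; the ~80 eV
#'   pump/probe difference is neglected)
#' @param fwhm full width at half maximum of each pulse, fs (default 15)
#' @param split fraction of the total fluence in the pump (default 0.5)
#' @param pump_center pump-pulse centre, fs (default 20)
#' @return object of class `pulse_pair`
#' @export
pulse_pair <- function(total_fluence, delay, photon_energy = 7.14, fwhm = 15,
                       split = 0.5, pump_center = 20) {
  stopifnot(total_fluence >= 0, delay >= 0, fwhm > 0, split >= 0, split <= 1)
  out <- list(photon_energy = photon_energy, fwhm = fwhm, delay = delay,
              total_fluence = total_fluence, split = split,
              pump_center = pump_center,
              sigma = fwhm / (2 * sqrt(2 * log(2))))
  class(out) <- "pulse_pair"
  out
}

#' @export
print.pulse_pair <- function(x, ...) {
  cat(sprintf(
    "<pulse_pair> %.3g photons/A^2 total (%.0f%% pump), %.3g fs FWHM, delay %.4g fs, %.4g keV\n",
    x$total_fluence, 100 * x$split, x$fwhm, x$delay, x$photon_energy))
  invisible(x)
}

#' Instantaneous photon flux of a pulse pair
#'
#' Sum of the two normalized Gaussians scaled by their fluence shares.
#'
#' @param pulses a [pulse_pair()]
#' @param t time, fs (vectorized)
#' @return flux in photons/A^2/fs
#' @export
pulse_flux <- function(pulses, t) {
  s <- pulses$sigma
  g <- function(mu) exp(-(t - mu)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  pulses$total_fluence *
    (pulses$split * g(pulses$pump_center) +
     (1 - pulses$split) * g(pulses$pump_center + pulses$delay))
}

## deterministic composition of the default dense supercell (used as the
## charging environment for vacuum-mode comparisons)
default_supercell_composition <- function(target_atom_count = 300,
                                          sulfur_fraction = 2 / 300,
                                          composition = c(H = 0.52, C = 0.15,
                                                          N = 0.04, O = 0.29)) {
  n_S <- max(2L, as.integer(round(sulfur_fraction * target_atom_count)))
  n_extra <- max(0L, target_atom_count - 4L - (n_S - 2L))
  cnt <- .allocate(n_extra, composition[c("H", "C", "N", "O")])
  out <- c(H = cnt[[1]], C = cnt[[2]] + 2L, N = cnt[[3]], O = cnt[[4]],
           S = n_S)
  out[out > 0]
}

#' Run the pump-probe experiment over an ensemble of trajectories
#'
#' For each delay: integrates the rate equations for the cell composition
#' through the double pulse (once; the mean-field populations depend only on
#' the composition), then for each trajectory generates a fresh seeded cell
#' (dense mode) or the four-atom vacuum fixture, samples per-atom charge
#' staircases from the populations, and integrates the screened ion dynamics
#' to the probe.  The observable is the tracked S-S distance at the
#' probe-pulse centre (default) or a probe-profile-weighted average.
#'
#' In vacuum mode the moiety is ionized exactly as in the dense crystal (the
#' charge staircases are sampled from the same crystal-environment
#' populations) but moves with no screening and no surrounding atoms,
#' isolating the mechanical effect of the dense environment.
#'
#' @param pulses a [pulse_pair()]; its `delay` is overridden by `delays`
#' @param n_trajectories ensemble size per delay (default 20)
#' @param mode `"dense"` or `"vacuum"`
#' @param delays vector of pump-probe delays, fs (default: the delay in
#'   `pulses`)
#' @param seed master seed; per-trajectory seeds are derived as
#'   `(seed + 104729*delay_index + 7919*trajectory) mod (2^31-1)`
#' @param cell_factory function(seed) returning a `sim_cell` (dense mode;
#'   default [generate_supercell()])
#' @param rates a `rate_table`
#' @param sample_radius crystal radius for electron trapping, A
#' @param params [pair_potential_params()]
#' @param config [dynamics_config()] (its `t_end` is set per delay)
#' @param observable `"probe_center"` or `"probe_weighted"`
#' @param reference_composition charging composition for vacuum mode
#'   (default: the default dense supercell composition)
#' @param rate_dt,rate_stride rate-equation step and output stride, fs
#' @return object of class `pp_ensemble`: `table` (delay, mean, sd, n),
#'   `values` (trajectory x delay matrix of S-S distances, A), `charges`
#'   (trajectory x delay matrix of maximum sampled sulfur charge), metadata
#' @export
run_experiment <- function(pulses, n_trajectories = 20,
                           mode = c("dense", "vacuum"), delays = NULL,
                           seed = 1, cell_factory = NULL,
                           rates = default_rate_table(),
                           sample_radius = 1000,
                           params = pair_potential_params(),
                           config = dynamics_config(),
                           observable = c("probe_center", "probe_weighted"),
                           reference_composition = NULL,
                           rate_dt = 0.02, rate_stride = 0.5) {
  mode <- match.arg(mode)
  observable <- match.arg(observable)
  stopifnot(n_trajectories >= 1)
  if (is.null(delays)) delays <- pulses$delay
  if (is.null(cell_factory))
    cell_factory <- function(s) generate_supercell(seed = s)
  vac_cell <- if (mode == "vacuum") generate_vacuum_disulfide() else NULL
  if (mode == "vacuum" && is.null(reference_composition))
    reference_composition <- default_supercell_composition()
  ref_volume <- 14^3

  nd <- length(delays)
  vals <- matrix(NA_real_, n_trajectories, nd)
  qmax <- matrix(NA_real_, n_trajectories, nd)
  seeds_used <- matrix(0, n_trajectories, nd)
  hist_cache <- list()
  init_d <- NA_real_

  for (di in seq_len(nd)) {
    d <- delays[di]
    pp <- pulse_pair(pulses$total_fluence, d, pulses$photon_energy,
                     pulses$fwhm, pulses$split, pulses$pump_center)
    probe_center <- pp$pump_center + d
    t_end <- probe_center +
      (if (observable == "probe_weighted") 2.5 * pp$sigma else 0)
    tseeds <- derive_seeds(seed, n_trajectories, stream = di)
    seeds_used[, di] <- tseeds
    for (k in seq_len(n_trajectories)) {
      cell <- if (mode == "dense") cell_factory(tseeds[k]) else vac_cell
      if (is.na(init_d)) init_d <- ss_distance(cell)
      comp <- if (mode == "dense") cell_composition(cell)
              else reference_composition
      vol <- if (mode == "dense" && is.finite(cell$edge_length))
               cell$edge_length^3 else ref_volume
      key <- paste(paste(names(comp), comp, sep = ":", collapse = ","),
                   vol, d, sep = "|")
      if (is.null(hist_cache[[key]])) {
        hist_cache[[key]] <- run_rate_equations(
          comp, pp, rates, t_end = t_end, dt = rate_dt, stride = rate_stride,
          cell_volume = vol, sample_radius = sample_radius)
      }
      hist <- hist_cache[[key]]
      qtraj <- tryCatch(
        sample_ion_charges(hist, cell, seed = tseeds[k] + 1),
        error = function(e) stop("trajectory ", k, " (delay ", d, " fs): ",
                                 conditionMessage(e)))
      kap <- if (mode == "dense") hist$kappa else rep(0, length(hist$times))
      cfg <- config
      cfg$t_end <- t_end
      traj <- tryCatch(
        integrate_ions(cell, qtraj, kappa = kap, kappa_times = hist$times,
                       params = params, config = cfg),
        error = function(e) stop("trajectory ", k, " (delay ", d, " fs): ",
                                 conditionMessage(e)))
      vals[k, di] <- observe_ss(traj, pp, observable)
      sulfur <- cell$atoms$element == "S"
      qmax[k, di] <- max(qtraj$charges[sulfur, ncol(qtraj$charges)])
    }
  }
  tab <- data.frame(delay = delays,
                    mean = colMeans(vals),
                    sd = apply(vals, 2, stats::sd),
                    n = n_trajectories)
  out <- list(table = tab, values = vals, charges = qmax, mode = mode,
              observable = observable, pulses = pulses, seed = seed,
              seeds = seeds_used, initial_distance = init_d)
  class(out) <- "pp_ensemble"
  out
}

## S-S observable from a trajectory: value at the probe centre, or a
## probe-Gaussian-weighted time average
observe_ss <- function(traj, pulses, observable = "probe_center") {
  tc <- pulses$pump_center + pulses$delay
  if (observable == "probe_center") {
    stats::approx(traj$times, traj$ss, xout = min(tc, max(traj$times)))$y
  } else {
    w <- exp(-(traj$times - tc)^2 / (2 * pulses$sigma^2))
    sum(w * traj$ss) / sum(w)
  }
}

#' @export
print.pp_ensemble <- function(x, ...) {
  cat(sprintf("<pp_ensemble> %s mode, %d trajectories/delay, %.3g photons/A^2 total\n",
              x$mode, nrow(x$values), x$pulses$total_fluence))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
summary.pp_ensemble <- function(object, ...) {
  tab <- object$table
  tab$jackknife_sd <- vapply(seq_len(ncol(object$values)), function(j)
    jackknife_dispersion(object$values[, j], seed = object$seed), numeric(1))
  tab$max_S_charge <- apply(object$charges, 2, max)
  structure(list(table = tab, mode = object$mode,
                 fluence = object$pulses$total_fluence),
            class = "summary.pp_ensemble")
}

#' @export
print.summary.pp_ensemble <- function(x, ...) {
  cat(sprintf("Pump-probe ensemble (%s mode, total fluence %.3g photons/A^2)\n",
              x$mode, x$fluence))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.pp_ensemble <- function(x, ...) x$table

#' @export
plot.pp_ensemble <- function(x, add = FALSE, col = 1, ...) {
  tab <- x$table
  if (!add) {
    plot(tab$delay, tab$mean, type = "b", pch = 16, col = col,
         xlab = "pump-probe delay (fs)", ylab = "mean S-S distance (A)",
         ylim = range(c(tab$mean - tab$sd, tab$mean + tab$sd)), ...)
  } else lines(tab$delay, tab$mean, type = "b", pch = 16, col = col)
  segments(tab$delay, tab$mean - tab$sd, tab$delay, tab$mean + tab$sd, col = col)
  invisible(x)
}

#' Mean S-S elongation speed over a delay window
#'
#' Least-squares slope of the ensemble-mean S-S distance versus delay inside
#' `window`, converted from A/fs to m/s (1 A/fs = 1e5 m/s).
#'
#' @param obs a `pp_ensemble`
#' @param window delay interval, fs
#' @return speed in m/s
#' @export
elongation_speed <- function(obs, window = c(20, 100)) {
  tab <- obs$table
  sel <- tab$delay >= window[1] & tab$delay <= window[2]
  if (sum(sel) < 2) stop("need at least 2 delays inside the window")
  fit <- stats::lsfit(tab$delay[sel], tab$mean[sel])
  unname(fit$coefficients[2]) * 1e5
}

#' Fluence-ratio displacement (caging) signature
#'
#' Ratio of the S-S response to a fluence increase at a fixed delay:
#' `type = "displacement"` (default) compares mean displacements from the
#' initial bond length, `(d_hi - d0) / (d_lo - d0)`; `type = "distance"`
#' compares the mean distances directly, `d_hi / d_lo`.
#'
#' @param obs_lo,obs_hi `pp_ensemble`s at the lower / higher fluence
#' @param delay delay at which to compare, fs (must be present in both)
#' @param type `"displacement"` or `"distance"`
#' @return the ratio
#' @export
displacement_ratio <- function(obs_lo, obs_hi, delay,
                               type = c("displacement", "distance")) {
  type <- match.arg(type)
  i_lo <- match(delay, obs_lo$table$delay)
  i_hi <- match(delay, obs_hi$table$delay)
  if (is.na(i_lo) || is.na(i_hi)) stop("delay ", delay, " fs not present in both ensembles")
  d_lo <- obs_lo$table$mean[i_lo]
  d_hi <- obs_hi$table$mean[i_hi]
  if (type == "distance") return(d_hi / d_lo)
  d0 <- obs_lo$initial_distance
  if (abs(d_lo - d0) < 1e-9)
    stop("zero displacement at the lower fluence: displacement ratio undefined")
  (d_hi - d0) / (d_lo - d0)
}

#' Jackknife-style dispersion of an ensemble observable
#'
#' Standard deviation across `n_resamples` means of random `fraction`-subsets
#' (drawn without replacement) of the per-trajectory values — the resampling
#' scheme used to attach uncertainties to ensemble observables.
#'
#' @param values per-trajectory observable values
#' @param fraction subset fraction, in (0, 1) (default 0.75)
#' @param n_resamples number of resampled datasets (default 100)
#' @param seed integer seed
#' @return dispersion estimate (standard deviation of subset means)
#' @export
jackknife_dispersion <- function(values, fraction = 0.75, n_resamples = 100,
                                 seed = NULL) {
  stopifnot(fraction > 0, fraction < 1, n_resamples >= 2)
  m <- floor(fraction * length(values))
  if (m < 1) stop("subset size < 1: too few values for fraction ", fraction)
  with_seed(seed, {
    means <- vapply(seq_len(n_resamples),
                    function(i) mean(sample(values, m)), numeric(1))
  })
  stats::sd(means)
}
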