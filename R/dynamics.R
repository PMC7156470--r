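## ion_dynamics: screened pairwise forces (Debye Coulomb + short-range
## collision wall), periodic replication summation truncated by the screening
## length, and fixed-step RK4 integration with a frozen boundary outside the
## free sphere.  The per-step force loop is compiled (src/dynamics.cpp); the
## exported R functions below define the same potentials independently and are
## used to cross-check the compiled kernel.

#' Screened (Debye) pair potential
#'
#' `V = k_e q_i q_j exp(-kappa r) / r`, the conventional screened Coulomb
#' interaction between two ions in an electron plasma with inverse screening
#' length `kappa`.
#'
#' @param qi,qj ionic charges, e
#' @param r separation, A (> 0)
#' @param kappa inverse screening length, A^-1
#' @return energy in eV
#' @export
screened_pair_potential <- function(qi, qj, r, kappa = 0) {
  stopifnot(all(r > 0), all(kappa >= 0))
  .ke * qi * qj * exp(-kappa * r) / r
}

#' Short-range ionic collision potential
#'
#' `D (1 - exp(-a (r - r_e)))^2` for `0 <= r <= r_e` and 0 beyond: a repulsive
#' wall excluding unphysically close approach of two ions, continuous (and
#' zero) at the contact radius `r_e`.
#'
#' @param r separation, A (>= 0)
#' @param D wall height scale, eV
#' @param a hardness, A^-1
#' @param r_e contact radius (sum of effective ionic radii), A
#' @return energy in eV
#' @export
collision_potential <- function(r, D = 27.2, a = 2.0, r_e = 2.0) {
  stopifnot(all(r >= 0), D >= 0, a > 0, r_e > 0)
  ifelse(r <= r_e, D * (1 - exp(-a * (r - r_e)))^2, 0)
}

#' Pair-potential parameters
#'
#' Collision-wall parameters per element pair: `r_e` defaults to the sum of
#' single-bond covalent radii; `D` and `a` set the height and hardness of the
#' wall.  The wall acts only between pairs in which both atoms are ionized
#' (it is an *ionic* collision potential), so a completely neutral cell is
#' force-free.
#'
#' @param D wall height, eV (default 27.2)
#' @param a hardness, A^-1 (default 2)
#' @param r_e optional matrix of contact radii (A) over the supported elements
#'   (H, C, N, O, S); default: sums of covalent radii
#' @param collision enable/disable the wall
#' @return object of class `pair_potential_params`
#' @export
pair_potential_params <- function(D = 27.2, a = 2.0, r_e = NULL,
                                  collision = TRUE) {
  stopifnot(D >= 0, a > 0)
  if (is.null(r_e))
    r_e <- outer(.covalent_radii, .covalent_radii, `+`)
  stopifnot(is.matrix(r_e), all(r_e > 0))
  out <- list(D = D, a = a, r_e = r_e, collision = collision)
  class(out) <- "pair_potential_params"
  out
}

#' Dynamics configuration
#'
#' @param dt RK4 time step, fs (default 0.02; halving the step changes
#'   ensemble S-S endpoints by well under 1e-3 A)
#' @param t_end end time, fs
#' @param image_cutoff_tolerance truncate the periodic replication sum where
#'   `exp(-kappa r) <` this tolerance (default 1e-2); at least the nearest
#'   image is always kept
#' @param rcut_max hard cap on the replication distance, A (default 12; the
#'   cap only binds while the plasma is still dilute and the ionic charges —
#'   which track the same ionization history — are correspondingly small, and
#'   the contributions of farther replicas of the lattice largely cancel by
#'   symmetry)
#' @param skin neighbour-list skin, A
#' @param out_stride trajectory output stride, fs (default 1)
#' @param max_step_disp per-step displacement above which integration aborts
#'   as unstable, A (default 0.5)
#' @param store_positions keep full per-frame positions in the trajectory
#' @return object of class `dynamics_config`
#' @export
dynamics_config <- function(dt = 0.02, t_end = 100,
                            image_cutoff_tolerance = 1e-2, rcut_max = 12,
                            skin = 1.5, out_stride = 1, max_step_disp = 0.5,
                            store_positions = FALSE) {
  stopifnot(dt > 0, t_end > 0, image_cutoff_tolerance > 0,
            image_cutoff_tolerance < 1, rcut_max > 0, skin > 0)
  out <- list(dt = dt, t_end = t_end,
              image_cutoff_tolerance = image_cutoff_tolerance,
              rcut_max = rcut_max, skin = skin, out_stride = out_stride,
              max_step_disp = max_step_disp,
              store_positions = store_positions)
  class(out) <- "dynamics_config"
  out
}

## image shift vectors for a given replication range (R reference path)
.image_shifts <- function(L, rcut) {
  if (!is.finite(L) || L <= 0) return(matrix(0, 1, 3))
  nmax <- max(1L, as.integer(ceiling(rcut / L)))
  g <- expand.grid(x = -nmax:nmax, y = -nmax:nmax, z = -nmax:nmax)
  as.matrix(g) * L
}

## replication cutoff: exp(-kappa r) < tolerance, floored just above the
## collision contact radii and capped by rcut_max (same rule as the kernel)
.replication_cutoff <- function(kappa, config) {
  rc <- config$rcut_max
  if (kappa > 1e-9)
    rc <- min(rc, max(3.5, -log(config$image_cutoff_tolerance) / kappa))
  rc
}

## total potential energy (reference implementation; smooth in positions: the
## replica set is fixed by kappa and the cell, with no per-pair distance cut)
total_potential <- function(cell, kappa, params = pair_potential_params(),
                            config = dynamics_config()) {
  a <- cell$atoms
  pos <- as.matrix(a[, c("x", "y", "z")])
  q <- a$charge
  n <- nrow(pos)
  rcut <- .replication_cutoff(kappa, config)
  shifts <- if (cell$periodic) .image_shifts(cell$edge_length, rcut)
            else matrix(0, 1, 3)
  re <- params$r_e[a$element, a$element]
  V <- 0
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    central <- all(sh == 0)
    for (i in seq_len(n)) {
      jj <- if (central) seq_len(n)[-i] else seq_len(n)
      dx <- sweep(pos[jj, , drop = FALSE], 2, pos[i, ] + sh)
      r <- sqrt(rowSums(dx^2))
      qq <- q[i] * q[jj]
      qq[cell$periodic & r > rcut] <- 0
      v <- ifelse(qq > 0, .ke * qq * exp(-kappa * r) / r, 0)
      if (params$collision) {
        wall <- qq > 0 & r <= re[i, jj]
        if (any(wall))
          v[wall] <- v[wall] + params$D *
            (1 - exp(-params$a * (r[wall] - re[i, jj][wall])))^2
      }
      V <- V + sum(v) / 2      # every ordered pair visited twice
    }
  }
  V
}

#' Total force on every atom
#'
#' Analytic gradient of the screened Coulomb plus collision potential, summed
#' over all pairs and over periodic replicas out to the distance where
#' `exp(-kappa r)` falls below the image cutoff tolerance (at least one image
#' shell is always included).  Forces are returned for all atoms, including
#' non-mobile ones (the integrator simply does not apply the latter).
#'
#' This is the package's reference implementation, written independently of
#' the compiled integration kernel and used to validate it.
#'
#' @param cell a `sim_cell` (atom charges are taken from the cell)
#' @param kappa inverse screening length, A^-1
#' @param params [pair_potential_params()]
#' @param config [dynamics_config()] (for the image cutoff)
#' @return n x 3 matrix of forces, eV/A
#' @export
total_force <- function(cell, kappa = 0, params = pair_potential_params(),
                        config = dynamics_config()) {
  a <- cell$atoms
  pos <- as.matrix(a[, c("x", "y", "z")])
  q <- a$charge
  n <- nrow(pos)
  rcut <- .replication_cutoff(kappa, config)
  shifts <- if (cell$periodic) .image_shifts(cell$edge_length, rcut)
            else matrix(0, 1, 3)
  re <- params$r_e[a$element, a$element]
  FF <- matrix(0, n, 3)
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    central <- all(sh == 0)
    for (i in seq_len(n)) {
      jj <- if (central) seq_len(n)[-i] else seq_len(n)
      dx <- -sweep(sweep(pos[jj, , drop = FALSE], 2, sh, `+`), 2, pos[i, ])
      ## dx = x_i - (x_j + shift)
      r <- sqrt(rowSums(dx^2))
      if (any(r == 0)) {
        j0 <- jj[which(r == 0)[1]]
        stop("overlapping atoms ", i, " and ", j0, ": pair distance is zero")
      }
      qq <- q[i] * q[jj]
      qq[cell$periodic & r > rcut] <- 0
      fmag <- ifelse(qq > 0, .ke * qq * exp(-kappa * r) * (1 + kappa * r) / r^2, 0)
      if (params$collision) {
        wall <- qq > 0 & r <= re[i, jj]
        if (any(wall)) {
          e1 <- exp(-params$a * (r[wall] - re[i, jj][wall]))
          fmag[wall] <- fmag[wall] - 2 * params$D * (1 - e1) * params$a * e1
        }
      }
      FF[i, ] <- FF[i, ] + colSums(dx / r * fmag)
    }
  }
  FF
}

#' Integrate the screened ion dynamics
#'
#' Classical RK4 with fixed step: mobile atoms (decided once, at t = 0, by the
#' free sphere around the S-S midpoint) move under the analytic gradient of
#' the screened Coulomb + collision potential; all other atoms are held fixed;
#' per-atom charges are piecewise-constant staircases and the screening
#' parameter is linearly interpolated between rate-equation outputs.
#'
#' @param cell a `sim_cell`
#' @param charge_trajectories a `charge_trajectories` from
#'   [sample_ion_charges()], or a numeric vector of static per-atom charges
#' @param kappa screening-parameter series (A^-1), or a single number
#' @param kappa_times times of the series, fs
#' @param params [pair_potential_params()]
#' @param config [dynamics_config()]
#' @return object of class `ion_trajectory`: `times` (fs), `ss` (tracked S-S
#'   distance, A), `kinetic`, `potential` (eV, mobile-atom energy ledger),
#'   `final` cell, and optionally `positions` (time x atom x 3)
#' @export
integrate_ions <- function(cell, charge_trajectories, kappa = 0,
                           kappa_times = NULL,
                           params = pair_potential_params(),
                           config = dynamics_config()) {
  stopifnot(inherits(cell, "sim_cell"))
  a <- cell$atoms
  n <- nrow(a)
  if (inherits(charge_trajectories, "charge_trajectories")) {
    qmat <- charge_trajectories$charges
    qtimes <- charge_trajectories$times
  } else {
    qmat <- matrix(as.numeric(charge_trajectories), n, 1)
    qtimes <- 0
  }
  stopifnot(nrow(qmat) == n)
  if (length(kappa) == 1 && is.null(kappa_times)) {
    kappa_times <- 0
  }
  stopifnot(length(kappa) == length(kappa_times))
  if (!all(a$mobile[cell$bridge]))
    stop("tracked bridge atoms must be mobile (increase free_radius)")
  eidx <- match(a$element, .element_symbols) - 1L
  res <- integrate_ions_cpp(
    as.matrix(a[, c("x", "y", "z")]), a$mass, a$mobile, eidx,
    params$r_e[.element_symbols, .element_symbols, drop = FALSE],
    params$D, params$a, params$collision,
    qmat, qtimes, as.numeric(kappa), as.numeric(kappa_times),
    if (cell$periodic) cell$edge_length else -1,
    cell$bridge[1] - 1L, cell$bridge[2] - 1L,
    config$dt, config$t_end, config$out_stride,
    config$image_cutoff_tolerance, config$rcut_max, config$skin,
    config$max_step_disp, config$store_positions)
  final <- cell
  final$atoms$x <- res$pos_final[, 1]
  final$atoms$y <- res$pos_final[, 2]
  final$atoms$z <- res$pos_final[, 3]
  final$atoms$vx <- res$vel_final[, 1]
  final$atoms$vy <- res$vel_final[, 2]
  final$atoms$vz <- res$vel_final[, 3]
  final$atoms$charge <- qmat[, ncol(qmat)]
  out <- list(times = res$times, ss = res$ss, kinetic = res$kinetic,
              potential = res$potential, final = final,
              positions = res$positions, config = config)
  class(out) <- "ion_trajectory"
  out
}

#' @export
print.ion_trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("<ion_trajectory> %d frames to %.4g fs; S-S %.3f -> %.3f A\n",
              nt, x$times[nt], x$ss[1], x$ss[nt]))
  invisible(x)
}

#' @export
plot.ion_trajectory <- function(x, ...) {
  plot(x$times, x$ss, type = "l", xlab = "time (fs)",
       ylab = "S-S distance (A)", ...)
  invisible(x)
}

#' Write a trajectory as multi-frame XYZ plus a CSV summary
#'
#' The XYZ file holds one frame per output time (requires the trajectory to
#' have been integrated with `store_positions = TRUE`); the CSV holds
#' (time, ss_distance, kinetic, potential).
#'
#' @param traj an `ion_trajectory`
#' @param xyz_path,csv_path output paths (either may be `NULL` to skip)
#' @export
write_trajectory <- function(traj, xyz_path = NULL, csv_path = NULL) {
  if (!is.null(xyz_path)) {
    if (is.null(traj$positions))
      stop("trajectory was integrated without store_positions = TRUE")
    el <- traj$final$atoms$element
    con <- file(xyz_path, "w")
    on.exit(close(con))
    for (k in seq_along(traj$times)) {
      writeLines(c(as.character(length(el)),
                   sprintf("t = %.3f fs", traj$times[k])), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el,
                         traj$positions[k, , 1], traj$positions[k, , 2],
                         traj$positions[k, , 3]), con)
    }
  }
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(time = traj$times, ss_distance = traj$ss,
                                kinetic = traj$kinetic,
                                potential = traj$potential),
                     csv_path, row.names = FALSE)
  }
  invisible(traj)
}
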