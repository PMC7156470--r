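## plasma_model: mean-field rate equations for charge-state populations,
## trapped-electron density/temperature, spherical trapping geometry, and the
## Debye screening parameter handed to the ion dynamics.
##
## Channels (all one-way, no recombination in the continuum model):
##   photoionization  q -> q+1, K-shell fraction creates a K hole; the
##                    photoelectron (KE = E_photon - binding) is trapped and
##                    thermalized if its energy is below the crystal trapping
##                    barrier, else it escapes -- ionizing along its escape
##                    path (Lotz cross sections at the photoelectron energy
##                    over a mean escape chord), leaving slow trapped
##                    secondaries behind
##   Auger decay      consumes a K hole, q -> q+1; the Auger electron is a
##                    secondary: it thermalizes instantly (always trapped);
##                    the fluorescent branch consumes the hole silently
##   impact ionization q -> q+1 by the thermal trapped-electron gas (Lotz);
##                    the ejected electron joins the gas, the energy budget is
##                    debited by the binding energy
## Trapped electrons thermalize instantly: T_e = (2/3) * energy / count.

#' Initial charge-state populations for a composition
#'
#' @param composition named integer vector of atom counts per element (H, C,
#'   N, O, S), or a `sim_cell`
#' @return object of class `charge_populations`: per element an occupation
#'   vector over charge states 0..Z (all mass in q = 0) and a K-hole count
#' @export
new_charge_populations <- function(composition) {
  counts <- .as_composition(composition)
  el <- lapply(names(counts), function(sym) {
    Z <- .atomic_numbers[[sym]]
    P <- numeric(Z + 1)
    P[1] <- counts[[sym]]
    list(P = P, K = 0)
  })
  names(el) <- names(counts)
  out <- list(elements = el, counts = counts)
  class(out) <- "charge_populations"
  out
}

.as_composition <- function(composition) {
  if (inherits(composition, "sim_cell")) composition <- cell_composition(composition)
  composition <- composition[composition > 0]
  .check_elements(names(composition))
  composition
}

#' Mean charge per element of a populations object
#' @param pops a `charge_populations`
#' @return named numeric vector
#' @export
mean_charges <- function(pops) {
  vapply(pops$elements, function(e) {
    n <- sum(e$P)
    if (n == 0) 0 else sum((seq_along(e$P) - 1) * e$P) / n
  }, numeric(1))
}

#' Create a plasma state
#'
#' @param cell_volume supercell volume, A^3
#' @param sample_radius radius of the (spherical) irradiated crystal, A;
#'   default 1000 A = 100 nm, nanocrystal scale
#' @return object of class `plasma_state` with fields `time` (fs), `n_e`
#'   (A^-3), `T_e` (eV), `kappa` (A^-1), `escaped_charge` (net positive charge
#'   of the whole crystal, e), `escaped_per_cell`, `n_trapped` (electrons per
#'   supercell), `energy` (trapped-electron energy budget per supercell, eV),
#'   `sample_radius`, `cell_volume`
#' @export
new_plasma_state <- function(cell_volume, sample_radius = 1000) {
  stopifnot(cell_volume > 0, sample_radius > 0)
  out <- list(time = 0, n_e = 0, T_e = 0, kappa = 0,
              escaped_charge = 0, escaped_per_cell = 0,
              n_trapped = 0, energy = 0,
              sample_radius = sample_radius, cell_volume = cell_volume,
              n_cells = (4 / 3) * pi * sample_radius^3 / cell_volume)
  class(out) <- "plasma_state"
  out
}

#' Inverse Debye screening length of the trapped-electron gas
#'
#' `kappa = sqrt(4 pi k_e n_e / T_e)` in the eV-Angstrom unit system
#' (equivalently the inverse of the Debye length); zero for an empty plasma.
#'
#' @param n_e trapped-electron density, A^-3
#' @param T_e electron temperature, eV
#' @return kappa in A^-1
#' @export
screening_parameter <- function(n_e, T_e) {
  stopifnot(all(n_e >= 0))
  if (any(n_e > 0 & T_e <= 0)) stop("T_e must be positive when n_e > 0")
  ifelse(n_e > 0, sqrt(4 * pi * .ke * n_e / T_e), 0)
}

#' Decide the fate of an ejected electron
#'
#' The crystal is treated as a uniformly charged sphere: an electron born with
#' kinetic energy below the Coulomb barrier `k_e * Q_net / R` of the net
#' positive crystal charge is trapped and thermalizes; otherwise it escapes
#' (and deepens the barrier for later electrons).
#'
#' @param kinetic_energy electron kinetic energy at birth, eV
#' @param plasma a `plasma_state`
#' @return `"trapped"` or `"escaped"`
#' @export
electron_fate <- function(kinetic_energy, plasma) {
  stopifnot(kinetic_energy >= 0, inherits(plasma, "plasma_state"))
  barrier <- .ke * plasma$escaped_charge / plasma$sample_radius
  if (kinetic_energy < barrier) "trapped" else "escaped"
}

## ---- internal rate-equation machinery -------------------------------------

## Precomputed per-composition context.  All charge-state slots of all
## elements are concatenated into one vector of length M so the derivative is
## a handful of vectorized operations; K-hole counts follow as one slot per
## element.  Secondary electrons (Auger, impact) thermalize instantly and are
## always trapped; only photoelectrons are tested against the trapping
## barrier, at birth, with their full kinetic energy.
.rq_context <- function(composition, rates, cell_volume, sample_radius,
                        trapping = TRUE, pe_path = TRUE,
                        path_fraction = 0.75) {
  counts <- .as_composition(composition)
  Eph <- rates$photon_energy * 1000
  nel <- length(counts)
  sig <- kfrac <- EpeK <- EpeV <- B <- pref <- numeric(0)
  elem_id <- integer(0)   # element index per slot
  lastslot <- logical(0)  # TRUE for the fully stripped slot of each element
  iP <- list()
  rA <- fy <- EA <- Zs <- numeric(nel)
  off <- 0L
  for (k in seq_len(nel)) {
    sym <- names(counts)[k]
    ed <- .get_element(rates, sym)
    Z <- ed$Z
    iP[[sym]] <- off + seq_len(Z + 1)
    sig <- c(sig, ed$photo_cross_section)
    kf <- rep(ed$k_fraction, Z + 1)
    kf[ed$kshell_binding >= Eph] <- 0
    kfrac <- c(kfrac, kf)
    EpeK <- c(EpeK, pmax(Eph - ed$kshell_binding, 0))
    EpeV <- c(EpeV, pmax(Eph - c(ed$valence_binding, Eph), 0))
    Bq <- c(ed$valence_binding, 1e9)          # stripped slot: no channel
    B <- c(B, Bq)
    nv <- c(.outer_electrons(Z - (0:(Z - 1))), 0)
    pref <- c(pref, (2 / sqrt(pi)) * (.lotz_A * nv / Bq) * sqrt(2 / .me))
    elem_id <- c(elem_id, rep(k, Z + 1))
    lastslot <- c(lastslot, rep(FALSE, Z), TRUE)
    rA[k] <- ed$auger_rate; fy[k] <- ed$fluorescence_yield
    EA[k] <- ed$auger_energy; Zs[k] <- Z
    off <- off + Z + 1L
  }
  M <- off
  ind <- matrix(0, M, nel)                    # slot -> element indicator
  ind[cbind(seq_len(M), elem_id)] <- 1
  ## Lotz cross sections at a representative photoelectron energy, used for
  ## collisional ionization along the escape path of escaping photoelectrons
  nv_all <- .outer_electrons(
    unlist(lapply(seq_len(nel), function(k) {
      Z <- .atomic_numbers[[names(counts)[k]]]
      c(Z - (0:(Z - 1)), 0)
    })))
  E_path <- Eph - 500
  sig_path <- if (pe_path) .lotz_sigma(rep(E_path, M), B, nv_all) else numeric(M)
  list(counts = counts, syms = names(counts), nel = nel, M = M, iP = iP,
       sig = sig, kfrac = kfrac, EpeK = EpeK, EpeV = EpeV, B = B,
       sig_path = sig_path, path_len = path_fraction * sample_radius,
       pref = pref, elem_id = elem_id, notlast = !lastslot, ind = ind,
       rA = rA, fy = fy, EA = EA, Z = Zs,
       i_K = M + seq_len(nel), i_Ne = M + nel + 1L, i_E = M + nel + 2L,
       i_esc = M + nel + 3L, nstate = M + nel + 3L,
       V = cell_volume, R = sample_radius,
       ncells = (4 / 3) * pi * sample_radius^3 / cell_volume,
       trapping = trapping)
}

.rq_pack <- function(pops, ctx) {
  y <- numeric(ctx$nstate)
  for (k in seq_len(ctx$nel)) {
    sym <- ctx$syms[k]
    y[ctx$iP[[sym]]] <- pops$elements[[sym]]$P
    y[ctx$i_K[k]] <- pops$elements[[sym]]$K
  }
  y
}

.rq_deriv <- function(y, flux_val, ctx) {
  M <- ctx$M
  P <- y[seq_len(M)]
  K <- y[ctx$i_K]
  Ne <- y[ctx$i_Ne]; Eb <- y[ctx$i_E]; esc <- y[ctx$i_esc]
  Te <- if (Ne > 1e-12) max(0, (2 / 3) * Eb / Ne) else 0
  n_e <- Ne / ctx$V
  barrier <- if (ctx$trapping) .ke * (esc * ctx$ncells) / ctx$R else -1
  dP <- numeric(M); dK <- numeric(ctx$nel)
  dNe <- 0; dE <- 0; desc <- 0
  ## photoionization (K and valence branches; photoelectron vs barrier)
  if (flux_val > 0) {
    f <- P * (ctx$sig * flux_val)
    fK <- f * ctx$kfrac
    fV <- f - fK
    dP <- dP - f
    dP[-1] <- dP[-1] + f[-M]      # element boundaries carry zero flux
    dK <- dK + as.numeric(crossprod(ctx$ind, fK))
    tK <- ctx$EpeK < barrier; tV <- ctx$EpeV < barrier
    trapped_n <- sum(fK * tK) + sum(fV * tV)
    dNe <- dNe + trapped_n
    dE <- dE + sum(fK * ctx$EpeK * tK) + sum(fV * ctx$EpeV * tV)
    esc_rate <- sum(fK) + sum(fV) - trapped_n
    desc <- desc + esc_rate
    ## escaping photoelectrons ionize along their escape chord; the slow
    ## knock-on secondaries stay behind and thermalize
    if (esc_rate > 0 && ctx$path_len > 0) {
      fS <- (esc_rate * ctx$path_len / ctx$V) * P * ctx$sig_path
      dP <- dP - fS
      dP[-1] <- dP[-1] + fS[-M]
      dNe <- dNe + sum(fS)
      dE <- dE + sum(fS * ctx$B)   # mean knock-on energy ~ binding energy
    }
  }
  ## K-hole decay: Auger ionizes (electron always trapped), fluorescence not
  act <- K * ctx$rA > 1e-300
  if (any(act)) {
    segsum <- as.numeric(crossprod(ctx$ind, P * ctx$notlast))
    augtot <- K * ctx$rA * (1 - ctx$fy)
    scale <- ifelse(act & segsum > 1e-300, augtot / segsum, 0)
    fA <- P * ctx$notlast * scale[ctx$elem_id]
    dP <- dP - fA
    dP[-1] <- dP[-1] + fA[-M]
    dK <- dK - K * ctx$rA
    aug_n <- as.numeric(crossprod(ctx$ind, fA))
    dNe <- dNe + sum(aug_n)
    dE <- dE + sum(aug_n * ctx$EA)
  }
  ## impact ionization by the trapped gas (secondary stays in the gas)
  if (n_e > 0 && Te > 0) {
    sv <- ctx$pref / sqrt(Te) * .expint_e1(ctx$B / Te)
    fI <- P * (n_e * sv)
    dP <- dP - fI
    dP[-1] <- dP[-1] + fI[-M]
    dNe <- dNe + sum(fI)
    dE <- dE - sum(fI * ctx$B)
  }
  c(dP, dK, dNe, dE, desc)
}

## one RK4 step with halving on negativity
.rq_step <- function(y, t, dt, flux_fun, ctx, depth = 0L) {
  f1 <- flux_fun(t); f2 <- flux_fun(t + dt / 2); f3 <- flux_fun(t + dt)
  k1 <- .rq_deriv(y, f1, ctx)
  k2 <- .rq_deriv(y + dt / 2 * k1, f2, ctx)
  k3 <- .rq_deriv(y + dt / 2 * k2, f2, ctx)
  k4 <- .rq_deriv(y + dt * k3, f3, ctx)
  y1 <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (min(y1) < -1e-8) {
    if (depth >= 12L)
      stop("rate-equation integration failed: negative occupation at t = ", t)
    yh <- .rq_step(y, t, dt / 2, flux_fun, ctx, depth + 1L)
    return(.rq_step(yh, t + dt / 2, dt / 2, flux_fun, ctx, depth + 1L))
  }
  y1[y1 < 0] <- 0
  y1
}

.rq_unpack <- function(y, ctx) {
  el <- lapply(seq_len(ctx$nel), function(k)
    list(P = y[ctx$iP[[ctx$syms[k]]]], K = y[ctx$i_K[k]]))
  names(el) <- ctx$syms
  pops <- list(elements = el, counts = ctx$counts)
  class(pops) <- "charge_populations"
  pops
}

#' Advance the coupled rate equations by one step
#'
#' Single fixed step (internally sub-divided if an occupation would go
#' negative) of the coupled photoionization / Auger / impact-ionization rate
#' equations, with electron trapping decided against the instantaneous
#' spherical-crystal barrier and instantaneous thermalization of trapped
#' electrons.
#'
#' @param pops a `charge_populations`
#' @param plasma a `plasma_state`
#' @param rates a `rate_table`
#' @param flux instantaneous photon flux (photons/A^2/fs), held constant over
#'   the step, or a function of time `flux(t)`
#' @param dt step, fs
#' @param trapping if `FALSE`, every ejected electron escapes with its full
#'   energy and no plasma forms (photoionization-only limit)
#' @param pe_path enable collisional ionization along the escape path of
#'   escaping photoelectrons
#' @param path_fraction mean escape chord length as a fraction of the crystal
#'   radius (default 0.75)
#' @return list with updated `pops` and `plasma`
#' @export
advance_rate_equations <- function(pops, plasma, rates, flux, dt,
                                   trapping = TRUE, pe_path = TRUE,
                                   path_fraction = 0.75) {
  stopifnot(inherits(pops, "charge_populations"),
            inherits(plasma, "plasma_state"), dt > 0)
  ctx <- .rq_context(pops$counts, rates, plasma$cell_volume,
                     plasma$sample_radius, trapping,
                     pe_path = pe_path && trapping,
                     path_fraction = path_fraction)
  y <- .rq_pack(pops, ctx)
  y[ctx$i_Ne] <- plasma$n_trapped
  y[ctx$i_E] <- plasma$energy
  y[ctx$i_esc] <- plasma$escaped_per_cell
  flux_fun <- if (is.function(flux)) flux else function(t) flux
  y1 <- .rq_step(y, plasma$time, dt, flux_fun, ctx)
  new_pops <- .rq_unpack(y1, ctx)
  pl <- plasma
  pl$time <- plasma$time + dt
  pl$n_trapped <- y1[ctx$i_Ne]
  pl$energy <- max(0, y1[ctx$i_E])
  pl$escaped_per_cell <- y1[ctx$i_esc]
  pl$escaped_charge <- pl$escaped_per_cell * ctx$ncells
  pl$n_e <- pl$n_trapped / ctx$V
  pl$T_e <- if (pl$n_trapped > 1e-12) (2 / 3) * pl$energy / pl$n_trapped else 0
  pl$kappa <- if (pl$T_e > 0) screening_parameter(pl$n_e, pl$T_e) else 0
  list(pops = new_pops, plasma = pl)
}

#' Integrate the rate equations through a pulse pair
#'
#' Drives [advance_rate_equations()] (as a single packed RK4 loop) from t = 0
#' to `t_end`, recording the populations and plasma parameters on a regular
#' output grid.
#'
#' @param composition named atom counts or a `sim_cell`
#' @param pulses a [pulse_pair()]
#' @param rates a `rate_table` (default: packaged table)
#' @param t_end end time, fs (default: probe centre)
#' @param dt integration step, fs
#' @param stride output stride, fs
#' @param cell_volume supercell volume, A^3 (taken from the cell if one is
#'   given)
#' @param sample_radius crystal radius for the trapping geometry, A
#' @param trapping disable to let every electron escape (no plasma at all)
#' @param pe_path,path_fraction escape-path ionization by escaping
#'   photoelectrons (see [advance_rate_equations()])
#' @return object of class `plasma_history`: output `times`; per-element
#'   occupation history `pops` (list of matrices, time x charge state);
#'   `mean_charge` (time x element); vectors `n_e`, `T_e`, `kappa`,
#'   `escaped_charge` (crystal), `n_trapped`, `energy`; `final` populations;
#'   the `composition` and geometry used
#' @export
run_rate_equations <- function(composition, pulses, rates = default_rate_table(),
                               t_end = NULL, dt = 0.02, stride = 0.5,
                               cell_volume = NULL, sample_radius = 1000,
                               trapping = TRUE, pe_path = TRUE,
                               path_fraction = 0.75) {
  if (inherits(composition, "sim_cell")) {
    if (is.null(cell_volume) && is.finite(composition$edge_length))
      cell_volume <- composition$edge_length^3
    composition <- cell_composition(composition)
  }
  if (is.null(cell_volume)) stop("cell_volume required when composition is a count vector")
  if (is.null(t_end)) t_end <- pulses$pump_center + pulses$delay
  ctx <- .rq_context(composition, rates, cell_volume, sample_radius, trapping,
                     pe_path = pe_path && trapping,
                     path_fraction = path_fraction)
  pops0 <- new_charge_populations(composition)
  y <- .rq_pack(pops0, ctx)
  flux_fun <- function(t) pulse_flux(pulses, t)

  nstep <- max(1L, as.integer(ceiling(t_end / dt - 1e-9)))
  dt <- t_end / nstep
  rec_every <- max(1L, as.integer(round(stride / dt)))
  nrec <- nstep %/% rec_every + 2L   # initial state + strides + final step
  times <- numeric(nrec)
  esym <- ctx$syms
  pops_hist <- lapply(stats::setNames(seq_len(ctx$nel), esym),
                      function(k) matrix(0, nrec, ctx$Z[k] + 1))
  scal <- matrix(0, nrec, 5,
                 dimnames = list(NULL, c("n_e", "T_e", "kappa",
                                         "escaped_charge", "n_trapped")))
  energy <- numeric(nrec)

  rec <- function(k, y, t) {
    times[k] <<- t
    Ne <- y[ctx$i_Ne]; Eb <- max(0, y[ctx$i_E])
    Te <- if (Ne > 1e-12) (2 / 3) * Eb / Ne else 0
    ne <- Ne / ctx$V
    scal[k, ] <<- c(ne, Te, if (Te > 0) screening_parameter(ne, Te) else 0,
                    y[ctx$i_esc] * ctx$ncells, Ne)
    energy[k] <<- Eb
    for (s in esym) pops_hist[[s]][k, ] <<- y[ctx$iP[[s]]]
  }
  rec(1L, y, 0)
  k <- 1L
  for (i in seq_len(nstep)) {
    y <- .rq_step(y, (i - 1) * dt, dt, flux_fun, ctx)
    if (i %% rec_every == 0L || i == nstep) {
      k <- k + 1L
      rec(k, y, i * dt)
    }
  }
  times <- times[1:k]
  mean_charge <- sapply(esym, function(s) {
    P <- pops_hist[[s]][1:k, , drop = FALSE]
    as.numeric(P %*% (seq_len(ncol(P)) - 1)) / ctx$counts[[s]]
  })
  out <- list(times = times,
              pops = lapply(pops_hist, function(m) m[1:k, , drop = FALSE]),
              mean_charge = mean_charge,
              n_e = scal[1:k, "n_e"], T_e = scal[1:k, "T_e"],
              kappa = scal[1:k, "kappa"],
              escaped_charge = scal[1:k, "escaped_charge"],
              n_trapped = scal[1:k, "n_trapped"], energy = energy[1:k],
              final = .rq_unpack(y, ctx),
              composition = ctx$counts, cell_volume = cell_volume,
              sample_radius = sample_radius, pulses = pulses, dt = dt)
  class(out) <- "plasma_history"
  out
}

#' @export
print.plasma_history <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<plasma_history> %d outputs over %.4g fs (dt = %.3g fs)\n",
              n, x$times[n], x$dt))
  mc <- x$mean_charge[n, ]
  cat("  final mean charges:",
      paste(sprintf("%s %.3f", colnames(x$mean_charge), mc), collapse = ", "), "\n")
  cat(sprintf("  final n_e = %.4g /A^3, T_e = %.4g eV, kappa = %.4g /A, escaped = %.4g e\n",
              x$n_e[n], x$T_e[n], x$kappa[n], x$escaped_charge[n]))
  invisible(x)
}

#' @export
as.data.frame.plasma_history <- function(x, ...) {
  data.frame(time = x$times, x$mean_charge, n_e = x$n_e, T_e = x$T_e,
             kappa = x$kappa, escaped_charge = x$escaped_charge,
             check.names = FALSE)
}

#' @export
plot.plasma_history <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  matplot(x$times, x$mean_charge, type = "l", lty = 1, xlab = "time (fs)",
          ylab = "mean charge (e)", main = "mean charge per element", ...)
  legend("topleft", colnames(x$mean_charge), col = seq_len(ncol(x$mean_charge)),
         lty = 1, bty = "n", cex = 0.8)
  plot(x$times, x$n_e, type = "l", xlab = "time (fs)", ylab = "n_e (1/A^3)",
       main = "trapped-electron density")
  plot(x$times, x$T_e, type = "l", xlab = "time (fs)", ylab = "T_e (eV)",
       main = "electron temperature")
  plot(x$times, x$kappa, type = "l", xlab = "time (fs)", ylab = "kappa (1/A)",
       main = "inverse screening length")
  invisible(x)
}

#' Write a plasma history as CSV
#' @param x a `plasma_history`
#' @param path output path
#' @export
write_plasma_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Sample per-atom charge staircases from mean-field populations
#'
#' Realizes integer per-atom charge trajectories Q_i(t) consistent with the
#' rate-equation populations: each atom draws an independent uniform level u
#' and carries, at every time, the u-quantile of its element's charge-state
#' distribution — a monotone non-decreasing integer staircase (the one-way
#' rate equations shift the distribution upward in time) whose marginal
#' matches the populations exactly at every time, with atoms ionizing
#' independently of one another as in an explicit stochastic treatment.
#'
#' @param pops_history a `plasma_history`
#' @param cell a `sim_cell` whose elements are covered by the history
#' @param seed integer seed
#' @param mode `"sampled"` (integer staircases) or `"mean"` (every atom carries
#'   its element's real-valued mean charge)
#' @return object of class `charge_trajectories`: list with `times` and
#'   `charges`, an atoms x times matrix
#' @export
sample_ion_charges <- function(pops_history, cell, seed = NULL,
                               mode = c("sampled", "mean")) {
  stopifnot(inherits(pops_history, "plasma_history"), inherits(cell, "sim_cell"))
  mode <- match.arg(mode)
  elems <- cell$atoms$element
  missing_el <- setdiff(unique(elems), colnames(pops_history$mean_charge))
  if (length(missing_el))
    stop("populations do not cover element(s): ", paste(missing_el, collapse = ", "))
  nt <- length(pops_history$times)
  n <- length(elems)
  ch <- matrix(0, n, nt)
  if (mode == "mean") {
    for (sym in unique(elems)) {
      idx <- which(elems == sym)
      ch[idx, ] <- matrix(pops_history$mean_charge[, sym], length(idx), nt,
                          byrow = TRUE)
    }
  } else {
    with_seed(seed, {
      for (sym in unique(elems)) {
        idx <- which(elems == sym)
        m <- length(idx)
        u <- runif(m)
        P <- pops_history$pops[[sym]]
        tot <- sum(P[1, ])
        cdf <- t(apply(P, 1, cumsum)) / tot     # nt x (Z+1)
        ## q_i(t) = number of cdf levels strictly below u_i
        for (k in seq_len(nt)) {
          ch[idx, k] <- findInterval(u, cdf[k, ], left.open = FALSE)
        }
      }
    })
    ## enforce monotone staircases against numerical wiggle
    if (nt > 1) for (i in seq_len(n)) ch[i, ] <- cummax(ch[i, ])
  }
  out <- list(times = pops_history$times, charges = ch, mode = mode)
  class(out) <- "charge_trajectories"
  out
}
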