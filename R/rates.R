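## ionization_rates: per-element, per-charge-state rates for photoionization,
## K-hole (Auger) decay and electron-impact ionization, at the pulse photon
## energy.  The atomic data live in a versioned JSON resource shipped with the
## package and can be overridden by path.

.lotz_A <- 450      # Lotz constant, eV^2 A^2 per outer-shell electron (4.5e-14 cm^2 eV^2)

## number of electrons in the outermost occupied shell for an ion with nel
## electrons (shell filling 2/8/8, adequate for Z <= 18)
.outer_electrons <- function(nel) {
  ifelse(nel <= 0, 0, ifelse(nel <= 2, nel, ifelse(nel <= 10, nel - 2, nel - 10)))
}

#' Load the element rate table
#'
#' Reads the per-element atomic data (photoionization cross sections at the
#' pulse photon energy, K-shell binding energies, K-hole decay rates and
#' fluorescence yields, successive ionization energies) and expands them into
#' per-charge-state arrays.  The charge-state dependence of the photo cross
#' section uses a screened-hydrogenic electron-count scaling
#' sigma(q) = sigma(0) (Z-q)/Z; K-shell binding energies are ramped by
#' +12 eV per unit charge.  Both scalings are crude but inconsequential: the
#' photo channel contributes well under one event per light atom per pulse.
#'
#' @param path optional path to a JSON table overriding the packaged resource
#' @return object of class `rate_table`: a list with `photon_energy` (keV) and
#'   `elements`, a named list of `element_data` objects with fields
#'   `symbol`, `Z`, `mass`, `photo_cross_section` (A^2, index q+1 for charge
#'   state q = 0..Z), `k_fraction`, `kshell_binding` (eV, per q),
#'   `valence_binding` (eV, entry q+1 = lowest ionization energy of charge
#'   state q, strictly increasing), `auger_rate` (fs^-1, total K-hole decay),
#'   `fluorescence_yield`, `auger_energy` (eV).
#' @export
default_rate_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rate_table_7.14keV.json", package = "plasmaMD")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  elements <- lapply(names(raw$elements), function(sym) {
    e <- raw$elements[[sym]]
    Z <- as.integer(e$Z)
    ie <- as.numeric(e$ionization_energies)
    if (length(ie) != Z) stop("rate table: ", sym, " needs ", Z, " ionization energies")
    if (any(diff(ie) <= 0)) stop("rate table: ", sym, " ionization energies must increase")
    q <- 0:Z
    ed <- list(
      symbol = sym, Z = Z, mass = e$mass,
      photo_cross_section = e$photo_xs * (Z - q) / Z,
      k_fraction = e$k_fraction,
      kshell_binding = e$kshell_binding + 12 * q,
      valence_binding = ie,
      auger_rate = e$auger_rate,
      fluorescence_yield = e$fluorescence_yield,
      auger_energy = e$auger_energy
    )
    class(ed) <- "element_data"
    ed
  })
  names(elements) <- names(raw$elements)
  out <- list(photon_energy = raw$photon_energy_keV, elements = elements,
              version = raw$version)
  class(out) <- "rate_table"
  out
}

#' @export
print.rate_table <- function(x, ...) {
  cat("Element rate table (version ", x$version, ") at ",
      x$photon_energy, " keV\n", sep = "")
  for (e in x$elements)
    cat(sprintf("  %-2s Z=%2d  sigma_ph(0)=%.2e A^2  K-hole rate=%.3f fs^-1\n",
                e$symbol, e$Z, e$photo_cross_section[1], e$auger_rate))
  invisible(x)
}

.get_element <- function(rates, symbol) {
  e <- rates$elements[[symbol]]
  if (is.null(e)) stop("element '", symbol, "' missing from rate table")
  e
}

#' Photoionization rate of a charge state
#'
#' The rate is the product of the tabulated cross section for charge state `q`
#' and the instantaneous photon flux; it vanishes for fully stripped ions.
#'
#' @param elem an `element_data` entry from [default_rate_table()]
#' @param q charge state (0..Z)
#' @param flux instantaneous photon flux, photons/A^2/fs
#' @return rate in fs^-1
#' @export
photoionization_rate <- function(elem, q, flux) {
  stopifnot(inherits(elem, "element_data"), all(flux >= 0))
  if (any(q < 0 | q > elem$Z)) stop("charge state out of range for ", elem$symbol)
  elem$photo_cross_section[q + 1L] * flux
}

#' Auger (K-hole) decay rate
#'
#' Effective non-radiative decay rate of `kholes` independent K-shell holes:
#' `kholes * auger_rate * (1 - fluorescence_yield)`.  The radiative branch
#' re-emits a photon that is not tracked further (no reabsorption).
#'
#' @param elem an `element_data` entry
#' @param kholes number of K-shell holes (0, 1 or 2)
#' @return rate in fs^-1
#' @export
auger_decay_rate <- function(elem, kholes) {
  stopifnot(inherits(elem, "element_data"), all(kholes %in% 0:2))
  kholes * elem$auger_rate * (1 - elem$fluorescence_yield)
}

## Lotz impact-ionization cross section (A^2) for electron energy E (eV) and
## binding energy B (eV), nv outer-shell electrons
.lotz_sigma <- function(E, B, nv) {
  n <- max(length(E), length(B), length(nv))
  E <- rep_len(E, n); B <- rep_len(B, n); nv <- rep_len(nv, n)
  s <- numeric(n)
  ok <- E > B
  s[ok] <- .lotz_A * nv[ok] * log(E[ok] / B[ok]) / (E[ok] * B[ok])
  s
}

## Maxwellian-averaged <sigma v> (A^3/fs) by numerical quadrature.
## f(E) = 2 sqrt(E/pi) (kT)^(-3/2) exp(-E/kT); v(E) = sqrt(2 E / m_e).
.lotz_sigmav_quad <- function(B, T_e, nv) {
  if (nv <= 0 || T_e <= 0) return(0)
  b <- B / T_e
  if (b > 500) return(0)   # Maxwellian tail above threshold underflows
  integrand <- function(E)
    .lotz_sigma(E, B, nv) * sqrt(2 * E / .me) *
      2 * sqrt(E / pi) * T_e^(-1.5) * exp(-E / T_e)
  upper <- B + 30 * T_e
  stats::integrate(integrand, lower = B, upper = upper,
                   rel.tol = 1e-8, stop.on.error = FALSE)$value
}

## Closed form of the same average: <sigma v> =
## (A nv / B) sqrt(2/(pi me)) * 2/sqrt(2) ... reduces to
## (2/sqrt(pi)) (A nv / B) sqrt(2/me) T^(-1/2) E1(B/T),
## with E1 the exponential integral.  Used as the fast path inside the
## rate-equation integrator; agreement with the quadrature is tested.
.expint_e1 <- function(x) {
  ## Abramowitz & Stegun 5.1.53 / 5.1.56 rational approximations
  out <- numeric(length(x))
  lo <- x <= 1 & x > 0
  hi <- x > 1
  if (any(lo)) {
    t <- x[lo]
    out[lo] <- -log(t) - 0.57721566 + t * (0.99999193 + t * (-0.24991055 +
                 t * (0.05519968 + t * (-0.00976004 + t * 0.00107857))))
  }
  if (any(hi)) {
    t <- x[hi]
    num <- t^2 + 2.334733 * t + 0.250621
    den <- t^2 + 3.330657 * t + 1.681534
    out[hi] <- exp(-t) / t * num / den
  }
  out[x > 500] <- 0
  out
}

.lotz_sigmav_closed <- function(B, T_e, nv) {
  if (T_e <= 0) return(B * 0)
  (2 / sqrt(pi)) * (.lotz_A * nv / B) * sqrt(2 / .me) / sqrt(T_e) *
    .expint_e1(B / T_e)
}

#' Electron-impact ionization rate (Lotz form)
#'
#' Rate of collisional ionization of charge state `q` immersed in a thermal
#' electron gas of density `n_e` and temperature `T_e`:
#' `n_e * <sigma_imp v>` with the Lotz cross section
#' `sigma(E) = a * nv * ln(E/B) / (E B)` for `E > B`, Maxwellian-averaged by
#' numerical quadrature.  `B` is the lowest ionization energy of charge state
#' `q` and `nv` the number of outer-shell electrons; the Lotz constant is
#' `a = 4.5e-14 cm^2 eV^2`.
#'
#' @param elem an `element_data` entry
#' @param q charge state (0..Z)
#' @param n_e trapped-electron density, A^-3
#' @param T_e electron temperature, eV
#' @param method `"quadrature"` (reference) or `"closed"` (exponential-integral
#'   closed form of the same average, used internally for speed)
#' @return rate in fs^-1
#' @export
impact_ionization_rate <- function(elem, q, n_e, T_e,
                                   method = c("quadrature", "closed")) {
  stopifnot(inherits(elem, "element_data"), n_e >= 0)
  method <- match.arg(method)
  if (q >= elem$Z) return(0)
  if (n_e == 0) return(0)
  if (T_e <= 0) stop("T_e must be positive when n_e > 0")
  B <- elem$valence_binding[q + 1L]
  nv <- .outer_electrons(elem$Z - q)
  sv <- if (method == "quadrature") .lotz_sigmav_quad(B, T_e, nv)
        else .lotz_sigmav_closed(B, T_e, nv)
  n_e * sv
}
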