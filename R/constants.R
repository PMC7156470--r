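#' @useDynLib plasmaMD, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats integrate lm coef rexp runif sd splinefun approx setNames
#' @importFrom utils read.csv write.csv head tail
#' @importFrom graphics lines legend matplot abline points par segments
#' @keywords internal
"_PACKAGE"

## Unit system, fixed package-wide: length in Angstrom, time in fs, energy in eV,
## charge in elementary charges, mass in atomic mass units (u).

#' Physical constants of the package unit system
#'
#' The package works in Angstrom / femtosecond / electronvolt / elementary
#' charge / atomic mass unit throughout.  `ke` is the Coulomb constant
#' e^2/(4 pi eps0) expressed in eV*Angstrom; `acc` converts a force in eV/A
#' acting on a mass in u into an acceleration in A/fs^2 (equivalently,
#' 1 u A^2/fs^2 = 103.6427 eV); `me` is the electron mass in eV fs^2/A^2,
#' used to convert electron kinetic energies to speeds.
#'
#' @return Named list with elements `ke` (eV*A), `acc` (A/fs^2 per eV/A/u),
#'   `u_A2fs2_eV` (eV per u*A^2/fs^2), `me` (eV fs^2/A^2).
#' @examples
#' md_constants()$ke  # 14.3996
#' @export
md_constants <- function() {
  list(
    ke         = 14.3996,          # Coulomb constant, eV*Angstrom
    u_A2fs2_eV = 103.6427,         # 1 u (A/fs)^2 in eV
    acc        = 1 / 103.6427,     # (eV/A)/u -> A/fs^2
    me         = 0.0568563         # electron mass, eV fs^2/A^2 (=511 keV/c^2)
  )
}

.ke     <- 14.3996
.u2eV   <- 103.6427
.accf   <- 1 / 103.6427
.me     <- 0.0568563

## Elements handled by the simulator (Z <= 16 shell filling 2/8/8)
.element_symbols <- c("H", "C", "N", "O", "S")

.atomic_numbers <- c(H = 1L, C = 6L, N = 7L, O = 8L, S = 16L)

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

## Single-bond covalent radii (Angstrom), used for collision-potential contact
## radii r_e = r_cov(i) + r_cov(j).
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)

.check_elements <- function(elements) {
  bad <- setdiff(unique(elements), .element_symbols)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(.element_symbols, collapse = ", "), ")")
  invisible(TRUE)
}

#' Convert a fluence from photons per square micron to photons per square Angstrom
#'
#' Experimental XFEL fluences are conventionally quoted in photons/um^2; the
#' simulator works in photons/A^2 (1 um^2 = 1e8 A^2).
#'
#' @param f_um2 fluence in photons/um^2
#' @return fluence in photons/A^2
#' @examples
#' fluence_per_A2(8.8e11)   # low-fluence case, 8800 photons/A^2
#' @export
fluence_per_A2 <- function(f_um2) f_um2 / 1e8

#' Experimental total-fluence cases
#'
#' The three total pump+probe fluences used in the study conditions:
#' maximum 7.0e12, medium 4.4e12 and low 8.8e11 photons/um^2.
#'
#' @param units `"um2"` (photons/um^2, as printed) or `"A2"` (photons/A^2,
#'   simulation units)
#' @return named numeric vector with elements `low`, `med`, `max`
#' @export
fluence_cases <- function(units = c("um2", "A2")) {
  units <- match.arg(units)
  f <- c(low = 8.8e11, med = 4.4e12, max = 7.0e12)
  if (units == "A2") f <- fluence_per_A2(f)
  f
}

## Internal seeded-RNG helper: evaluates `expr` with the RNG seeded to `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

## Deterministic per-trajectory seed derivation from a master seed (documented
## scheme: seed_i = (master + 7919 * i) mod (2^31 - 1), i = 1..n).
derive_seeds <- function(master_seed, n, stream = 0L) {
  master_seed <- as.double(master_seed)
  ((master_seed + 104729 * as.double(stream) + 7919 * seq_len(n)) %% 2147483647)
}
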