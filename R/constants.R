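#' @keywords internal
#' @useDynLib gmmnea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## CODATA 2018 values; energies at the user interface are always eV.
.EV_PER_HARTREE <- 27.211386245988
.EV_NM <- 1239.841984 # hc in eV * nm

## SI constants entering the physical cross-section prefactor
.E_CHARGE <- 1.602176634e-19     # C
.HBAR <- 1.054571817e-34         # J s
.M_ELECTRON <- 9.1093837015e-31  # kg
.C_LIGHT <- 2.99792458e8         # m / s
.EPS0 <- 8.8541878128e-12        # F / m

#' Physical constants and prefactor convention for cross sections
#'
#' Bundles the unit conventions shared by the discrete and GMM spectrum
#' builders. In `"arbitrary"` mode the cross-section prefactor is just the
#' dimensionally required `1/E` factor, so spectra are in arbitrary units but
#' every shape-based metric (RIC, bRIC, bootstrap bands) is exact. In
#' `"physical"` mode the prefactor additionally carries
#' `pi * e^2 * hbar / (2 m c eps0 n_r)` and spectra come out in cm^2,
#' as required for photolysis rates.
#'
#' @param prefactor_mode `"arbitrary"` (default) or `"physical"`.
#' @param n_r refractive index of the medium (no optical dispersion assumed);
#'   must be positive. Only used in physical mode.
#' @return An object of class `nea_constants`.
#' @export
nea_constants <- function(prefactor_mode = c("arbitrary", "physical"), n_r = 1) {
  prefactor_mode <- match.arg(prefactor_mode)
  if (!is.numeric(n_r) || length(n_r) != 1L || !is.finite(n_r) || n_r <= 0)
    stop("`n_r` must be a single positive number", call. = FALSE)
  structure(
    list(prefactor_mode = prefactor_mode, n_r = n_r,
         ev_per_hartree = .EV_PER_HARTREE),
    class = "nea_constants"
  )
}

#' @export
print.nea_constants <- function(x, ...) {
  cat("<nea_constants> prefactor_mode =", x$prefactor_mode,
      " n_r =", x$n_r, "\n")
  invisible(x)
}

## C(E): the energy-dependent prefactor multiplying the ensemble kernel sum.
## E in eV; returns either 1/E (arbitrary units) or the full physical factor
## such that sigma comes out in cm^2 when the sum carries dE[eV] * f * g[1/eV].
cross_section_prefactor <- function(E, constants) {
  stopifnot(inherits(constants, "nea_constants"))
  if (any(E <= 0)) stop("photon energies must be positive", call. = FALSE)
  if (constants$prefactor_mode == "arbitrary") return(1 / E)
  ## pi e^2 hbar / (2 m c eps0 n_r) has units J m^2; dividing by the charge
  ## (J per eV) and multiplying by 1e4 converts to cm^2 eV for an eV-grid sum.
  pref <- pi * .E_CHARGE^2 * .HBAR /
    (2 * .M_ELECTRON * .C_LIGHT * .EPS0 * constants$n_r)
  pref / .E_CHARGE * 1e4 / E
}

#' Convert oscillator strength to transition dipole moment
#'
#' Uses `M^2 = 3 hbar^2 e^2 f / (2 m dE)`; in atomic units
#' `M = sqrt(3 f / (2 dE_Hartree))` with the energy supplied in eV.
#'
#' @param delta_E vertical excitation energies in eV, all positive.
#' @param f oscillator strengths (dimensionless, non-negative).
#' @return Transition dipole moments in atomic units, zero exactly where
#'   `f` is zero.
#' @seealso [strength_from_dipole()] for the exact inverse.
#' @export
#' @examples
#' dipole_from_strength(27.211386245988, 2 / 3) # 1 a.u. by construction
dipole_from_strength <- function(delta_E, f) {
  if (any(!is.finite(delta_E)) || any(delta_E <= 0))
    stop("`delta_E` must be positive and finite", call. = FALSE)
  if (any(!is.finite(f)) || any(f < 0))
    stop("`f` must be non-negative and finite", call. = FALSE)
  sqrt(3 * f / (2 * delta_E / .EV_PER_HARTREE))
}

#' Convert transition dipole moment back to oscillator strength
#'
#' @param delta_E vertical excitation energies in eV, all positive.
#' @param M transition dipole moments in atomic units, non-negative.
#' @return Oscillator strengths (dimensionless).
#' @export
strength_from_dipole <- function(delta_E, M) {
  if (any(!is.finite(delta_E)) || any(delta_E <= 0))
    stop("`delta_E` must be positive and finite", call. = FALSE)
  if (any(!is.finite(M)) || any(M < 0))
    stop("`M` must be non-negative and finite", call. = FALSE)
  (2 / 3) * (delta_E / .EV_PER_HARTREE) * M^2
}

## Run code with a private, restored RNG stream seeded from `seed`.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
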