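#' Ground-truth band mixture for synthetic ensembles
#'
#' A stated truth from which ensembles are drawn: a bivariate mixture over
#' (delta_E in eV, M in a.u.) plus a point mass `theta0` of forbidden
#' transitions. Component means must sit at least 4 standard deviations
#' above zero in both coordinates, keeping the positivity rejection rate
#' below ~1% so the realized density matches the evaluation density used
#' by the closed form.
#'
#' @param state transition index.
#' @param weights component weights (positive, summing to 1).
#' @param mu1,mu2 component means: energy (eV) and dipole (a.u.).
#' @param sd1,sd2 component standard deviations.
#' @param rho component correlation coefficients in (-1, 1).
#' @param theta0 probability of an exactly forbidden transition, in [0, 1).
#' @return a `band_truth`, which is also a valid `band_gmm` so
#'   [band_spectrum_gmm()] evaluates the analytic ground-truth spectrum
#'   directly.
#' @export
band_truth <- function(state, weights, mu1, mu2, sd1, sd2, rho = 0,
                       theta0 = 0) {
  K <- length(weights)
  rho <- rep_len(rho, K)
  stopifnot(length(mu1) == K, length(mu2) == K, length(sd1) == K,
            length(sd2) == K, all(weights > 0),
            abs(sum(weights) - 1) < 1e-10, all(sd1 > 0), all(sd2 > 0),
            all(abs(rho) < 1), theta0 >= 0, theta0 <= 1)
  if (any(mu1 < 4 * sd1) || any(mu2 < 4 * sd2))
    stop("component means must be >= 4 sd above zero in both coordinates ",
         "(positivity rejection would exceed ~1%)", call. = FALSE)
  sigma <- array(0, c(2, 2, K))
  for (k in seq_len(K)) {
    sigma[1, 1, k] <- sd1[k]^2
    sigma[2, 2, k] <- sd2[k]^2
    sigma[1, 2, k] <- sigma[2, 1, k] <- rho[k] * sd1[k] * sd2[k]
  }
  gmm <- structure(
    list(K = K, model = "VVV",
         ## dark truths keep raw weights so the energy marginal stays drawable
         pro = if (theta0 < 1) weights * (1 - theta0) else weights,
         mean = rbind(mu1, mu2, deparse.level = 0), sigma = sigma,
         loglik = NA_real_, n = NA_integer_, df = NA_integer_,
         bic = NA_real_),
    class = "gmm_params")
  structure(list(state = as.integer(state), theta0 = theta0, gmm = gmm,
                 dark = theta0 == 1),
            class = c("band_truth", "band_gmm"))
}

#' Demonstration fixture: three bands spanning the regimes of real data
#'
#' One unimodal correlated band, one bimodal band (two overlapping
#' electronic clusters), and one band with a 30% forbidden-transition
#' mass — the qualitative structures seen in computed (delta_E, f)
#' ensembles of small organic chromophores.
#'
#' @return list of three [band_truth()] objects (states 1-3).
#' @export
demo_truths <- function() {
  list(
    band_truth(1, weights = 1, mu1 = 4.5, mu2 = 0.80, sd1 = 0.15,
               sd2 = 0.10, rho = 0.3),
    band_truth(2, weights = c(0.6, 0.4), mu1 = c(5.5, 5.9),
               mu2 = c(0.50, 0.35), sd1 = c(0.12, 0.10),
               sd2 = c(0.06, 0.05), rho = c(-0.2, 0.2)),
    band_truth(3, weights = 1, mu1 = 6.5, mu2 = 0.40, sd1 = 0.20,
               sd2 = 0.08, rho = 0, theta0 = 0.3)
  )
}

#' Draw a synthetic ensemble from ground-truth band mixtures
#'
#' Per geometry and band: with probability `theta0` the transition is
#' forbidden (f = 0); otherwise (delta_E, M) is drawn from the truth
#' mixture with rejection of non-positive coordinates, and f is recovered
#' by inverting the dipole relation. Deterministic under `seed`.
#'
#' @param truths list of [band_truth()] objects with distinct states.
#' @param n_geoms number of geometries (>= 1).
#' @param seed integer seed.
#' @return an [ensemble_table()] with geometry ids `g00001`, ...
#' @export
sample_ensemble <- function(truths, n_geoms, seed = NULL) {
  n_geoms <- as.integer(n_geoms)
  stopifnot(n_geoms >= 1L, length(truths) >= 1L)
  states <- vapply(truths, `[[`, integer(1), "state")
  stopifnot(!anyDuplicated(states))
  ids <- sprintf("g%05d", seq_len(n_geoms))
  with_seed(seed, {
    tabs <- lapply(truths, function(tr) {
      allowed <- stats::runif(n_geoms) >= tr$theta0
      n_on <- sum(allowed)
      dE <- M <- numeric(n_geoms)
      ## dark rows still need a positive vertical energy
      dE[] <- pmax(.draw_mixture(tr$gmm, n_geoms)[, 1], 1e-6)
      if (n_on > 0L) {
        draws <- .draw_mixture_positive(tr$gmm, n_on)
        dE[allowed] <- draws[, 1]
        M[allowed] <- draws[, 2]
      }
      data.frame(geom_id = ids, state = tr$state, delta_E = dE,
                 f = strength_from_dipole(dE, M),
                 stringsAsFactors = FALSE)
    })
    ensemble_table(do.call(rbind, tabs))
  })
}

.draw_mixture <- function(gmm, n) {
  g <- gmm
  g$pro <- g$pro / sum(g$pro)
  gmm_simulate(g, n)
}

## Rejection of non-positive coordinates; the truth placement invariant
## keeps the rejection rate < ~1%, and > 10% aborts.
.draw_mixture_positive <- function(gmm, n) {
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  drawn <- 0L
  while (got < n) {
    m <- max(n - got, 64L)
    cand <- .draw_mixture(gmm, m)
    drawn <- drawn + m
    keep <- cand[, 1] > 0 & cand[, 2] > 0
    k <- which(keep)
    take <- utils::head(k, n - got)
    if (length(take)) {
      out[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
    if (drawn >= 256L && (drawn - got) / drawn > 0.10)
      stop("rejection rate above 10%: truth violates the positive-support ",
           "placement invariant", call. = FALSE)
  }
  out
}

#' Inject anomalous points into a synthetic ensemble
#'
#' Emulates a corrupted quantum-chemistry run: for `k` randomly chosen
#' geometries of one band, the dipole is inflated to `magnitude` robust
#' standard deviations (MAD) above the band median and f is recomputed.
#'
#' @param table an [ensemble_table()].
#' @param band transition index to corrupt.
#' @param k number of anomalies (< N_g / 10).
#' @param magnitude offset in robust-sd multiples (e.g. 10).
#' @param seed integer seed.
#' @return the modified ensemble, with attribute `injected_ids` giving the
#'   corrupted geometry ids for ground-truth evaluation of the screening.
#' @export
inject_outliers <- function(table, band, k, magnitude = 10, seed = NULL) {
  stopifnot(inherits(table, "nea_ensemble"))
  k <- as.integer(k)
  ng <- n_geometries(table)
  if (k < 0L || k >= ng / 10)
    stop("`k` must satisfy 0 <= k < N_g / 10", call. = FALSE)
  if (!band %in% ensemble_states(table))
    stop("band ", band, " not present in ensemble", call. = FALSE)
  if (k == 0L) {
    attr(table, "injected_ids") <- character(0)
    return(table)
  }
  s <- extract_band(table, band)
  m_med <- stats::median(s$M)
  m_sd <- stats::mad(s$M)
  if (m_sd == 0) stop("band has zero dipole spread", call. = FALSE)
  ids <- with_seed(seed, sample(s$geom_id, k))
  df <- as.data.frame(table)
  rows <- df$state == band & df$geom_id %in% ids
  M_new <- m_med + magnitude * m_sd
  df$f[rows] <- strength_from_dipole(df$delta_E[rows], M_new)
  out <- ensemble_table(df)
  attr(out, "injected_ids") <- sort(ids)
  out
}

#' Analytic ground-truth spectra of a set of band truths
#'
#' @param truths list of [band_truth()] objects.
#' @param grid an [energy_grid()].
#' @param constants an [nea_constants()] object.
#' @return a `full_spectrum` evaluated from the truths' closed forms.
#' @export
truth_spectrum <- function(truths, grid, constants = nea_constants()) {
  bands <- lapply(truths, band_spectrum_gmm, grid = grid,
                  constants = constants)
  new_full_spectrum(grid, bands, constants)
}
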