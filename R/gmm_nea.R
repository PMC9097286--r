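#' Fit a per-band (delta_E, M) Gaussian mixture with a zero-dipole mass
#'
#' The probability mass `theta0` of exactly forbidden transitions (M = 0)
#' is estimated as the fraction of geometries with `f = 0`; those
#' geometries are removed and a BIC-selected mixture is fitted to the
#' remaining (delta_E in eV, M in a.u.) pairs. Component weights are then
#' rescaled by `1 - theta0` so total probability is conserved.
#'
#' @param sample a `transition_sample` from [extract_band()].
#' @param config a [fit_config()] controlling model selection.
#' @param f_tol strengths `<= f_tol` count as forbidden (default 0: exact).
#' @return a `band_gmm`: `state`, `theta0`, `gmm` (`gmm_params` with
#'   *rescaled* weights summing to `1 - theta0`), `dark` flag. A band with
#'   all strengths zero is returned dark (no fit).
#' @export
fit_band_gmm <- function(sample, config = fit_config(), f_tol = 0) {
  stopifnot(inherits(sample, "transition_sample"))
  zero <- sample$f <= f_tol
  theta0 <- mean(zero)
  if (all(zero)) {
    return(structure(list(state = sample$state, theta0 = 1, gmm = NULL,
                          dark = TRUE),
                     class = "band_gmm"))
  }
  nz <- sum(!zero)
  if (nz < 8L)
    stop("state ", sample$state, ": only ", nz,
         " geometries with nonzero dipole (need >= 8)", call. = FALSE)
  X <- cbind(sample$delta_E[!zero], sample$M[!zero])
  gmm <- select_model(X, config)
  .check_positive_support(gmm, sample$state)
  gmm$pro <- gmm$pro * (1 - theta0)
  structure(list(state = sample$state, theta0 = theta0, gmm = gmm,
                 dark = FALSE),
            class = "band_gmm")
}

## The mixture lives on the whole plane although delta_E > 0, M >= 0
## physically; warn when truncation leakage is non-negligible.
.check_positive_support <- function(gmm, state) {
  pars <- gmm_component_params(gmm)
  p_neg <- stats::pnorm(0, pars$mu1, sqrt(pars$s1sq)) +
    stats::pnorm(0, pars$mu2, sqrt(pars$s2sq))
  if (any(p_neg > 0.01))
    warning("state ", state, ": fitted component(s) ",
            paste(which(p_neg > 0.01), collapse = ", "),
            " place > 1% mass at negative delta_E or M; ",
            "the untruncated closed form may be inaccurate", call. = FALSE)
  invisible(NULL)
}

#' @export
print.band_gmm <- function(x, ...) {
  if (x$dark) cat("<band_gmm> state", x$state, "- dark (theta0 = 1)\n")
  else cat(sprintf("<band_gmm> state %d: theta0 = %.3f, K = %d, model = %s\n",
                   x$state, x$theta0, x$gmm$K, x$gmm$model))
  invisible(x)
}

#' Conditional moments of M given delta_E = E, per mixture component
#'
#' For a bivariate normal component, the conditional distribution of the
#' dipole at fixed energy is normal with
#' `mu_tilde(E) = mu2 + rho (s2 / s1) (E - mu1)` and
#' `var_tilde = s2sq (1 - rho^2)`; its second moment
#' `mu_tilde^2 + var_tilde` is what enters the closed-form spectrum.
#'
#' @param gmm a `gmm_params` object.
#' @param E energies (eV) at which to evaluate.
#' @return list with `mu_tilde` (length(E) x K matrix) and `var_tilde`
#'   (length-K vector).
#' @export
conditional_moments <- function(gmm, E) {
  pars <- gmm_component_params(gmm)
  K <- nrow(pars)
  mu_tilde <- vapply(seq_len(K), function(k)
    pars$mu2[k] + pars$rho[k] * sqrt(pars$s2sq[k] / pars$s1sq[k]) *
      (E - pars$mu1[k]),
    numeric(length(E)))
  if (length(E) == 1L) mu_tilde <- matrix(mu_tilde, nrow = 1L)
  list(mu_tilde = mu_tilde,
       var_tilde = pars$s2sq * (1 - pars$rho^2))
}

#' Bandwidth-free band spectrum from a fitted mixture
#'
#' The closed-form delta -> 0 limit of the ensemble sum:
#' `sigma(E) = C(E) E (2/3) E_Ha sum_k pro_k phi(E; mu1k, s1sqk)
#' (mu_tilde_k(E)^2 + var_tilde_k)`,
#' with `E` in eV on the grid, `E_Ha = E / 27.211386...` the same energy in
#' Hartree (from the atomic-units dipole/strength relation
#' `f = (2/3) dE_Ha M^2`), `phi` the marginal normal density per eV, and
#' `C(E)` the shared prefactor convention of [band_spectrum_discrete()] —
#' so discrete and mixture spectra are directly comparable. No broadening
#' parameter appears anywhere. Dark bands give a zero spectrum.
#'
#' @param band a `band_gmm` from [fit_band_gmm()] (or a synthetic truth).
#' @param grid an [energy_grid()].
#' @param constants an [nea_constants()] object.
#' @return a `band_spectrum`.
#' @export
band_spectrum_gmm <- function(band, grid, constants = nea_constants()) {
  stopifnot(inherits(band, "band_gmm"))
  E <- as.numeric(grid)
  if (band$dark)
    return(new_band_spectrum(band$state, grid, numeric(length(E)), constants))
  gmm <- band$gmm
  pars <- gmm_component_params(gmm)
  cm <- conditional_moments(gmm, E)
  mix <- numeric(length(E))
  for (k in seq_len(gmm$K)) {
    phi <- stats::dnorm(E, pars$mu1[k], sqrt(pars$s1sq[k]))
    mix <- mix + pars$pro[k] * phi * (cm$mu_tilde[, k]^2 + cm$var_tilde[k])
  }
  sigma <- cross_section_prefactor(E, constants) * E * (2 / 3) *
    (E / .EV_PER_HARTREE) * mix
  new_band_spectrum(band$state, grid, sigma, constants)
}

#' Percentile-bootstrap confidence bands for a GMM-NEA band spectrum
#'
#' Each replica resamples geometries with replacement, recomputes `theta0`,
#' refits the mixture with (K, model) held fixed at the original selection
#' (warm-started from the original parameters), and evaluates the closed
#' form. Replicas whose refit fails are redrawn (logged); more than 10%
#' failures aborts.
#'
#' @param sample the `transition_sample` the band was fitted on.
#' @param band the fitted `band_gmm`.
#' @param grid an [energy_grid()].
#' @param boot a [bootstrap_spec()].
#' @param constants an [nea_constants()] object.
#' @param config a [fit_config()] whose tolerances drive the refits.
#' @param reselect refit with full model re-selection per replica instead
#'   of the fixed (K, model) prescription (default `FALSE`).
#' @return the band's `band_spectrum` with `ci_low` / `ci_high` filled in;
#'   the replica matrix is attached as attribute `"replicas"`.
#' @export
bootstrap_ci_gmm <- function(sample, band, grid, boot = bootstrap_spec(),
                             constants = nea_constants(),
                             config = fit_config(), reselect = FALSE) {
  stopifnot(inherits(band, "band_gmm"), inherits(boot, "bootstrap_spec"))
  if (band$dark)
    stop("cannot bootstrap a dark band (theta0 = 1)", call. = FALSE)
  point <- band_spectrum_gmm(band, grid, constants)
  ng <- length(sample$delta_E)
  reps <- matrix(NA_real_, length(grid), boot$B)
  failures <- 0L
  max_fail <- ceiling(0.1 * boot$B)
  with_seed(boot$seed, {
    b <- 1L
    while (b <= boot$B) {
      idx <- sample.int(ng, ng, replace = TRUE)
      rb <- tryCatch(
        .refit_band(sample, idx, band, config, reselect),
        error = function(e) NULL)
      if (is.null(rb)) {
        failures <- failures + 1L
        if (failures > max_fail)
          stop("more than 10% of bootstrap replicas failed to refit (",
               failures, " failures in ", b - 1L + failures, " draws); ",
               "the band fit is too fragile for resampling", call. = FALSE)
        next
      }
      reps[, b] <- band_spectrum_gmm(rb, grid, constants)$sigma
      b <- b + 1L
    }
  })
  if (failures > 0L)
    message(failures, " bootstrap replica(s) redrawn after refit failure")
  qb <- .boot_quantiles(reps, boot$alpha)
  point$ci_low <- qb$low
  point$ci_high <- qb$high
  attr(point, "replicas") <- reps
  point
}

.refit_band <- function(sample, idx, band, config, reselect) {
  f_b <- sample$f[idx]
  theta0 <- mean(f_b == 0)
  if (all(f_b == 0))
    return(structure(list(state = band$state, theta0 = 1, gmm = NULL,
                          dark = TRUE), class = "band_gmm"))
  X <- cbind(sample$delta_E[idx][f_b > 0], sample$M[idx][f_b > 0])
  if (nrow(X) < max(3L, band$gmm$K))
    stop("too few nonzero points in replica", call. = FALSE)
  gmm <- if (reselect) {
    select_model(X, config)
  } else {
    cfg <- config
    cfg$restarts <- 1L
    ## warm start: responsibilities of the resampled points under the
    ## original fit (weights renormalized)
    g0 <- band$gmm
    es <- .estep(X, g0$pro / sum(g0$pro), g0$mean, g0$sigma)
    if (is.null(es)) stop("warm start failed", call. = FALSE)
    fit <- .em_once(X, g0$K, g0$model, cfg, es$resp)
    if (is.null(fit)) stop("replica EM collapsed", call. = FALSE)
    structure(list(K = g0$K, model = g0$model, pro = fit$pro,
                   mean = fit$mean, sigma = fit$sigma, loglik = fit$loglik,
                   n = nrow(X), df = g0$df,
                   bic = 2 * fit$loglik - g0$df * log(nrow(X))),
              class = "gmm_params")
  }
  gmm$pro <- gmm$pro * (1 - theta0)
  structure(list(state = band$state, theta0 = theta0, gmm = gmm,
                 dark = FALSE), class = "band_gmm")
}

#' Full GMM-NEA spectrum for an ensemble
#'
#' Fits every band with [fit_band_gmm()] (dark bands contribute zero) and
#' sums the closed-form band spectra. With `boot`, geometries are resampled
#' jointly across bands and per-band percentile bounds are computed with
#' the (K, model) of each band held fixed; the total CI follows the
#' `ci_method` convention of [full_spectrum_discrete()].
#'
#' @inheritParams full_spectrum_discrete
#' @param config a [fit_config()] for the per-band model selection.
#' @param f_tol forbidden-transition tolerance (see [fit_band_gmm()]).
#' @return a `full_spectrum`; the per-band fits are attached as attribute
#'   `"band_fits"`.
#' @export
full_spectrum_gmm <- function(table, config = fit_config(), grid = NULL,
                              boot = NULL, constants = nea_constants(),
                              ci_method = c("sum-bounds", "sum-replicas"),
                              f_tol = 0) {
  stopifnot(inherits(table, "nea_ensemble"))
  ci_method <- match.arg(ci_method)
  states <- ensemble_states(table)
  samples <- lapply(states, extract_band, table = table)
  fits <- lapply(samples, fit_band_gmm, config = config, f_tol = f_tol)
  if (is.null(grid)) {
    sds <- unlist(lapply(fits, function(b)
      if (b$dark) numeric(0) else sqrt(gmm_component_params(b$gmm)$s1sq)))
    grid <- default_energy_grid(table, deltas = max(sds))
  }
  bands <- lapply(fits, band_spectrum_gmm, grid = grid, constants = constants)

  ci <- NULL
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "bootstrap_spec"))
    ng <- n_geometries(table)
    lit <- which(!vapply(fits, `[[`, logical(1), "dark"))
    band_reps <- lapply(seq_along(states), function(i)
      matrix(0, length(grid), boot$B))
    failures <- 0L
    max_fail <- ceiling(0.1 * boot$B)
    with_seed(boot$seed, {
      b <- 1L
      while (b <= boot$B) {
        idx <- sample.int(ng, ng, replace = TRUE)
        rbs <- tryCatch(
          lapply(lit, function(i)
            .refit_band(samples[[i]], idx, fits[[i]], config,
                        reselect = FALSE)),
          error = function(e) NULL)
        if (is.null(rbs)) {
          failures <- failures + 1L
          if (failures > max_fail)
            stop("more than 10% of joint bootstrap replicas failed",
                 call. = FALSE)
          next
        }
        for (j in seq_along(lit))
          band_reps[[lit[j]]][, b] <-
            band_spectrum_gmm(rbs[[j]], grid, constants)$sigma
        b <- b + 1L
      }
    })
    for (i in seq_along(bands)) {
      qb <- .boot_quantiles(band_reps[[i]], boot$alpha)
      bands[[i]]$ci_low <- qb$low
      bands[[i]]$ci_high <- qb$high
    }
    if (ci_method == "sum-bounds") {
      ci <- list(low = Reduce(`+`, lapply(bands, `[[`, "ci_low")),
                 high = Reduce(`+`, lapply(bands, `[[`, "ci_high")))
    } else {
      ci <- .boot_quantiles(Reduce(`+`, band_reps), boot$alpha)
    }
  }
  out <- new_full_spectrum(grid, bands, constants, ci)
  attr(out, "band_fits") <- fits
  out
}

#' Band-fit report (one row per mixture component)
#'
#' Mirrors a "K | model" table: per state, the zero-dipole mass and the
#' fitted component parameters.
#'
#' @param fits list of `band_gmm` objects (e.g. attribute `band_fits` of
#'   [full_spectrum_gmm()]).
#' @return data frame with columns state, theta0, K, model, component, pro,
#'   mu1, mu2, s1sq, s2sq, rho.
#' @export
band_fit_report <- function(fits) {
  rows <- lapply(fits, function(b) {
    if (b$dark)
      return(data.frame(state = b$state, theta0 = 1, K = 0L,
                        model = NA_character_, component = NA_integer_,
                        pro = NA_real_, mu1 = NA_real_, mu2 = NA_real_,
                        s1sq = NA_real_, s2sq = NA_real_, rho = NA_real_))
    p <- gmm_component_params(b$gmm)
    cbind(data.frame(state = b$state, theta0 = b$theta0, K = b$gmm$K,
                     model = b$gmm$model), p)
  })
  do.call(rbind, rows)
}
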