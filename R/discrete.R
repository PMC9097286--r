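#' Photon-energy grid
#'
#' @param from,to grid limits in eV (`0 < from < to`).
#' @param n number of points (>= 2).
#' @return strictly increasing numeric vector of class `energy_grid`.
#' @export
energy_grid <- function(from, to, n = 2001L) {
  if (!is.finite(from) || !is.finite(to) || from <= 0 || to <= from)
    stop("need 0 < from < to", call. = FALSE)
  n <- as.integer(n)
  if (n < 2L) stop("grid needs at least 2 points", call. = FALSE)
  structure(seq(from, to, length.out = n), class = "energy_grid")
}

#' Default grid for an ensemble
#'
#' Spans `[min dE - 3 max_delta, max dE + 3 max_delta]`, floored at a small
#' positive energy, with 2001 points — enough to resolve bandwidths of a few
#' hundredths of an eV over a ~10 eV window.
#'
#' @param table an [ensemble_table()].
#' @param deltas broadenings (eV) whose maximum pads the data range.
#' @param n number of grid points.
#' @return an [energy_grid()].
#' @export
default_energy_grid <- function(table, deltas = 0.1, n = 2001L) {
  pad <- 3 * max(deltas)
  lo <- max(min(table$delta_E) - pad, 1e-6)
  energy_grid(lo, max(table$delta_E) + pad, n)
}

#' Normalized Gaussian line shape
#'
#' Normal density with standard deviation `delta / 2` (the full-width
#' convention forced by the bandwidth identity delta_opt = 2h); integrates
#' to one over the real line.
#'
#' @param x energy offset(s), eV.
#' @param delta full-width, eV, positive.
#' @param fwhm if `TRUE`, interpret `delta` as the FWHM instead
#'   (sd = delta / (2 sqrt(2 log 2))), for interoperability.
#' @return density values (1/eV).
#' @export
gaussian_lineshape <- function(x, delta, fwhm = FALSE) {
  if (!is.finite(delta) || delta <= 0)
    stop("`delta` must be positive", call. = FALSE)
  sd <- if (fwhm) delta / (2 * sqrt(2 * log(2))) else delta / 2
  stats::dnorm(x, sd = sd)
}

## Per-geometry kernel matrix: column j = C(E) * dE_j * f_j * g(E - dE_j).
## Shared by the point estimate and the bootstrap (replica spectra are
## column-count weighted averages of this matrix).
.discrete_kernel_matrix <- function(delta_E, f, delta, grid, constants,
                                    fwhm = FALSE) {
  CE <- cross_section_prefactor(as.numeric(grid), constants)
  G <- gaussian_lineshape(outer(as.numeric(grid), delta_E, "-"), delta,
                          fwhm = fwhm)
  CE * sweep(G, 2L, delta_E * f, "*")
}

#' Discrete NEA band spectrum with fixed broadening
#'
#' `sigma(E) = C(E) (1/N_g) sum_j dE_j f_j g(E - dE_j, delta)` — each
#' computed transition contributes a Gaussian at its vertical energy,
#' weighted by `dE * f`; `C(E)` carries `1/E` plus, in physical mode, the
#' cross-section constants (output then in cm^2).
#'
#' @param sample a `transition_sample` from [extract_band()].
#' @param delta phenomenological full-width (eV), positive.
#' @param grid an [energy_grid()].
#' @param constants an [nea_constants()] object.
#' @param fwhm interpret `delta` as FWHM (see [gaussian_lineshape()]).
#' @return a `band_spectrum`: list with `state`, `grid`, `sigma`, and the
#'   prefactor mode recorded for downstream unit checks.
#' @export
band_spectrum_discrete <- function(sample, delta, grid,
                                   constants = nea_constants(),
                                   fwhm = FALSE) {
  stopifnot(inherits(sample, "transition_sample"))
  ng <- length(sample$delta_E)
  if (ng == 0L) stop("empty transition sample", call. = FALSE)
  if (all(sample$f == 0)) {
    warning("all oscillator strengths are zero for state ", sample$state,
            "; returning a zero spectrum", call. = FALSE)
    sigma <- numeric(length(grid))
  } else {
    sigma <- numeric(length(grid))
    idx <- seq_len(ng)
    for (block in split(idx, ceiling(idx / 2000))) {
      K <- .discrete_kernel_matrix(sample$delta_E[block], sample$f[block],
                                   delta, grid, constants, fwhm)
      sigma <- sigma + rowSums(K)
    }
    sigma <- sigma / ng
  }
  new_band_spectrum(sample$state, grid, sigma, constants)
}

new_band_spectrum <- function(state, grid, sigma, constants,
                              ci_low = NULL, ci_high = NULL) {
  stopifnot(length(sigma) == length(grid))
  structure(
    list(state = state, grid = grid, sigma = sigma,
         ci_low = ci_low, ci_high = ci_high,
         prefactor_mode = constants$prefactor_mode),
    class = "band_spectrum"
  )
}

#' @export
print.band_spectrum <- function(x, ...) {
  cat("<band_spectrum> state", x$state, "-", length(x$grid), "points, peak",
      format(max(x$sigma), digits = 4),
      if (!is.null(x$ci_low)) "(with CI)" else "", "\n")
  invisible(x)
}

#' Weighted quantile by interpolated cumulative weights
#'
#' Tied abscissae are aggregated (weights summed) before interpolation, so
#' the quantile function is exactly invariant under duplication of the
#' sample. Positions are midpoints of the cumulative weight; equal weights
#' give `(i - 1/2)/n` plotting positions.
#'
#' @param x numeric values.
#' @param w non-negative weights (need not be normalized).
#' @param probs probabilities in `[0, 1]`.
#' @return quantiles at `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(probs >= 0 & probs <= 1))
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  agg <- rowsum(w, group = x)
  xs <- as.numeric(rownames(agg))
  ws <- as.numeric(agg) / sum(agg)
  if (length(xs) == 1L) return(rep(xs, length(probs)))
  p <- cumsum(ws) - ws / 2
  stats::approx(p, xs, xout = probs, rule = 2, ties = "ordered")$y
}

## Plug-in weighted standard deviation, weights normalized to sum 1.
weighted_sd <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sqrt(sum(w * (x - mu)^2))
}

#' Automatic per-band broadening (auto-delta)
#'
#' The discrete NEA band is formally a weighted KDE of the excitation
#' energies with weights `w_j` proportional to `dE_j f_j`; the optimal
#' empirical broadening is therefore `delta = 2 h` with the weighted
#' rule-of-thumb bandwidth
#' `h = 0.9 min(sd_w, IQR_w / 1.34) n_eff^(-1/5)`,
#' where `n_eff = (sum w)^2 / sum(w^2)` is the Kish effective sample size
#' of the normalized weights.
#'
#' @param sample a `transition_sample`.
#' @return a `kde_bandwidth`: list with the normalized weights `w`,
#'   `sigma_w`, `iqr_w`, `n_eff`, bandwidth `h` and broadening
#'   `delta = 2 h` (eV).
#' @export
auto_delta <- function(sample) {
  stopifnot(inherits(sample, "transition_sample"))
  w_raw <- sample$delta_E * sample$f
  if (all(w_raw == 0))
    stop("all weights (delta_E * f) are zero for state ", sample$state,
         ": bandwidth undefined (dark band)", call. = FALSE)
  nz <- sum(w_raw > 0)
  if (nz < 8L)
    stop("need at least 8 geometries with nonzero weight (got ", nz,
         "): interquartile range too unstable", call. = FALSE)
  w <- w_raw / sum(w_raw)
  sd_w <- weighted_sd(sample$delta_E, w)
  q <- weighted_quantile(sample$delta_E, w, c(0.25, 0.75))
  iqr_w <- q[2] - q[1]
  spread <- min(sd_w, iqr_w / 1.34)
  if (spread <= 0)
    stop("weighted spread of delta_E is zero: bandwidth undefined",
         call. = FALSE)
  n_eff <- 1 / sum(w^2)
  h <- 0.9 * spread * n_eff^(-1 / 5)
  structure(
    list(state = sample$state, w = w, sigma_w = sd_w, iqr_w = iqr_w,
         n_eff = n_eff, h = h, delta = 2 * h),
    class = "kde_bandwidth"
  )
}

#' @export
print.kde_bandwidth <- function(x, ...) {
  cat(sprintf("<kde_bandwidth> state %d: h = %.5g eV, delta = %.5g eV (n_eff = %.1f)\n",
              x$state, x$h, x$delta, x$n_eff))
  invisible(x)
}

#' Bootstrap specification
#'
#' @param B number of replicas (default 999).
#' @param alpha complement of the confidence level (default 0.05, i.e. 95%
#'   bands from the 2.5% and 97.5% quantiles).
#' @param seed integer seed for the resampling stream.
#' @return a `bootstrap_spec` list.
#' @export
bootstrap_spec <- function(B = 999L, alpha = 0.05, seed = NULL) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("`B` must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  structure(list(B = B, alpha = alpha, seed = seed), class = "bootstrap_spec")
}

.boot_quantiles <- function(replicas, alpha) {
  ## replicas: n_grid x B matrix; row-wise empirical percentile bounds
  probs <- c(alpha / 2, 1 - alpha / 2)
  qs <- apply(replicas, 1L, stats::quantile, probs = probs, names = FALSE,
              type = 7)
  list(low = qs[1L, ], high = qs[2L, ])
}

#' Full discrete NEA spectrum with percentile-bootstrap bands
#'
#' Point estimate: incoherent sum of per-band discrete spectra. Bands:
#' geometries are resampled with replacement jointly across all transitions
#' (B replicas), each replica spectrum is recomputed with the same deltas,
#' and pointwise percentile bounds are taken per band. The full-spectrum CI
#' is by default the sum of the per-band bounds; `ci_method =
#' "sum-replicas"` instead takes quantiles of the summed replicas.
#'
#' @param table an [ensemble_table()].
#' @param deltas named (by state) or positionally ordered vector of
#'   broadenings (eV), one per band, or a single value recycled.
#' @param grid an [energy_grid()]; default from [default_energy_grid()].
#' @param boot a [bootstrap_spec()], or `NULL` for no CI.
#' @param constants an [nea_constants()] object.
#' @param ci_method `"sum-bounds"` (default) or `"sum-replicas"` for the
#'   full-spectrum CI convention.
#' @return a `full_spectrum`: list with `grid`, `total`, `bands` (list of
#'   `band_spectrum`), and CI arrays when `boot` is given.
#' @export
full_spectrum_discrete <- function(table, deltas, grid = NULL,
                                   boot = NULL,
                                   constants = nea_constants(),
                                   ci_method = c("sum-bounds", "sum-replicas")) {
  stopifnot(inherits(table, "nea_ensemble"))
  ci_method <- match.arg(ci_method)
  states <- ensemble_states(table)
  samples <- lapply(states, extract_band, table = table)
  names(samples) <- as.character(states)
  dark <- vapply(samples, function(s) all(s$f == 0), logical(1))
  if (!is.null(names(deltas)) && any(dark)) {
    ## dark bands yield zero spectra for any delta; fill a placeholder so a
    ## named auto_deltas() vector (which drops them) still matches
    fill <- setdiff(as.character(states[dark]), names(deltas))
    if (length(fill)) deltas[fill] <- 0.1
  }
  deltas <- .match_deltas(deltas, states)
  if (is.null(grid)) grid <- default_energy_grid(table, deltas)
  if (!is.null(boot)) stopifnot(inherits(boot, "bootstrap_spec"))
  ng <- n_geometries(table)

  ## Per-band kernel matrices reused by replicas (spectrum is linear in the
  ## geometry multiplicities).
  kmats <- lapply(seq_along(states), function(i) {
    s <- samples[[i]]
    if (all(s$f == 0)) matrix(0, nrow = length(grid), ncol = ng)
    else .discrete_kernel_matrix(s$delta_E, s$f, deltas[i], grid, constants)
  })
  bands <- lapply(seq_along(states), function(i)
    new_band_spectrum(states[i], grid, rowSums(kmats[[i]]) / ng, constants))

  ci <- NULL
  if (!is.null(boot)) {
    counts <- with_seed(boot$seed, {
      vapply(seq_len(boot$B),
             function(b) tabulate(sample.int(ng, ng, replace = TRUE), ng),
             integer(ng))
    }) # ng x B
    band_reps <- lapply(kmats, function(K) (K %*% counts) / ng)
    for (i in seq_along(bands)) {
      qb <- .boot_quantiles(band_reps[[i]], boot$alpha)
      bands[[i]]$ci_low <- qb$low
      bands[[i]]$ci_high <- qb$high
    }
    if (ci_method == "sum-bounds") {
      ci <- list(low = Reduce(`+`, lapply(bands, `[[`, "ci_low")),
                 high = Reduce(`+`, lapply(bands, `[[`, "ci_high")))
    } else {
      tot_reps <- Reduce(`+`, band_reps)
      ci <- .boot_quantiles(tot_reps, boot$alpha)
    }
  }
  new_full_spectrum(grid, bands, constants, ci)
}

.match_deltas <- function(deltas, states) {
  if (!is.null(names(deltas))) {
    miss <- setdiff(as.character(states), names(deltas))
    if (length(miss))
      stop("no delta supplied for state(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    deltas <- as.numeric(deltas[as.character(states)])
  } else if (length(deltas) == 1L) {
    deltas <- rep(as.numeric(deltas), length(states))
  } else if (length(deltas) != length(states)) {
    stop("need one delta per band (", length(states), " bands, got ",
         length(deltas), ")", call. = FALSE)
  }
  if (any(!is.finite(deltas) | deltas <= 0))
    stop("all deltas must be positive", call. = FALSE)
  deltas
}

new_full_spectrum <- function(grid, bands, constants, ci = NULL) {
  total <- Reduce(`+`, lapply(bands, `[[`, "sigma"))
  structure(
    list(grid = grid, total = total, bands = bands,
         ci_low = ci$low, ci_high = ci$high,
         prefactor_mode = constants$prefactor_mode),
    class = "full_spectrum"
  )
}

#' @export
print.full_spectrum <- function(x, ...) {
  cat("<full_spectrum>", length(x$bands), "bands,", length(x$grid),
      "grid points, peak", format(max(x$total), digits = 4),
      if (!is.null(x$ci_low)) "(with CI)" else "", "\n")
  invisible(x)
}

#' Auto-delta broadenings for every band of an ensemble
#'
#' @param table an [ensemble_table()].
#' @return named numeric vector of per-state broadenings (eV); dark bands
#'   (all f = 0) are dropped with a warning.
#' @export
auto_deltas <- function(table) {
  states <- ensemble_states(table)
  out <- c()
  for (n in states) {
    s <- extract_band(table, n)
    d <- tryCatch(auto_delta(s)$delta, error = function(e) {
      warning("state ", n, " skipped: ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
    if (!is.na(d)) out[as.character(n)] <- d
  }
  out
}
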