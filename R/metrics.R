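## Reconstruction-quality metrics: relative integral change (RIC), its
## band-wise mean (bRIC), and the sequential variant used as an
## active-learning stopping rule. All integrals are trapezoid-rule.

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

## Accept a band_spectrum / full_spectrum or a list(grid, sigma).
.as_curve <- function(spec) {
  if (inherits(spec, "band_spectrum"))
    list(grid = as.numeric(spec$grid), sigma = spec$sigma)
  else if (inherits(spec, "full_spectrum"))
    list(grid = as.numeric(spec$grid), sigma = spec$total)
  else if (is.list(spec) && all(c("grid", "sigma") %in% names(spec)))
    list(grid = as.numeric(spec$grid), sigma = spec$sigma)
  else stop("not a spectrum object", call. = FALSE)
}

#' Relative integral change between two spectra
#'
#' `RIC = integral |sigma_R - sigma_T| dE / integral sigma_T dE`, computed
#' on the target's grid (the reconstruction is linearly interpolated onto
#' it when grids differ). Zero iff the spectra agree pointwise; invariant
#' under joint rescaling, so the prefactor convention cancels.
#'
#' @param sigma_R reconstructed spectrum (`band_spectrum`, `full_spectrum`,
#'   or `list(grid, sigma)`).
#' @param sigma_T target spectrum, same forms; must have positive area.
#' @return a `metric_result`: list with `value`, `grid`.
#' @export
ric <- function(sigma_R, sigma_T) {
  r <- .as_curve(sigma_R); t <- .as_curve(sigma_T)
  area_t <- trapz(t$grid, t$sigma)
  if (area_t <= 0)
    stop("target spectrum has zero area: RIC undefined", call. = FALSE)
  if (!isTRUE(all.equal(r$grid, t$grid, tolerance = 1e-12)))
    r$sigma <- stats::approx(r$grid, r$sigma, xout = t$grid, rule = 2)$y
  structure(list(value = trapz(t$grid, abs(r$sigma - t$sigma)) / area_t,
                 grid = t$grid),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat("<metric_result>", format(x$value, digits = 6),
      if (!is.null(x$per_band)) paste0("(", nrow(x$per_band), " bands)"),
      "\n")
  invisible(x)
}

.match_band_lists <- function(bands_R, bands_T) {
  sr <- vapply(bands_R, function(b) .band_state(b), integer(1))
  st <- vapply(bands_T, function(b) .band_state(b), integer(1))
  if (!setequal(sr, st) || length(sr) != length(st))
    stop("band sets differ: reconstructed {",
         paste(sort(sr), collapse = ","), "} vs target {",
         paste(sort(st), collapse = ","), "}", call. = FALSE)
  list(R = bands_R[order(sr)], T = bands_T[order(st)], states = sort(st))
}

.band_state <- function(b) {
  s <- if (inherits(b, "band_spectrum")) b$state else b$state
  if (is.null(s)) stop("band spectrum lacks a state index", call. = FALSE)
  as.integer(s)
}

#' Band-wise relative integral change
#'
#' Unweighted mean of per-band RIC over matched bands, so weak bands count
#' as much as strong ones. Target bands with zero area (dark bands) are
#' excluded from the mean and listed in the result.
#'
#' @param bands_R list of reconstructed per-band spectra (each with a
#'   `state` element).
#' @param bands_T list of target per-band spectra over the same states.
#' @return a `metric_result` with `value`, `per_band` (data frame), and
#'   `excluded` (states with zero target area).
#' @export
bric <- function(bands_R, bands_T) {
  m <- .match_band_lists(bands_R, bands_T)
  vals <- rep(NA_real_, length(m$states))
  excluded <- integer(0)
  for (i in seq_along(m$states)) {
    t <- .as_curve(m$T[[i]])
    if (trapz(t$grid, t$sigma) <= 0) {
      excluded <- c(excluded, m$states[i])
    } else {
      vals[i] <- ric(m$R[[i]], m$T[[i]])$value
    }
  }
  if (all(is.na(vals)))
    stop("every target band has zero area: bRIC undefined", call. = FALSE)
  structure(list(value = mean(vals, na.rm = TRUE),
                 per_band = data.frame(state = m$states, ric = vals),
                 excluded = excluded),
            class = "metric_result")
}

#' Sequential band-wise RIC and the active-learning stopping rule
#'
#' Compares the spectra reconstructed without (`bands_old`) and with
#' (`bands_new`) the latest batch of geometries, normalizing each band by
#' the *new* (better-sampled) spectrum:
#' `mean_n integral |sigma_new,n - sigma_old,n| dE / integral sigma_new,n dE`.
#' Sampling is deemed converged when the value falls below `threshold`.
#'
#' @param bands_old,bands_new per-band spectra lists over the same states.
#' @param threshold stopping threshold; the named presets
#'   `bric_seq_thresholds` (`loose` 0.1, `standard` 0.05, `strict` 0.025)
#'   may be used.
#' @return a `metric_result` with `value`, `per_band`, `excluded`,
#'   `threshold` and logical `stop`.
#' @export
bric_seq <- function(bands_old, bands_new,
                     threshold = bric_seq_thresholds[["standard"]]) {
  m <- .match_band_lists(bands_old, bands_new)
  vals <- rep(NA_real_, length(m$states))
  excluded <- integer(0)
  for (i in seq_along(m$states)) {
    new <- .as_curve(m$T[[i]])
    if (trapz(new$grid, new$sigma) <= 0) excluded <- c(excluded, m$states[i])
    else vals[i] <- ric(m$R[[i]], m$T[[i]])$value
  }
  if (all(is.na(vals)))
    stop("every new-batch band has zero area: bRIC_seq undefined",
         call. = FALSE)
  value <- mean(vals, na.rm = TRUE)
  structure(list(value = value,
                 per_band = data.frame(state = m$states, ric = vals),
                 excluded = excluded, threshold = threshold,
                 stop = value < threshold),
            class = "metric_result")
}

#' @rdname bric_seq
#' @export
bric_seq_thresholds <- c(loose = 0.1, standard = 0.05, strict = 0.025)
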