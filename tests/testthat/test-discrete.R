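test_that("gaussian lineshape is a normalized symmetric density", {
  expect_equal(gaussian_lineshape(0, 2), 1 / sqrt(2 * pi), tolerance = 1e-14)
  x <- seq(0.1, 5, by = 0.3)
  expect_equal(gaussian_lineshape(x, 0.7), gaussian_lineshape(-x, 0.7))
  for (delta in c(0.02, 0.5, 3)) {
    int <- stats::integrate(gaussian_lineshape, -10 * delta, 10 * delta,
                            delta = delta, rel.tol = 1e-12)$value
    expect_equal(int, 1, tolerance = 1e-9)
  }
  # FWHM interpretation: half maximum at +/- delta/2
  expect_equal(gaussian_lineshape(0.35, 0.7, fwhm = TRUE),
               gaussian_lineshape(0, 0.7, fwhm = TRUE) / 2, tolerance = 1e-12)
  expect_error(gaussian_lineshape(0, 0), "positive")
})

test_that("discrete band spectrum has the single-geometry closed form", {
  s <- structure(list(state = 1L, geom_id = "g1", delta_E = 4.0, f = 0.25,
                      M = dipole_from_strength(4.0, 0.25)),
                 class = "transition_sample")
  grid <- energy_grid(3, 5, 401)
  sp <- band_spectrum_discrete(s, delta = 0.2, grid = grid)
  # at E = dE0 in arbitrary mode: C(E) * dE0 * f0 * g(0) = f0 * g(0) / 1
  i0 <- which.min(abs(as.numeric(grid) - 4.0))
  expect_equal(sp$sigma[i0], 0.25 * gaussian_lineshape(0, 0.2) / 4.0 * 4.0,
               tolerance = 1e-12)
  # zero strength: zero spectrum with a warning
  s0 <- s; s0$f <- 0; s0$M <- 0
  expect_warning(sp0 <- band_spectrum_discrete(s0, 0.2, grid), "zero")
  expect_true(all(sp0$sigma == 0))
})

test_that("discrete spectrum is homogeneous of degree 1 in f", {
  tab <- sample_ensemble(demo_truths()[1], 40, seed = 11)
  s <- extract_band(tab, 1)
  grid <- energy_grid(3.5, 5.5, 201)
  sp1 <- band_spectrum_discrete(s, 0.1, grid)
  s2 <- s; s2$f <- 3.7 * s$f; s2$M <- dipole_from_strength(s2$delta_E, s2$f)
  sp2 <- band_spectrum_discrete(s2, 0.1, grid)
  expect_equal(sp2$sigma, 3.7 * sp1$sigma, tolerance = 1e-12)
})

test_that("small-delta band area converges to mean oscillator strength", {
  tab <- sample_ensemble(demo_truths()[1], 60, seed = 3)
  s <- extract_band(tab, 1)
  delta <- 1e-2 * min(s$delta_E)
  grid <- energy_grid(min(s$delta_E) - 10 * delta,
                      max(s$delta_E) + 10 * delta, 6001)
  sp <- band_spectrum_discrete(s, delta, grid)
  area <- trapz_ref(as.numeric(grid), sp$sigma)
  expect_equal(area, mean(s$f), tolerance = 1e-3)
})

test_that("auto_delta implements the weighted rule of thumb", {
  tab <- sample_ensemble(demo_truths()[1], 200, seed = 5)
  s <- extract_band(tab, 1)
  bw <- auto_delta(s)
  expect_equal(sum(bw$w), 1, tolerance = 1e-14)
  expect_identical(bw$delta, 2 * bw$h) # exact, by construction

  # independent evaluation of the formula with equal weights
  se <- s
  se$f <- 0.2 / se$delta_E # makes w_j = dE * f constant
  se$M <- dipole_from_strength(se$delta_E, se$f)
  bwe <- auto_delta(se)
  n <- length(se$delta_E)
  w <- rep(1 / n, n)
  sd_w <- sqrt(mean((se$delta_E - mean(se$delta_E))^2))
  cw <- cumsum(w)
  qf <- stats::approx(cw - w / 2, sort(se$delta_E),
                      xout = c(0.25, 0.75), rule = 2)$y
  h_ref <- 0.9 * min(sd_w, (qf[2] - qf[1]) / 1.34) * n^(-1 / 5)
  expect_equal(bwe$h, h_ref, tolerance = 1e-12)
})

test_that("duplicating every record scales h by exactly 2^(-1/5)", {
  tab <- sample_ensemble(demo_truths()[1], 100, seed = 7)
  s <- extract_band(tab, 1)
  dup <- list(state = 1L, geom_id = c(s$geom_id, paste0(s$geom_id, "b")),
              delta_E = c(s$delta_E, s$delta_E), f = c(s$f, s$f),
              M = c(s$M, s$M))
  class(dup) <- "transition_sample"
  h1 <- auto_delta(s)
  h2 <- auto_delta(dup)
  expect_identical(h2$sigma_w, h1$sigma_w)
  expect_identical(h2$iqr_w, h1$iqr_w)
  expect_equal(h2$n_eff, 2 * h1$n_eff, tolerance = 1e-14)
  expect_equal(h2$h / h1$h, 2^(-1 / 5), tolerance = 1e-15)
})

test_that("auto_delta enforces its preconditions", {
  s <- structure(list(state = 1L, geom_id = letters[1:5],
                      delta_E = c(4, 4.1, 4.2, 4.3, 4.4),
                      f = rep(0.1, 5), M = rep(0.3, 5)),
                 class = "transition_sample")
  expect_error(auto_delta(s), "at least 8")
  s$f <- rep(0, 5); s$M <- rep(0, 5)
  expect_error(auto_delta(s), "dark band")
})

test_that("weighted quantiles interpolate cumulative weights", {
  x <- c(1, 2, 3, 4)
  # all weight on one point
  expect_equal(weighted_quantile(x, c(0, 1, 0, 0), c(0.1, 0.9)), c(2, 2))
  # equal weights: midpoint positions, linear in between
  q <- weighted_quantile(x, rep(1, 4), 0.5)
  expect_equal(q, 2.5)
  # duplication invariance at arbitrary probs
  p <- seq(0, 1, by = 0.05)
  expect_equal(weighted_quantile(c(x, x), rep(1, 8), p),
               weighted_quantile(x, rep(1, 4), p))
})

test_that("bootstrap bands: degenerate, reproducible, enumerable", {
  # identical geometries: all replicas equal the point estimate
  df <- data.frame(geom_id = c("a", "b", "c"), state = 1L,
                   delta_E = 4.0, f = 0.2)
  tab <- ensemble_table(df)
  sp <- full_spectrum_discrete(tab, 0.2, grid = energy_grid(3, 5, 101),
                               boot = bootstrap_spec(99, seed = 1))
  expect_equal(sp$ci_low, sp$total, tolerance = 1e-14)
  expect_equal(sp$ci_high, sp$total, tolerance = 1e-14)

  # fixed seed: bit-identical CI bands
  tab2 <- sample_ensemble(demo_truths()[1], 30, seed = 2)
  g <- energy_grid(3.5, 5.5, 101)
  a <- full_spectrum_discrete(tab2, 0.1, g, boot = bootstrap_spec(199, seed = 42))
  b <- full_spectrum_discrete(tab2, 0.1, g, boot = bootstrap_spec(199, seed = 42))
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  expect_true(all(a$ci_low <= a$ci_high))

  # 2-geometry band: the bootstrap support has 3 resamples with probs
  # 1/4, 1/2, 1/4, so with B = 999 the 2.5/97.5% quantiles hit the extreme
  # resampled spectra; enumerate them exhaustively
  df2 <- data.frame(geom_id = c("g1", "g2"), state = 1L,
                    delta_E = c(4.0, 4.5), f = c(0.1, 0.3))
  tab3 <- ensemble_table(df2)
  g2 <- energy_grid(3.5, 5.0, 61)
  sp3 <- full_spectrum_discrete(tab3, 0.3, g2,
                                boot = bootstrap_spec(999, seed = 7))
  s1 <- extract_band(tab3, 1)
  rep_spec <- function(idx) {
    si <- list(state = 1L, geom_id = s1$geom_id[idx],
               delta_E = s1$delta_E[idx], f = s1$f[idx], M = s1$M[idx])
    class(si) <- "transition_sample"
    band_spectrum_discrete(si, 0.3, g2)$sigma
  }
  variants <- cbind(rep_spec(c(1, 1)), rep_spec(c(1, 2)), rep_spec(c(2, 2)))
  lo <- pmin(variants[, 1], variants[, 2], variants[, 3])
  hi <- pmax(variants[, 1], variants[, 2], variants[, 3])
  expect_equal(sp3$ci_low, lo, tolerance = 1e-12)
  expect_equal(sp3$ci_high, hi, tolerance = 1e-12)
})

test_that("full spectrum is the pointwise sum of its bands", {
  tab <- sample_ensemble(demo_truths(), 50, seed = 9)
  deltas <- auto_deltas(tab)
  sp <- full_spectrum_discrete(tab, deltas)
  expect_equal(sp$total, Reduce(`+`, lapply(sp$bands, `[[`, "sigma")),
               tolerance = 1e-12)
  expect_equal(length(sp$grid), 2001L)
})

test_that("bootstrap spec and delta matching validate their inputs", {
  expect_error(bootstrap_spec(0), ">= 1")
  expect_error(bootstrap_spec(10, alpha = 1.2), "0, 1")
  tab <- toy_table()
  expect_error(full_spectrum_discrete(tab, c(0.1, 0.2)), "one delta per band")
  expect_error(full_spectrum_discrete(tab, -0.1), "positive")
})
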