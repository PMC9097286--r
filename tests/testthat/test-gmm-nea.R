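test_that("theta0 is the exact forbidden-transition fraction", {
  df <- data.frame(geom_id = sprintf("g%02d", 1:10), state = 1L,
                   delta_E = seq(4, 4.9, by = 0.1),
                   f = c(0, 0, 0, rep(0.1, 7)))
  s <- extract_band(ensemble_table(df), 1)
  expect_error(fit_band_gmm(s, quick_config()), "need >= 8") # only 7 nonzero
  df$f <- c(0, 0, 0, rep(0.1, 7)) # keep theta0 but supply enough points
  df2 <- data.frame(geom_id = sprintf("g%02d", 1:20), state = 1L,
                    delta_E = 4 + (1:20) / 20,
                    f = c(rep(0, 6), 0.08 + (1:14) / 100))
  s2 <- extract_band(ensemble_table(df2), 1)
  fit <- fit_band_gmm(s2, quick_config(K_range = 1))
  expect_identical(fit$theta0, 0.3)
  expect_equal(sum(fit$gmm$pro), 1 - fit$theta0, tolerance = 1e-12)

  df2$f[] <- 0
  s3 <- extract_band(ensemble_table(df2), 1)
  dark <- fit_band_gmm(s3, quick_config())
  expect_true(dark$dark)
  expect_identical(dark$theta0, 1)
  g <- energy_grid(3, 6, 51)
  expect_true(all(band_spectrum_gmm(dark, g)$sigma == 0))
})

test_that("conditional moments follow the bivariate-normal formulas", {
  tr <- band_truth(1, 1, mu1 = 5, mu2 = 0.6, sd1 = 0.2, sd2 = 0.1,
                   rho = 0.5)
  E <- c(4.6, 5.0, 5.4)
  cm <- conditional_moments(tr$gmm, E)
  expect_equal(cm$mu_tilde[, 1], 0.6 + 0.5 * (0.1 / 0.2) * (E - 5),
               tolerance = 1e-12)
  expect_equal(cm$var_tilde, 0.1^2 * (1 - 0.25), tolerance = 1e-12)
  # rho = 0: E-independent conditional mean
  tr0 <- band_truth(1, 1, mu1 = 5, mu2 = 0.6, sd1 = 0.2, sd2 = 0.1)
  cm0 <- conditional_moments(tr0$gmm, E)
  expect_true(all(cm0$mu_tilde == 0.6))
})

test_that("K = 1, rho = 0 spectrum factorizes in closed form", {
  theta0 <- 0.2
  tr <- band_truth(1, 1, mu1 = 5, mu2 = 0.6, sd1 = 0.2, sd2 = 0.1,
                   theta0 = theta0)
  g <- energy_grid(4, 6, 301)
  E <- as.numeric(g)
  sp <- band_spectrum_gmm(tr, g)
  ref <- (1 / E) * E * (2 / 3) * (E / HA_EV) * (1 - theta0) *
    (0.6^2 + 0.1^2) * stats::dnorm(E, 5, 0.2)
  expect_equal(sp$sigma, ref, tolerance = 1e-12)
})

test_that("closed form matches the pre-limit 2-D quadrature oracle", {
  tr <- demo_truths()[[2]] # bimodal, correlated: the hard case
  g <- energy_grid(5.0, 6.4, 41)
  sp <- band_spectrum_gmm(tr, g)
  oracle <- quadrature_spectrum_ref(tr, g, delta = 1e-4)
  keep <- sp$sigma > 1e-6 * max(sp$sigma)
  expect_true(all(abs(sp$sigma[keep] - oracle[keep]) / sp$sigma[keep] < 1e-4))
})

test_that("mu_tilde^2 + var_tilde matches Monte-Carlo E[M^2 | dE]", {
  tr <- band_truth(1, 1, mu1 = 5, mu2 = 0.6, sd1 = 0.2, sd2 = 0.1,
                   rho = 0.6)
  set.seed(77)
  X <- gmm_simulate(tr$gmm, 2e5)
  E_test <- seq(4.7, 5.3, length.out = 25)
  eps <- 0.004
  cm <- conditional_moments(tr$gmm, E_test)
  for (i in seq_along(E_test)) {
    sel <- abs(X[, 1] - E_test[i]) < eps
    m2 <- X[sel, 2]^2
    mc <- mean(m2); se <- stats::sd(m2) / sqrt(length(m2))
    expect_lt(abs(cm$mu_tilde[i, 1]^2 + cm$var_tilde[1] - mc), 3 * se + 1e-4)
  }
})

test_that("scaling all dipoles by sqrt(c) scales the spectrum by c", {
  c_fac <- 2.5
  tr <- band_truth(1, c(0.6, 0.4), mu1 = c(5.5, 5.9), mu2 = c(0.5, 0.35),
                   sd1 = c(0.12, 0.1), sd2 = c(0.06, 0.05),
                   rho = c(-0.2, 0.2))
  # analytic parameter transform of M -> sqrt(c) M
  trc <- band_truth(1, c(0.6, 0.4), mu1 = c(5.5, 5.9),
                    mu2 = sqrt(c_fac) * c(0.5, 0.35),
                    sd1 = c(0.12, 0.1), sd2 = sqrt(c_fac) * c(0.06, 0.05),
                    rho = c(-0.2, 0.2))
  g <- energy_grid(5, 6.5, 201)
  expect_equal(band_spectrum_gmm(trc, g)$sigma,
               c_fac * band_spectrum_gmm(tr, g)$sigma, tolerance = 1e-12)
})

test_that("fitting in Hartree reparameterizes but leaves the spectrum invariant", {
  tab <- sample_ensemble(demo_truths()[1], 300, seed = 21)
  s <- extract_band(tab, 1)
  cfg <- quick_config(K_range = 1) # K = 1: init-independent closed form
  fit_ev <- fit_band_gmm(s, cfg)
  s_ha <- s; s_ha$delta_E <- s$delta_E / HA_EV
  X <- cbind(s_ha$delta_E, s_ha$M)
  gmm_ha <- select_model(X, cfg)
  # convert the Hartree-fit parameters back to eV
  gmm_ha$mean[1, ] <- gmm_ha$mean[1, ] * HA_EV
  gmm_ha$sigma[1, 1, ] <- gmm_ha$sigma[1, 1, ] * HA_EV^2
  gmm_ha$sigma[1, 2, ] <- gmm_ha$sigma[1, 2, ] * HA_EV
  gmm_ha$sigma[2, 1, ] <- gmm_ha$sigma[2, 1, ] * HA_EV
  band_ha <- structure(list(state = 1L, theta0 = fit_ev$theta0,
                            gmm = gmm_ha, dark = FALSE), class = "band_gmm")
  g <- energy_grid(3.8, 5.2, 101)
  expect_equal(band_spectrum_gmm(band_ha, g)$sigma,
               band_spectrum_gmm(fit_ev, g)$sigma, tolerance = 1e-8)
})

test_that("parameter recovery on synthetic data with a zero mass", {
  tr <- band_truth(1, c(0.55, 0.45), mu1 = c(4.0, 5.6), mu2 = c(0.8, 0.4),
                   sd1 = c(0.15, 0.2), sd2 = c(0.08, 0.05), theta0 = 0.1)
  tab <- sample_ensemble(list(tr), 2000, seed = 31)
  s <- extract_band(tab, 1)
  fit <- fit_band_gmm(s, quick_config(seed = 5))
  # theta0 within the binomial 3-sigma interval around 0.1
  expect_lt(abs(fit$theta0 - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
  expect_identical(fit$gmm$K, 2L)
  mu_hat <- fit$gmm$mean[, order(fit$gmm$mean[1, ])]
  expect_lt(max(abs(mu_hat - tr$gmm$mean) / abs(tr$gmm$mean)), 0.05)
  expect_equal(sum(fit$gmm$pro), 1 - fit$theta0, tolerance = 1e-12)
})

test_that("gmm bootstrap bands are reproducible and sane", {
  tab <- sample_ensemble(demo_truths()[1], 150, seed = 41)
  s <- extract_band(tab, 1)
  cfg <- quick_config(K_range = 1:2, seed = 3)
  fit <- fit_band_gmm(s, cfg)
  g <- energy_grid(3.8, 5.2, 101)
  b1 <- bootstrap_ci_gmm(s, fit, g, bootstrap_spec(99, seed = 8), config = cfg)
  b2 <- bootstrap_ci_gmm(s, fit, g, bootstrap_spec(99, seed = 8), config = cfg)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_true(all(b1$ci_low <= b1$ci_high))
  expect_identical(dim(attr(b1, "replicas")), c(101L, 99L))
})

test_that("degenerate samples abort the bootstrap with a diagnostic", {
  df <- data.frame(geom_id = sprintf("g%02d", 1:20), state = 1L,
                   delta_E = 4.5, f = 0.1) # identical rows: zero variance
  s <- extract_band(ensemble_table(df), 1)
  expect_error(fit_band_gmm(s, quick_config()), "failed")
})

test_that("full GMM-NEA spectrum assembles dark and bright bands", {
  truths <- list(demo_truths()[[1]],
                 band_truth(2, 1, mu1 = 6, mu2 = 0.5, sd1 = 0.2, sd2 = 0.1,
                            theta0 = 1))
  tab <- sample_ensemble(truths, 200, seed = 51)
  sp <- full_spectrum_gmm(tab, quick_config(K_range = 1:2, seed = 2),
                          grid = energy_grid(3.5, 7, 201))
  fits <- attr(sp, "band_fits")
  expect_true(fits[[2]]$dark)
  expect_true(all(sp$bands[[2]]$sigma == 0))
  expect_equal(sp$total, sp$bands[[1]]$sigma + sp$bands[[2]]$sigma)
  rep <- band_fit_report(fits)
  expect_identical(rep$K[rep$state == 2], 0L)
})
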