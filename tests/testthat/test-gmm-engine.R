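## Independent enumeration of covariance parameters per family definition:
## volume (lambda) / shape (A) / orientation (D) counts for d = 2.
ref_free_params <- function(model, K, d = 2) {
  cov <- switch(model,
    EII = 1, VII = K, EEI = d, VEI = K + (d - 1), EVI = 1 + K * (d - 1),
    VVI = K * d, EEE = d * (d + 1) / 2, VVV = K * d * (d + 1) / 2)
  (K - 1) + K * d + cov
}

test_that("free-parameter counts match the family definitions", {
  expect_identical(count_free_params("EII", 1), 3L)   # 0 + 2 + 1
  expect_identical(count_free_params("VVV", 6), 35L)  # 5 + 12 + 18
  expect_identical(count_free_params("EEE", 3), 11L)  # 2 + 6 + 3
  for (m in gmmnea:::GMM_MODELS)
    for (K in 1:6)
      expect_identical(count_free_params(m, K), as.integer(ref_free_params(m, K)))
  expect_error(count_free_params("XXX", 2), "unsupported")
})

test_that("K = 1 fits equal the closed-form single-Gaussian MLE", {
  set.seed(10)
  X <- cbind(rnorm(300, 5, 0.4), rnorm(300, 1, 0.2) + 0.3 * rnorm(300))
  n <- nrow(X)
  fit <- em_fit(X, 1, "VVV", quick_config())
  S <- stats::cov(X) * (n - 1) / n
  mu <- colMeans(X)
  ll_ref <- sum(-log(2 * pi) - 0.5 * log(det(S)) -
                0.5 * stats::mahalanobis(X, mu, S))
  expect_equal(fit$loglik, ll_ref, tolerance = 1e-9)
  expect_equal(fit$mean[, 1], mu, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$sigma[, , 1], S, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$bic, 2 * ll_ref - 5 * log(n), tolerance = 1e-8)
})

test_that("duplicating the dataset doubles the log-likelihood only", {
  set.seed(11)
  X <- cbind(rnorm(150, 4, 0.3), rnorm(150, 0.8, 0.1))
  f1 <- em_fit(X, 1, "EEE", quick_config())
  f2 <- em_fit(rbind(X, X), 1, "EEE", quick_config())
  expect_equal(f2$mean, f1$mean, tolerance = 1e-12)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-12)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-10)
})

test_that("EM log-likelihood is monotone and weights normalize", {
  set.seed(12)
  X <- rbind(cbind(rnorm(200, 4, 0.3), rnorm(200, 0.8, 0.1)),
             cbind(rnorm(150, 6, 0.2), rnorm(150, 0.4, 0.05)))
  for (m in gmmnea:::GMM_MODELS) {
    fit <- em_fit(X, 2, m, quick_config(seed = 2))
    expect_true(all(diff(fit$trace) >= -1e-10 * (abs(fit$loglik) + 1)),
                info = m)
    expect_equal(sum(fit$pro), 1, tolerance = 1e-12)
    expect_identical(fit$model, m)
  }
})

test_that("fitted covariances respect the family constraints exactly", {
  set.seed(13)
  X <- rbind(cbind(rnorm(200, 4, 0.3), rnorm(200, 0.8, 0.1)),
             cbind(rnorm(200, 5.5, 0.5), rnorm(200, 0.3, 0.2)))
  fits <- lapply(gmmnea:::GMM_MODELS, function(m)
    em_fit(X, 2, m, quick_config(seed = 3)))
  names(fits) <- gmmnea:::GMM_MODELS
  sig <- function(f, k) f$sigma[, , k]
  # shared covariance families: components bit-identical
  expect_identical(sig(fits$EEE, 1), sig(fits$EEE, 2))
  expect_identical(sig(fits$EII, 1), sig(fits$EII, 2))
  expect_identical(sig(fits$EEI, 1), sig(fits$EEI, 2))
  # diagonal families: zero correlation
  for (m in c("EII", "VII", "EEI", "VEI", "EVI", "VVI"))
    expect_true(all(fits[[m]]$sigma[1, 2, ] == 0), info = m)
  # spherical families: equal variances within a component
  for (m in c("EII", "VII"))
    expect_equal(fits[[m]]$sigma[1, 1, ], fits[[m]]$sigma[2, 2, ], info = m)
  # VEI: shared shape -> variance ratio equal across components
  r <- fits$VEI$sigma[1, 1, ] / fits$VEI$sigma[2, 2, ]
  expect_equal(r[1], r[2], tolerance = 1e-8)
  # EVI: shared volume -> determinants equal across components
  d <- fits$EVI$sigma[1, 1, ] * fits$EVI$sigma[2, 2, ]
  expect_equal(d[1], d[2], tolerance = 1e-8)
})

test_that("compiled EM agrees with the pure-R reference implementation", {
  set.seed(14)
  X <- rbind(cbind(rnorm(120, 4, 0.3), rnorm(120, 0.8, 0.1)),
             cbind(rnorm(80, 5.2, 0.25), rnorm(80, 0.5, 0.08)))
  cfg <- fit_config(restarts = 1, seed = 1)
  for (m in gmmnea:::GMM_MODELS) {
    resp0 <- matrix(0, nrow(X), 2)
    set.seed(20)
    resp0[cbind(seq_len(nrow(X)), sample(1:2, nrow(X), TRUE))] <- 1
    a <- gmmnea:::.em_once(X, 2, m, cfg, resp0)
    b <- gmmnea:::.em_once_r(X, 2, m, cfg, resp0)
    expect_equal(a$loglik, b$loglik, tolerance = 1e-8, info = m)
    expect_equal(a$sigma, b$sigma, tolerance = 1e-6, info = m)
  }
})

test_that("mean recovery from a single spherical Gaussian", {
  set.seed(15)
  mu <- c(5, 1); s <- 0.3; n <- 500
  X <- cbind(rnorm(n, mu[1], s), rnorm(n, mu[2], s))
  fit <- em_fit(X, 1, "EII", quick_config())
  expect_true(all(abs(fit$mean[, 1] - mu) < 3 * s / sqrt(n)))
})

test_that("select_model maximizes BIC with a minimal-complexity tie rule", {
  # exactly spherical 4-point configuration: all one-component families give
  # the same log-likelihood, so the minimal parameter count (3) must win
  X <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) + 5
  sel <- select_model(X, fit_config(K_range = 1:2, restarts = 1, seed = 1))
  expect_identical(sel$K, 1L)
  expect_identical(sel$df, 3L)
  audit <- attr(sel, "audit")
  expect_true(all(c("K", "model", "loglik", "df", "bic") %in% names(audit)))
  # BIC penalty: among equal-loglik candidates a larger df never wins
  k1 <- audit[audit$K == 1 & !is.na(audit$loglik), ]
  same_ll <- k1[abs(k1$loglik - max(k1$loglik)) < 1e-9, ]
  expect_identical(min(same_ll$df), sel$df)
})

test_that("select_model recovers two well-separated components", {
  # mean gap >= 8 sd in both coordinates
  truth <- band_truth(1, weights = c(0.55, 0.45), mu1 = c(4.0, 5.6),
                      mu2 = c(0.8, 0.4), sd1 = c(0.15, 0.2),
                      sd2 = c(0.08, 0.05), rho = c(0.2, -0.1))$gmm
  ok <- 0L
  for (seed in 1:5) {
    set.seed(100 + seed)
    X <- gmm_simulate(truth, 800)
    sel <- select_model(X, quick_config(seed = seed))
    if (sel$K == 2L) {
      mu_hat <- sel$mean[, order(sel$mean[1, ])]
      rel <- abs(mu_hat - truth$mean) / abs(truth$mean)
      if (max(rel) < 0.05) ok <- ok + 1L
    }
  }
  expect_gte(ok, 4L)
})

test_that("degenerate inputs fail loudly", {
  X <- matrix(rep(c(1, 2), each = 20), ncol = 2) # zero variance
  expect_error(em_fit(X, 2, "VVV", quick_config()), "restarts failed")
  expect_error(em_fit(matrix(1:3, ncol = 1), 1, "VVV", quick_config()),
               "two columns")
  set.seed(16)
  # two tight, well-separated 5-point clusters: fits, but n = 10 <= df = 11
  Xs <- rbind(cbind(rnorm(5, 0, 0.1), rnorm(5, 0, 0.1)),
              cbind(rnorm(5, 10, 0.1), rnorm(5, 10, 0.1)))
  expect_warning(em_fit(Xs, 2, "VVV", quick_config()), "parameter count")
})
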