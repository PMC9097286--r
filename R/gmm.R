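## Bivariate Gaussian mixtures under eigen-decomposition covariance
## constraints (Sigma_k = lambda_k D_k A_k D_k'), fitted by EM with
## k-means++ seeded restarts and selected by BIC. The eight families with
## closed-form (or trivially iterated) M-steps are supported.

GMM_MODELS <- c("EII", "VII", "EEI", "VEI", "EVI", "VVI", "EEE", "VVV")

#' Number of free parameters of a constrained bivariate GMM
#'
#' `(K - 1)` mixing weights, `K * d` means, plus the covariance parameters
#' of the family: EII 1, VII K, EEI d, VEI K + (d-1), EVI 1 + K(d-1),
#' VVI Kd, EEE d(d+1)/2, VVV K d(d+1)/2.
#'
#' @param model family label (one of `r paste(GMM_MODELS, collapse = ", ")`).
#' @param K number of components.
#' @param d dimension (2).
#' @return integer parameter count.
#' @export
count_free_params <- function(model, K, d = 2L) {
  if (!model %in% GMM_MODELS)
    stop("unsupported covariance model: ", model, call. = FALSE)
  K <- as.integer(K); d <- as.integer(d)
  stopifnot(K >= 1L, d >= 1L)
  cov_pars <- switch(model,
    EII = 1L,
    VII = K,
    EEI = d,
    VEI = K + (d - 1L),
    EVI = 1L + K * (d - 1L),
    VVI = K * d,
    EEE = (d * (d + 1L)) %/% 2L,
    VVV = K * ((d * (d + 1L)) %/% 2L)
  )
  (K - 1L) + K * d + cov_pars
}

#' EM fit configuration
#'
#' @param K_range candidate component counts (default 1..9).
#' @param models candidate covariance families (default all eight).
#' @param restarts random k-means++ restarts per candidate (default 5).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @param floor_frac variance floor as a fraction of each dimension's data
#'   variance (default 1e-10); a component collapsing below it aborts the run.
#' @param seed integer seed controlling initialization.
#' @return a `fit_config` list.
#' @export
fit_config <- function(K_range = 1:9, models = GMM_MODELS, restarts = 5L,
                       tol = 1e-8, max_iter = 500L, floor_frac = 1e-10,
                       seed = NULL) {
  stopifnot(length(K_range) >= 1L, all(K_range >= 1L), tol > 0,
            max_iter >= 1L, all(models %in% GMM_MODELS))
  structure(list(K_range = sort(unique(as.integer(K_range))),
                 models = models, restarts = as.integer(restarts),
                 tol = tol, max_iter = as.integer(max_iter),
                 floor_frac = floor_frac, seed = seed),
            class = "fit_config")
}

## n x K matrix of log component densities for 2-D Gaussians given
## per-component (mu1, mu2, s1sq, s2sq, c12).
.log_dens_matrix <- function(X, mean, sigma) {
  n <- nrow(X); K <- ncol(mean)
  L <- matrix(0, n, K)
  for (k in seq_len(K)) {
    s1 <- sigma[1, 1, k]; s2 <- sigma[2, 2, k]; c12 <- sigma[1, 2, k]
    det <- s1 * s2 - c12^2
    if (!is.finite(det) || det <= 0) return(NULL)
    d1 <- X[, 1] - mean[1, k]; d2 <- X[, 2] - mean[2, k]
    qf <- (d1^2 * s2 - 2 * d1 * d2 * c12 + d2^2 * s1) / det
    L[, k] <- -log(2 * pi) - 0.5 * log(det) - 0.5 * qf
  }
  L
}

.estep <- function(X, pro, mean, sigma) {
  L <- .log_dens_matrix(X, mean, sigma)
  if (is.null(L)) return(NULL)
  L <- sweep(L, 2L, log(pro), "+")
  m <- do.call(pmax, c(as.data.frame(L), list(-Inf)))
  ls <- m + log(rowSums(exp(L - m)))
  list(loglik = sum(ls), resp = exp(L - ls))
}

## Family M-steps. W is a list of K weighted scatter matrices, nk the
## component counts; returns 2 x 2 x K covariance array or NULL on failure.
.mstep_cov <- function(model, W, nk, n, d = 2) {
  K <- length(nk)
  sig <- array(0, c(2, 2, K))
  fill_diag <- function(v1, v2, k) { sig[1, 1, k] <<- v1; sig[2, 2, k] <<- v2 }
  switch(model,
    EII = {
      lam <- sum(vapply(W, function(w) w[1, 1] + w[2, 2], 0)) / (d * n)
      for (k in seq_len(K)) fill_diag(lam, lam, k)
    },
    VII = {
      for (k in seq_len(K)) {
        lam <- (W[[k]][1, 1] + W[[k]][2, 2]) / (d * nk[k])
        fill_diag(lam, lam, k)
      }
    },
    EEI = {
      tot <- Reduce(`+`, W)
      for (k in seq_len(K)) fill_diag(tot[1, 1] / n, tot[2, 2] / n, k)
    },
    VEI = {
      ## Sigma_k = lambda_k B, B diagonal with unit determinant; alternate
      ## between lambda_k and B (converges in a few passes).
      lam <- vapply(seq_len(K), function(k)
        (W[[k]][1, 1] + W[[k]][2, 2]) / (d * nk[k]), 0)
      b <- c(1, 1)
      for (it in 1:20) {
        braw <- c(sum(vapply(seq_len(K), function(k) W[[k]][1, 1] / lam[k], 0)),
                  sum(vapply(seq_len(K), function(k) W[[k]][2, 2] / lam[k], 0)))
        if (any(braw <= 0)) return(NULL)
        b_new <- braw / sqrt(prod(braw))
        lam <- vapply(seq_len(K), function(k)
          (W[[k]][1, 1] / b_new[1] + W[[k]][2, 2] / b_new[2]) / (d * nk[k]), 0)
        if (max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
        b <- b_new
      }
      for (k in seq_len(K)) fill_diag(lam[k] * b[1], lam[k] * b[2], k)
    },
    EVI = {
      ## Sigma_k = lambda A_k, A_k diagonal with unit determinant.
      dets <- vapply(W, function(w) w[1, 1] * w[2, 2], 0)
      if (any(dets <= 0)) return(NULL)
      lam <- sum(sqrt(dets)) / n
      for (k in seq_len(K)) {
        a <- c(W[[k]][1, 1], W[[k]][2, 2]) / sqrt(dets[k])
        fill_diag(lam * a[1], lam * a[2], k)
      }
    },
    VVI = {
      for (k in seq_len(K))
        fill_diag(W[[k]][1, 1] / nk[k], W[[k]][2, 2] / nk[k], k)
    },
    EEE = {
      S <- Reduce(`+`, W) / n
      for (k in seq_len(K)) sig[, , k] <- S
    },
    VVV = {
      for (k in seq_len(K)) sig[, , k] <- W[[k]] / nk[k]
    }
  )
  sig
}

## k-means++ center seeding followed by nearest-center hard assignment.
.kmeanspp_resp <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1], ], "-")^2)
  if (K > 1L) for (k in 2:K) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[k] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[k], ], "-")^2))
  }
  D <- vapply(centers, function(j) rowSums(sweep(X, 2L, X[j, ], "-")^2),
              numeric(n))
  assign <- max.col(-D, ties.method = "first")
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), assign)] <- 1
  resp
}

## Compiled EM loop (src/em.cpp); the pure-R twin .em_once_r below is kept
## as an independent reference implementation exercised by the tests.
.em_once <- function(X, K, model, config, resp) {
  out <- .em_loop_cpp(X, resp, model, config$tol, config$max_iter,
                      .variance_floor(X, config), 0.1)
  if (!isTRUE(out$ok)) return(NULL)
  if (isTRUE(out$decreased))
    warning("EM log-likelihood decreased (numerical); model ", model,
            ", K = ", K, call. = FALSE)
  out[c("loglik", "pro", "mean", "sigma", "resp", "iterations", "trace")]
}

## Variance floor per dimension: tied to the data variance, but never below
## a sliver of the squared data magnitude, so exactly-degenerate inputs
## (zero spread, variance ~ rounding noise) are still rejected.
.variance_floor <- function(X, config) {
  config$floor_frac *
    pmax(apply(X, 2L, stats::var), 1e-10 * colMeans(X^2), 1e-300)
}

.em_once_r <- function(X, K, model, config, resp) {
  n <- nrow(X)
  vfloor <- .variance_floor(X, config)
  ll_old <- -Inf
  trace <- numeric(0)
  pro <- mean <- sigma <- NULL
  for (iter in seq_len(config$max_iter)) {
    nk <- colSums(resp)
    if (any(nk < max(1 / (10 * n) * n, 1e-8))) return(NULL) # collapsed weight
    pro <- nk / n
    mean <- t(crossprod(resp, X) / nk) # 2 x K
    W <- lapply(seq_len(K), function(k) {
      xc <- sweep(X, 2L, mean[, k])
      crossprod(xc * resp[, k], xc)
    })
    sigma <- .mstep_cov(model, W, nk, n)
    if (is.null(sigma)) return(NULL)
    if (any(sigma[1, 1, ] < vfloor[1]) || any(sigma[2, 2, ] < vfloor[2]))
      return(NULL) # degenerate component
    es <- .estep(X, pro, mean, sigma)
    if (is.null(es) || !is.finite(es$loglik)) return(NULL)
    trace <- c(trace, es$loglik)
    if (es$loglik < ll_old - 1e-8 * (abs(ll_old) + 1))
      warning("EM log-likelihood decreased (numerical); model ", model,
              ", K = ", K, call. = FALSE)
    done <- is.finite(ll_old) &&
      abs(es$loglik - ll_old) <= config$tol * (abs(es$loglik) + 1e-3)
    ll_old <- es$loglik
    resp <- es$resp
    if (done) break
  }
  list(loglik = ll_old, pro = pro, mean = mean, sigma = sigma,
       resp = resp, iterations = length(trace), trace = trace)
}

#' Fit a constrained bivariate Gaussian mixture by EM
#'
#' Best of `config$restarts` k-means++-seeded runs; the returned covariances
#' respect the family constraint exactly and the log-likelihood is
#' non-decreasing over iterations.
#'
#' @param X numeric matrix with n rows and 2 columns.
#' @param K number of mixture components.
#' @param model covariance family label.
#' @param config a [fit_config()].
#' @return a `gmm_params` object: `K`, `model`, `pro`, `mean` (2 x K),
#'   `sigma` (2 x 2 x K), `loglik`, `n`, `df`, `bic`, plus the
#'   log-likelihood `trace` of the winning run.
#' @export
em_fit <- function(X, K, model, config = fit_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != 2L) stop("`X` must have two columns", call. = FALSE)
  n <- nrow(X)
  K <- as.integer(K)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (n < K) stop("fewer observations than components", call. = FALSE)
  df <- count_free_params(model, K)
  if (n <= df)
    warning("sample size ", n, " does not exceed parameter count ", df,
            " (model ", model, ", K = ", K, ")", call. = FALSE)
  nrestart <- if (K == 1L) 1L else config$restarts
  best <- NULL
  with_seed(config$seed, {
    for (r in seq_len(nrestart)) {
      resp <- if (K == 1L) matrix(1, n, 1L) else .kmeanspp_resp(X, K)
      fit <- .em_once(X, K, model, config, resp)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
        best <- fit
    }
  })
  if (is.null(best))
    stop("all ", nrestart, " EM restarts failed (model ", model, ", K = ", K,
         "): components collapsed or covariance became singular",
         call. = FALSE)
  structure(
    list(K = K, model = model, pro = best$pro, mean = best$mean,
         sigma = best$sigma, loglik = best$loglik, n = n, df = df,
         bic = 2 * best$loglik - df * log(n),
         iterations = best$iterations, trace = best$trace),
    class = "gmm_params"
  )
}

#' @export
print.gmm_params <- function(x, ...) {
  cat(sprintf("<gmm_params> K = %d, model = %s, loglik = %.4f, BIC = %.4f (n = %d, df = %d)\n",
              x$K, x$model, x$loglik, x$bic, x$n, x$df))
  invisible(x)
}

#' Per-component parameters in (variance, correlation) form
#'
#' @param gmm a `gmm_params` object.
#' @return data frame with one row per component: `pro`, `mu1`, `mu2`,
#'   `s1sq`, `s2sq`, `rho`.
#' @export
gmm_component_params <- function(gmm) {
  K <- gmm$K
  data.frame(
    component = seq_len(K),
    pro = gmm$pro,
    mu1 = gmm$mean[1, ], mu2 = gmm$mean[2, ],
    s1sq = gmm$sigma[1, 1, seq_len(K)],
    s2sq = gmm$sigma[2, 2, seq_len(K)],
    rho = gmm$sigma[1, 2, seq_len(K)] /
      sqrt(gmm$sigma[1, 1, seq_len(K)] * gmm$sigma[2, 2, seq_len(K)])
  )
}

#' Mixture density of a fitted GMM
#'
#' @param gmm a `gmm_params` object (weights need not sum to 1; they are
#'   used as given).
#' @param X n x 2 matrix of evaluation points.
#' @return density values of length n.
#' @export
gmm_density <- function(gmm, X) {
  X <- as.matrix(X)
  L <- .log_dens_matrix(X, gmm$mean, gmm$sigma)
  as.numeric(exp(L) %*% gmm$pro)
}

#' Draw from a fitted GMM
#'
#' @param gmm a `gmm_params` object with weights summing to 1.
#' @param n number of draws.
#' @return n x 2 matrix.
#' @export
gmm_simulate <- function(gmm, n) {
  pars <- gmm_component_params(gmm)
  comp <- sample.int(gmm$K, n, replace = TRUE, prob = gmm$pro / sum(gmm$pro))
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  s1 <- sqrt(pars$s1sq[comp]); s2 <- sqrt(pars$s2sq[comp])
  rho <- pars$rho[comp]
  cbind(pars$mu1[comp] + s1 * z1,
        pars$mu2[comp] + s2 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' BIC model selection over component counts and covariance families
#'
#' Fits every (K, model) candidate in `config` and returns the fit
#' maximizing `BIC = 2 loglik - df log(n)`; ties go to the smaller
#' parameter count, then the smaller K. The full audit of attempted
#' candidates is attached as attribute `"audit"`.
#'
#' @param X numeric matrix with n rows and 2 columns.
#' @param config a [fit_config()].
#' @return the winning `gmm_params`, with attribute `audit` (data frame of
#'   K, model, loglik, df, bic, error).
#' @export
select_model <- function(X, config = fit_config()) {
  X <- as.matrix(X)
  cands <- expand.grid(K = config$K_range, model = config$models,
                       stringsAsFactors = FALSE)
  fits <- vector("list", nrow(cands))
  audit <- cands
  audit$loglik <- audit$bic <- NA_real_
  audit$df <- NA_integer_
  audit$error <- NA_character_
  seeds <- if (is.null(config$seed)) rep(list(NULL), nrow(cands))
           else as.list(config$seed + seq_len(nrow(cands)))
  for (i in seq_len(nrow(cands))) {
    cfg_i <- config
    cfg_i$seed <- seeds[[i]]
    fit <- tryCatch(
      withCallingHandlers(
        em_fit(X, cands$K[i], cands$model[i], cfg_i),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(fit, "error")) {
      audit$error[i] <- conditionMessage(fit)
    } else {
      fits[[i]] <- fit
      audit$loglik[i] <- fit$loglik
      audit$df[i] <- fit$df
      audit$bic[i] <- fit$bic
    }
  }
  ok <- which(!is.na(audit$bic))
  if (!length(ok))
    stop("every (K, model) candidate failed to fit:\n",
         paste(utils::head(paste0("  ", audit$model, " K=", audit$K, ": ",
                                  audit$error), 10L), collapse = "\n"),
         call. = FALSE)
  best_bic <- max(audit$bic[ok])
  eps <- 1e-7 * max(1, abs(best_bic))
  tied <- ok[audit$bic[ok] >= best_bic - eps]
  tied <- tied[order(audit$df[tied], audit$K[tied])]
  winner <- fits[[tied[1L]]]
  attr(winner, "audit") <- audit
  winner
}
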