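## Shared fixtures, built in code.

HA_EV <- 27.211386245988

## 2 geometries x 3 states, hand-written
toy_table <- function() {
  ensemble_table(data.frame(
    geom_id = rep(c("g1", "g2"), each = 3),
    state = rep(1:3, 2),
    delta_E = c(4.0, 5.0, 6.0, 4.2, 5.1, 6.3),
    f = c(0.10, 0.02, 0.00, 0.12, 0.03, 0.01)
  ))
}

## fast config for model selection in unit tests
quick_config <- function(seed = 1, K_range = 1:3, restarts = 2L)
  fit_config(K_range = K_range, restarts = restarts, seed = seed)

## single unimodal correlated truth (band 1 of the demo fixture)
truth1 <- function() demo_truths()[[1]]

## trapezoid rule, independent of the package's internal integrator
trapz_ref <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1])) / 2

## independent mixture pdf evaluation from plain parameters (used by the
## quadrature oracle; deliberately avoids gmm_density)
mix_pdf_ref <- function(pars, de, m) {
  out <- 0
  for (k in seq_len(nrow(pars))) {
    s1 <- sqrt(pars$s1sq[k]); s2 <- sqrt(pars$s2sq[k]); r <- pars$rho[k]
    z1 <- (de - pars$mu1[k]) / s1
    z2 <- (m - pars$mu2[k]) / s2
    out <- out + pars$pro[k] / (2 * pi * s1 * s2 * sqrt(1 - r^2)) *
      exp(-(z1^2 - 2 * r * z1 * z2 + z2^2) / (2 * (1 - r^2)))
  }
  out
}

## brute-force pre-limit spectrum: 2-D quadrature of
## C(E) dE_eV (2/3) dE_Ha M^2 g(E - dE, delta) p(dE, M) over (dE, M)
quadrature_spectrum_ref <- function(band, grid, delta = 1e-4) {
  pars <- gmm_component_params(band$gmm)
  de_lo <- min(pars$mu1 - 9 * sqrt(pars$s1sq))
  de_hi <- max(pars$mu1 + 9 * sqrt(pars$s1sq))
  m_lo <- max(min(pars$mu2 - 9 * sqrt(pars$s2sq)), 1e-9)
  m_hi <- max(pars$mu2 + 9 * sqrt(pars$s2sq))
  m_nodes <- seq(m_lo, m_hi, length.out = 601)
  dm <- m_nodes[2] - m_nodes[1]
  vapply(as.numeric(grid), function(E) {
    ## g( E - dE, delta ) confines dE to E +/- 8 delta
    de_nodes <- seq(max(E - 8 * delta, de_lo), min(E + 8 * delta, de_hi),
                    length.out = 161)
    if (de_nodes[1] >= de_nodes[length(de_nodes)]) return(0)
    dde <- de_nodes[2] - de_nodes[1]
    g <- stats::dnorm(E - de_nodes, sd = delta / 2)
    P <- outer(de_nodes, m_nodes, function(a, b) mix_pdf_ref(pars, a, b))
    inner <- as.numeric(P %*% (m_nodes^2)) * dm     # int M^2 p dM at each dE
    (1 / E) * sum(de_nodes * (2 / 3) * (de_nodes / HA_EV) * g * inner) * dde
  }, numeric(1))
}
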