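#' Robust location and scatter estimates
#'
#' Location is the coordinatewise median; scatter is the covariance of the
#' median-centered observations, `S = M_X' M_X / (n - 1)` — both immune to
#' a small number of gross anomalies, unlike the mean/covariance pair.
#'
#' @param X numeric n x p matrix.
#' @return list with `center` (length p) and `scatter` (p x p).
#' @export
robust_estimates <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  center <- apply(X, 2L, stats::median)
  Mx <- sweep(X, 2L, center)
  list(center = center, scatter = crossprod(Mx) / (n - 1))
}

#' Squared Mahalanobis distances under given estimates
#'
#' @param X numeric n x p matrix.
#' @param estimates list with `center` and `scatter` (e.g. from
#'   [robust_estimates()]).
#' @return non-negative distances, one per row of `X`.
#' @export
robust_mahalanobis_sq <- function(X, estimates = robust_estimates(X)) {
  X <- as.matrix(X)
  S <- estimates$scatter
  r <- qr(S)$rank
  if (r < ncol(S))
    stop("scatter matrix is singular (rank ", r, " < ", ncol(S),
         "); reduce the dimension, e.g. screen per band instead of jointly",
         call. = FALSE)
  stats::mahalanobis(X, estimates$center, S)
}

## Core screen on one matrix: chi-squared p-values + FDR labeling.
.screen_matrix <- function(X, q, rule = c("step-up", "literal")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L)
    stop("need at least p + 2 = ", p + 2L, " observations (got ", n, ")",
         call. = FALSE)
  d2 <- robust_mahalanobis_sq(X)
  pv <- stats::pchisq(d2, df = p, lower.tail = FALSE)
  rk <- rank(pv, ties.method = "first")
  flagged <- logical(n)
  if (rule == "step-up") {
    ord <- order(pv)
    pass <- which(pv[ord] <= seq_len(n) * q / n)
    if (length(pass)) flagged[ord[seq_len(max(pass))]] <- TRUE
  } else {
    flagged <- pv <= rk * q / n
  }
  data.frame(D2 = d2, p = pv, rank = rk, flagged = flagged)
}

#' FDR screening of anomalous quantum-chemistry points
#'
#' Squared robust Mahalanobis distances are referred to a chi-squared
#' distribution with p degrees of freedom; observations are labeled
#' outliers by the rank-based FDR rule at level `q` (default 0.001, i.e.
#' under 0.1% expected false detections). For an ensemble, screening runs
#' by default per band on the (delta_E, M) pairs, with a geometry flagged
#' if any of its bands flags it; `mode = "joint"` concatenates all bands
#' into one 2 N_s-dimensional vector per geometry and falls back to
#' per-band (with a warning) when n is too small for the joint scatter.
#'
#' @param X an [ensemble_table()] or a plain numeric matrix.
#' @param q FDR level in (0, 1].
#' @param mode `"per-band"` (default) or `"joint"` (ensembles only).
#' @param rule `"step-up"` (default; standard FDR: flag all ranks up to the
#'   largest i with `p_(i) <= i q / n`) or `"literal"` per-rank
#'   thresholding.
#' @return an `outlier_report` data frame (geom_id, band, D2, p, rank,
#'   flagged) with attributes `q`, `mode`, `rule` and `flagged_geoms`; for
#'   matrix input, the per-observation table.
#' @export
fdr_screen <- function(X, q = 0.001, mode = c("per-band", "joint"),
                       rule = c("step-up", "literal")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop("`q` must lie in (0, 1]", call. = FALSE)
  if (!inherits(X, "nea_ensemble")) {
    rep <- .screen_matrix(X, q, rule)
    return(structure(rep, q = q, mode = "matrix", rule = rule,
                     class = c("outlier_report", "data.frame")))
  }
  states <- ensemble_states(X)
  ng <- n_geometries(X)
  if (mode == "joint" && ng < 2L * length(states) + 2L) {
    warning("joint mode needs n >= 2 N_s + 2 (", 2L * length(states) + 2L,
            " > ", ng, "); falling back to per-band screening",
            call. = FALSE)
    mode <- "per-band"
  }
  if (mode == "joint") {
    samples <- lapply(states, extract_band, table = X)
    Xj <- do.call(cbind, lapply(samples, function(s) cbind(s$delta_E, s$M)))
    rep <- .screen_matrix(Xj, q, rule)
    out <- cbind(data.frame(geom_id = samples[[1]]$geom_id,
                            band = NA_integer_), rep)
  } else {
    rows <- lapply(states, function(n) {
      s <- extract_band(X, n)
      rep <- .screen_matrix(cbind(s$delta_E, s$M), q, rule)
      cbind(data.frame(geom_id = s$geom_id, band = n), rep)
    })
    out <- do.call(rbind, rows)
  }
  flagged_geoms <- sort(unique(out$geom_id[out$flagged]))
  structure(out, q = q, mode = mode, rule = rule,
            flagged_geoms = flagged_geoms,
            class = c("outlier_report", "data.frame"))
}

#' Geometries flagged by a screening report
#' @param report an `outlier_report`.
#' @return character vector of flagged geometry ids.
#' @export
flagged_geometries <- function(report) attr(report, "flagged_geoms")

#' Drop flagged geometries from an ensemble
#'
#' @param table an [ensemble_table()].
#' @param report an `outlier_report` from [fdr_screen()].
#' @return a re-validated [ensemble_table()] without the flagged geometries.
#' @export
remove_outliers <- function(table, report) {
  bad <- flagged_geometries(report)
  if (!length(bad)) return(table)
  ensemble_table(as.data.frame(table)[!table$geom_id %in% bad, ])
}

#' Write a QC report as CSV
#' @param report an `outlier_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# q=%g mode=%s rule=%s flagged=%d",
                     attr(report, "q"), attr(report, "mode"),
                     attr(report, "rule"),
                     length(attr(report, "flagged_geoms"))), con)
  utils::write.csv(as.data.frame(report), con, row.names = FALSE)
  invisible(path)
}
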