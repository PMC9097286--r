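#' Write a full spectrum as CSV
#'
#' Columns: `energy_eV`, `sigma_total`, `sigma_ci_low`, `sigma_ci_high`
#' (when present), then a `sigma_n<state>` / `ci_low_n<state>` /
#' `ci_high_n<state>` triple per band. Comment lines (prefixed `#`) carry
#' provenance such as the seed.
#'
#' @param spec a `full_spectrum`.
#' @param path output path.
#' @param comments character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, comments = character()) {
  stopifnot(inherits(spec, "full_spectrum"))
  df <- data.frame(energy_eV = as.numeric(spec$grid),
                   sigma_total = spec$total)
  if (!is.null(spec$ci_low)) {
    df$sigma_ci_low <- spec$ci_low
    df$sigma_ci_high <- spec$ci_high
  }
  for (b in spec$bands) {
    df[[paste0("sigma_n", b$state)]] <- b$sigma
    if (!is.null(b$ci_low)) {
      df[[paste0("ci_low_n", b$state)]] <- b$ci_low
      df[[paste0("ci_high_n", b$state)]] <- b$ci_high
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum CSV written by [write_spectrum()]
#'
#' @param path path to the CSV.
#' @return a `full_spectrum` (prefactor mode unknown: recorded as written,
#'   defaulting to `"arbitrary"`).
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  grid <- structure(df$energy_eV, class = "energy_grid")
  states <- as.integer(sub("^sigma_n", "",
                           grep("^sigma_n", names(df), value = TRUE)))
  bands <- lapply(states, function(n) {
    structure(list(state = n, grid = grid,
                   sigma = df[[paste0("sigma_n", n)]],
                   ci_low = df[[paste0("ci_low_n", n)]],
                   ci_high = df[[paste0("ci_high_n", n)]],
                   prefactor_mode = "arbitrary"),
              class = "band_spectrum")
  })
  structure(list(grid = grid, total = df$sigma_total, bands = bands,
                 ci_low = df$sigma_ci_low, ci_high = df$sigma_ci_high,
                 prefactor_mode = "arbitrary"),
            class = "full_spectrum")
}
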