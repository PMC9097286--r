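#' Construct and validate an ensemble table
#'
#' The canonical container for nuclear-ensemble quantum-chemistry output:
#' one row per (geometry, transition) with the vertical excitation energy
#' `delta_E` (eV) and oscillator strength `f`. The grid must be complete —
#' every geometry carries the same set of transitions — because bootstrap
#' resampling draws whole geometries jointly across transitions.
#'
#' @param df a data frame with columns `geom_id`, `state`, `delta_E`, `f`.
#' @return A validated `nea_ensemble` data frame sorted by (geom_id, state),
#'   with attributes `n_geom` and `n_state`.
#' @export
ensemble_table <- function(df) {
  required <- c("geom_id", "state", "delta_E", "f")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[required]
  if (nrow(df) == 0L)
    stop("ensemble table is empty (no rows)", call. = FALSE)
  df$geom_id <- as.character(df$geom_id)
  df$state <- as.integer(df$state)
  if (any(is.na(df$state)) || any(df$state < 1L))
    stop("`state` must be integer transition indices >= 1", call. = FALSE)
  bad_e <- which(!is.finite(df$delta_E) | df$delta_E <= 0)
  if (length(bad_e))
    stop("non-positive or non-finite delta_E at row(s) ",
         paste(utils::head(bad_e, 5L), collapse = ", "), call. = FALSE)
  bad_f <- which(!is.finite(df$f) | df$f < 0)
  if (length(bad_f))
    stop("negative or non-finite f at row(s) ",
         paste(utils::head(bad_f, 5L), collapse = ", "), call. = FALSE)
  key <- paste(df$geom_id, df$state, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (geom_id, state) pair(s): ",
         paste(utils::head(sub("\r", ", ", key[dup]), 5L), collapse = "; "),
         call. = FALSE)
  geoms <- sort(unique(df$geom_id))
  states <- sort(unique(df$state))
  if (nrow(df) != length(geoms) * length(states)) {
    full <- expand.grid(geom_id = geoms, state = states,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    fkey <- paste(full$geom_id, full$state, sep = "\r")
    miss <- setdiff(fkey, key)
    stop("incomplete state grid; missing (geom_id, state) pair(s): ",
         paste(utils::head(sub("\r", ", ", miss), 5L), collapse = "; "),
         if (length(miss) > 5L) " ..." else "", call. = FALSE)
  }
  df <- df[order(df$geom_id, df$state), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_geom = length(geoms), n_state = length(states),
            class = c("nea_ensemble", "data.frame"))
}

#' Read an ensemble table from CSV
#'
#' The canonical dialect is a UTF-8 header CSV with columns
#' `geom_id,state,delta_E,f` and '.' as decimal separator; `dialect` maps
#' those canonical names onto the file's actual headers.
#'
#' @param path path to the CSV file.
#' @param dialect named character vector mapping canonical column names to
#'   the file's column names, e.g. `c(delta_E = "dE_eV")`.
#' @return A validated [ensemble_table()].
#' @export
read_ensemble <- function(path, dialect = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  for (canon in names(dialect)) {
    j <- match(dialect[[canon]], names(df))
    if (is.na(j))
      stop("dialect column `", dialect[[canon]], "` not present in file",
           call. = FALSE)
    names(df)[j] <- canon
  }
  ensemble_table(df)
}

#' Write an ensemble table as canonical CSV
#'
#' @param table an [ensemble_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(table, path) {
  stopifnot(inherits(table, "nea_ensemble"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Number of geometries / states in an ensemble
#' @param table an [ensemble_table()].
#' @return integer count.
#' @export
n_geometries <- function(table) attr(table, "n_geom")

#' @rdname n_geometries
#' @export
n_states <- function(table) attr(table, "n_state")

#' States present in an ensemble
#' @param table an [ensemble_table()].
#' @return sorted integer vector of transition indices.
#' @export
ensemble_states <- function(table) sort(unique(table$state))

#' Extract one transition's sample from an ensemble
#'
#' Returns the per-geometry arrays for a single transition, with the
#' oscillator strengths converted to transition dipole moments (atomic
#' units) via [dipole_from_strength()].
#'
#' @param table an [ensemble_table()].
#' @param n transition index present in `table`.
#' @return A `transition_sample`: list with `state`, `geom_id`, `delta_E`
#'   (eV), `f`, and `M` (a.u.), aligned by geometry order.
#' @export
extract_band <- function(table, n) {
  stopifnot(inherits(table, "nea_ensemble"))
  n <- as.integer(n)
  rows <- table$state == n
  if (!any(rows))
    stop("state ", n, " not present in ensemble (states: ",
         paste(ensemble_states(table), collapse = ", "), ")", call. = FALSE)
  sub <- table[rows, , drop = FALSE]
  sub <- sub[order(sub$geom_id), , drop = FALSE]
  structure(
    list(state = n, geom_id = sub$geom_id, delta_E = sub$delta_E, f = sub$f,
         M = dipole_from_strength(sub$delta_E, sub$f)),
    class = "transition_sample"
  )
}

#' @export
print.transition_sample <- function(x, ...) {
  cat("<transition_sample> state", x$state, "-", length(x$delta_E),
      "geometries;", sum(x$f == 0), "dark (f = 0)\n")
  invisible(x)
}

## Reassemble an ensemble from a list of transition samples (test utility,
## inverse of extract_band over all states).
assemble_bands <- function(samples) {
  dfs <- lapply(samples, function(s)
    data.frame(geom_id = s$geom_id, state = s$state, delta_E = s$delta_E,
               f = s$f, stringsAsFactors = FALSE))
  ensemble_table(do.call(rbind, dfs))
}
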