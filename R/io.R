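#' Read an energy time series from disk
#'
#' Three dialects are supported:
#'
#' * `plain2col` — whitespace- or comma-separated columns `e_p`, `e_pw`,
#'   one frame per line; lines starting with `#` are comments.
#' * `plain3col` — columns `time`, `e_p`, `e_pw`; the time column is
#'   validated as a uniform grid of spacing `delta` (maximum deviation
#'   below `1e-6 * delta`) and then discarded.
#' * `namd_log` — a NAMD-style log: one `ETITLE:` header names the columns,
#'   every `ENERGY:` line carries one frame. `e_p` and `e_pw` are formed by
#'   summing the user-named column sets `p_columns` and `pw_columns` per
#'   frame (the force-field decomposition into protein self and
#'   protein-water terms is the user's declaration, not the package's).
#'
#' Parsing never silently drops frames: the returned length equals the
#' number of non-comment data lines, and any ragged row, non-numeric field
#' or grid violation raises a format error naming the offending line.
#'
#' @param path File to read.
#' @param delta Sampling interval between frames (time units, > 0).
#' @param dialect One of `"plain2col"`, `"plain3col"`, `"namd_log"`.
#' @param trajectory_id Identifier for the series; defaults to the file
#'   name without extension.
#' @param p_columns,pw_columns Character vectors of ETITLE column names to
#'   sum into `e_p` and `e_pw` (namd_log only).
#' @return An [energy_series()] tibble.
#' @export
read_energy_series <- function(path, delta,
                               dialect = c("plain2col", "plain3col", "namd_log"),
                               trajectory_id = NULL,
                               p_columns = NULL, pw_columns = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_io(sprintf("file not found: '%s'", path))
  if (is.null(trajectory_id)) {
    trajectory_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "namd_log") {
    return(parse_namd_log(lines, path, delta, trajectory_id, p_columns, pw_columns))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  data_idx <- which(keep)
  if (length(data_idx) == 0L) {
    stop_format(sprintf("'%s': empty series (no data lines).", path))
  }
  want <- if (dialect == "plain2col") 2L else 3L
  mat <- matrix(NA_real_, nrow = length(data_idx), ncol = want)
  for (i in seq_along(data_idx)) {
    ln <- data_idx[i]
    fields <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1]]
    if (length(fields) != want) {
      stop_format(sprintf(
        "'%s' line %d: expected %d fields, found %d.", path, ln, want, length(fields)
      ))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop_format(sprintf("'%s' line %d: non-numeric field.", path, ln))
    }
    mat[i, ] <- vals
  }
  if (dialect == "plain3col") {
    tgrid <- mat[, 1L]
    expected <- tgrid[1L] + delta * (seq_along(tgrid) - 1)
    dev <- abs(tgrid - expected)
    if (any(dev >= 1e-6 * delta)) {
      bad <- data_idx[which.max(dev)]
      stop_format(sprintf(
        "'%s' line %d: time column deviates from the uniform grid (delta = %g).",
        path, bad, delta
      ))
    }
    mat <- mat[, -1L, drop = FALSE]
  }
  if (nrow(mat) < 2L) {
    stop_format(sprintf("'%s': a series needs at least 2 frames, found %d.", path, nrow(mat)))
  }
  energy_series(mat[, 1L], mat[, 2L], delta = delta, trajectory_id = trajectory_id)
}

parse_namd_log <- function(lines, path, delta, trajectory_id,
                           p_columns, pw_columns) {
  if (is.null(p_columns) || is.null(pw_columns)) {
    stop_validation("namd_log dialect requires `p_columns` and `pw_columns`.")
  }
  split_fields <- function(x) strsplit(trimws(x), "[[:space:]]+")[[1]]
  title_idx <- which(startsWith(lines, "ETITLE:"))
  if (length(title_idx) == 0L) {
    stop_format(sprintf("'%s': no ETITLE: header found.", path))
  }
  header <- split_fields(lines[title_idx[1L]])[-1L]
  for (set in list(p_columns, pw_columns)) {
    missing <- setdiff(set, header)
    if (length(missing) > 0L) {
      stop_format(sprintf(
        "'%s': column(s) %s not present in ETITLE header.",
        path, paste(sprintf("'%s'", missing), collapse = ", ")
      ))
    }
  }
  energy_idx <- which(startsWith(lines, "ENERGY:"))
  if (length(energy_idx) == 0L) {
    stop_format(sprintf("'%s': empty series (no ENERGY: lines).", path))
  }
  e_p <- numeric(length(energy_idx))
  e_pw <- numeric(length(energy_idx))
  p_pos <- match(p_columns, header)
  pw_pos <- match(pw_columns, header)
  for (i in seq_along(energy_idx)) {
    ln <- energy_idx[i]
    fields <- split_fields(lines[ln])[-1L]
    if (length(fields) != length(header)) {
      stop_format(sprintf(
        "'%s' line %d: ENERGY line has %d fields but ETITLE names %d columns.",
        path, ln, length(fields), length(header)
      ))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals[c(p_pos, pw_pos)])) {
      stop_format(sprintf("'%s' line %d: non-numeric energy field.", path, ln))
    }
    e_p[i] <- sum(vals[p_pos])
    e_pw[i] <- sum(vals[pw_pos])
  }
  if (length(e_p) < 2L) {
    stop_format(sprintf("'%s': a series needs at least 2 frames, found %d.", path, length(e_p)))
  }
  energy_series(e_p, e_pw, delta = delta, trajectory_id = trajectory_id)
}

#' Write an energy series as plain3col text
#'
#' Writes `time e_p e_pw` with full (17 significant digit) precision so that
#' `read_energy_series(write_energy_series(s), dialect = "plain3col")`
#' reproduces `s` bit for bit. Multi-trajectory sets must be written one
#' trajectory per file.
#'
#' @param series An [energy_series()] tibble holding a single trajectory.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_energy_series <- function(series, path) {
  if (length(unique(series$trajectory_id)) != 1L) {
    stop_validation("write one trajectory per file; split the set first.")
  }
  delta <- sampling_interval(series)
  tgrid <- series$frame * delta
  body <- sprintf("%.17g %.17g %.17g", tgrid, series$e_p, series$e_pw)
  header <- c(
    sprintf("# trajectory_id: %s", series$trajectory_id[1L]),
    sprintf("# delta: %.17g", delta),
    "# time e_p e_pw (kcal/mol)"
  )
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write '%s'.", path))
  invisible(path)
}
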