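#' Build an energy time-series tibble
#'
#' The central data container: a tibble with one row per frame and columns
#' `trajectory_id`, `frame` (0-based index on a uniform grid of spacing
#' `delta`), `e_p` (protein self energy, kcal/mol) and `e_pw` (protein-water
#' interaction energy, kcal/mol). The total energy `e_tot = e_p + e_pw` is
#' never stored; it is recomputed wherever needed so that the variance
#' decomposition Var(e_tot) = Var(e_p) + Var(e_pw) + 2 Cov(e_p, e_pw) is a
#' testable identity of the data, not an assumption.
#'
#' Several trajectories sharing one sampling interval live in a single tibble
#' distinguished by `trajectory_id` (a trajectory set).
#'
#' @param e_p Numeric vector of protein self energies (kcal/mol).
#' @param e_pw Numeric vector of protein-water interaction energies
#'   (kcal/mol), same length as `e_p`.
#' @param delta Sampling interval between consecutive frames (time units,
#'   > 0).
#' @param trajectory_id Character scalar identifying the trajectory.
#' @return A tibble of class `energy_series` with attribute `delta`.
#' @examples
#' es <- energy_series(c(1, 1.5, 2), c(2, 1, 0), delta = 10)
#' energy_total(es)
#' @export
energy_series <- function(e_p, e_pw, delta, trajectory_id = "traj1") {
  if (!is.numeric(e_p) || !is.numeric(e_pw)) {
    stop_validation("`e_p` and `e_pw` must be numeric vectors.")
  }
  if (length(e_p) != length(e_pw)) {
    stop_size(sprintf(
      "`e_p` (length %d) and `e_pw` (length %d) must have equal length.",
      length(e_p), length(e_pw)
    ))
  }
  if (length(e_p) < 2L) {
    stop_size("an energy series needs at least 2 frames.")
  }
  if (anyNA(e_p) || anyNA(e_pw)) {
    stop_validation("energy series must not contain missing values.")
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0) {
    stop_validation("`delta` must be a single positive number.")
  }
  out <- tibble(
    trajectory_id = as.character(trajectory_id),
    frame = seq_along(e_p) - 1L,
    e_p = as.numeric(e_p),
    e_pw = as.numeric(e_pw)
  )
  new_energy_series(out, delta)
}

new_energy_series <- function(df, delta) {
  structure(
    df,
    delta = as.numeric(delta),
    class = c("energy_series", class(tibble()))
  )
}

#' Combine trajectories into one trajectory set
#'
#' Stacks several [energy_series()] tibbles that share a sampling interval.
#' Member lengths may differ; `trajectory_id`s must be distinct.
#'
#' @param ... `energy_series` objects, or a single list of them.
#' @return An `energy_series` tibble holding all trajectories.
#' @export
trajectory_set <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "energy_series")) {
    parts <- parts[[1]]
  }
  if (length(parts) == 0L) stop_size("at least one energy series is required.")
  ok <- vapply(parts, inherits, logical(1), "energy_series")
  if (!all(ok)) stop_validation("all arguments must be `energy_series` objects.")
  deltas <- vapply(parts, sampling_interval, numeric(1))
  if (max(deltas) - min(deltas) > 1e-12 * max(deltas)) {
    stop_validation("all members of a trajectory set must share `delta`.")
  }
  ids <- unlist(lapply(parts, function(p) unique(p$trajectory_id)))
  if (anyDuplicated(ids)) {
    stop_validation("trajectory ids must be distinct across the set.")
  }
  new_energy_series(bind_rows(lapply(parts, as_tibble)), deltas[[1]])
}

#' Sampling interval of an energy series
#' @param series An `energy_series` tibble.
#' @return The grid spacing `delta` (time units).
#' @export
sampling_interval <- function(series) {
  d <- attr(series, "delta", exact = TRUE)
  if (is.null(d)) stop_validation("not an `energy_series`: missing `delta` attribute.")
  d
}

#' Total energy of each frame
#'
#' @param series An `energy_series` tibble.
#' @return Numeric vector `e_p + e_pw`, one value per frame.
#' @export
energy_total <- function(series) {
  series$e_p + series$e_pw
}

#' Lengths of the trajectories in a set
#' @param series An `energy_series` tibble (one or many trajectories).
#' @return Named integer vector of frame counts, in order of first appearance.
#' @export
trajectory_lengths <- function(series) {
  ids <- unique(series$trajectory_id)
  vapply(ids, function(id) sum(series$trajectory_id == id), integer(1))
}

#' @export
print.energy_series <- function(x, ...) {
  ids <- unique(x$trajectory_id)
  cat(sprintf(
    "<energy_series> %d frame%s, %d trajector%s, delta = %g\n",
    nrow(x), if (nrow(x) == 1) "" else "s",
    length(ids), if (length(ids) == 1) "y" else "ies",
    sampling_interval(x)
  ))
  NextMethod()
}
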