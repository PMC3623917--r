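#' Plan analysis windows at one time scale
#'
#' At time scale `tau`, a window is `n = 2^m` frames spaced `s = tau/delta`
#' frames apart, fully contained in one trajectory. Window starts are placed
#' deterministically and evenly ("even" mode): windows are first allocated
#' to trajectories proportionally to their admissible start ranges
#' (largest-remainder rounding, ties to earlier trajectories), then within
#' each trajectory starts sit at `round(i * R / W)` for `i = 0 ... W-1`
#' over the `R` admissible starts, with duplicates after rounding removed.
#' Windows may overlap — even coverage at fine scales requires it. A seeded
#' `"random"` mode (starts sampled without replacement) is available for
#' sensitivity checks.
#'
#' @param series An [energy_series()] tibble (one or many trajectories).
#' @param tau Time scale: spacing between consecutive window points (must
#'   be an integer multiple of the sampling interval).
#' @param m Window exponent; each window has `n = 2^m` points.
#' @param max_windows Cap on the total number of windows across the set.
#' @param placement `"even"` (deterministic, default) or `"random"`.
#' @param seed Seed for `"random"` placement.
#' @return A tibble of class `window_plan` with columns `trajectory_id`,
#'   `start` (0-based frame index), `stride`, `n`, and attributes `tau`,
#'   `m`, `delta`.
#' @export
plan_windows <- function(series, tau, m = 6L, max_windows = 1000L,
                         placement = c("even", "random"), seed = 1L) {
  placement <- match.arg(placement)
  delta <- sampling_interval(series)
  s <- tau / delta
  if (abs(s - round(s)) > 1e-9) {
    stop_validation(sprintf(
      "time scale tau = %g is not an integer multiple of delta = %g.", tau, delta
    ))
  }
  s <- as.integer(round(s))
  if (s < 1L) stop_validation("tau must be at least one sampling interval.")
  if (!is.numeric(m) || m < 1L) stop_validation("`m` must give n = 2^m >= 2.")
  n <- as.integer(2^m)
  lens <- trajectory_lengths(series)
  span <- (n - 1L) * s
  n_admissible <- pmax(lens - span, 0L)
  if (all(n_admissible == 0L)) {
    stop_capacity(sprintf(
      "no trajectory is long enough for tau = %g, n = %d (span %d frames; longest trajectory %d).",
      tau, n, span + 1L, max(lens)
    ))
  }
  alloc <- allocate_proportional(n_admissible, min(max_windows, sum(n_admissible)))
  plans <- purrr::imap(alloc, function(w, id) {
    if (w == 0L) return(NULL)
    r <- n_admissible[[id]]
    starts <- if (placement == "even") {
      unique(as.integer(round((seq_len(w) - 1) * r / w)))
    } else {
      sort(withr::with_seed(seed, sample.int(r, w) - 1L))
    }
    tibble(trajectory_id = id, start = starts, stride = s, n = n)
  })
  out <- bind_rows(plans)
  structure(out, tau = tau, m = as.integer(m), delta = delta,
            class = c("window_plan", class(tibble())))
}

# Largest-remainder apportionment of `total` windows over trajectories with
# capacities `cap` (named). Deterministic: ties broken by position.
allocate_proportional <- function(cap, total) {
  quota <- total * cap / sum(cap)
  base <- pmin(floor(quota), cap)
  left <- total - sum(base)
  if (left > 0) {
    frac <- quota - floor(quota)
    frac[base >= cap] <- -1
    ord <- order(-frac, seq_along(frac))
    for (i in ord) {
      if (left == 0) break
      if (base[i] < cap[i]) {
        base[i] <- base[i] + 1
        left <- left - 1
      }
    }
  }
  stats::setNames(as.integer(base), names(cap))
}

#' Extract one window from an energy series
#'
#' Returns the two length-`n` subsequences at frames
#' `start, start + s, ..., start + (n-1) s` of the named trajectory.
#'
#' @param series An [energy_series()] tibble.
#' @param trajectory_id Trajectory to read from.
#' @param start 0-based start frame.
#' @param stride Frame stride `s = tau/delta`.
#' @param n Points per window.
#' @return A list with numeric vectors `e_p` and `e_pw`.
#' @export
extract_window <- function(series, trajectory_id, start, stride, n) {
  rows <- which(series$trajectory_id == trajectory_id)
  if (length(rows) == 0L) {
    stop_validation(sprintf("unknown trajectory '%s'.", trajectory_id))
  }
  idx <- start + stride * (seq_len(n) - 1L)
  if (start < 0L || max(idx) >= length(rows)) {
    abort(sprintf(
      "window (start %d, stride %d, n %d) exceeds trajectory '%s' of length %d.",
      start, stride, n, trajectory_id, length(rows)
    ), class = "roughscape_index_error")
  }
  sel <- rows[idx + 1L]
  list(e_p = series$e_p[sel], e_pw = series$e_pw[sel])
}
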