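#' Define one relaxation component of the synthetic energy model
#'
#' One component contributes a stationary Ornstein-Uhlenbeck (OU) mode with
#' relaxation time `theta` to both energy series: amplitude `a` (kcal/mol)
#' on the protein self energy and `b` (kcal/mol) on the protein-water
#' interaction energy, with cross-correlation `rho` between the two modes.
#' Stacking components with increasing `theta` emulates the hierarchy of
#' conformational substate dynamics whose relaxation times span
#' femtoseconds-to-nanoseconds analogues.
#'
#' @param theta Relaxation time (time units, > 0).
#' @param a Amplitude on the protein self energy (kcal/mol, >= 0).
#' @param b Amplitude on the protein-water interaction energy
#'   (kcal/mol, >= 0).
#' @param rho Cross-correlation between the two modes, in \[-1, 1\].
#'   Negative values emulate energetic compensation by the hydration shell.
#' @return A one-row tibble describing the component.
#' @export
ou_component <- function(theta, a, b, rho = 0) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0) {
    stop_validation("`theta` must be a single positive number.")
  }
  if (!is.numeric(a) || a < 0 || !is.numeric(b) || b < 0) {
    stop_validation("amplitudes `a` and `b` must be non-negative.")
  }
  if (!is.numeric(rho) || rho < -1 || rho > 1) {
    stop_validation("`rho` must lie in [-1, 1].")
  }
  tibble(theta = theta, a = as.numeric(a), b = as.numeric(b), rho = as.numeric(rho))
}

#' Specify a coupled multi-timescale synthetic energy model
#'
#' A mixture of independent OU components (see [ou_component()]) with
#' strictly increasing relaxation times. Component `k` contributes
#' `a_k * X_k(t)` to `e_p` and `b_k * (rho_k * X_k(t) +
#' sqrt(1 - rho_k^2) * Y_k(t))` to `e_pw`, where `X_k`, `Y_k` are
#' independent unit-variance stationary OU processes. The closed-form
#' stationary moments are therefore
#' `Var(e_p) = sum(a^2)`, `Var(e_pw) = sum(b^2)` and
#' `Cov(e_p, e_pw) = sum(rho * a * b)`; they are exposed through
#' [model_moments()] and serve as oracles for every downstream statistic.
#'
#' @param components A tibble of components, e.g. built by binding
#'   [ou_component()] rows; relaxation times must be strictly increasing.
#' @param mu_p,mu_w Baseline (mean) energies in kcal/mol.
#' @param delta Sampling interval (time units, > 0).
#' @param n_steps Number of frames to simulate (>= 2).
#' @param seed Integer seed; identical models reproduce identical series
#'   bit for bit.
#' @return A list of class `synthetic_model`.
#' @examples
#' m <- synthetic_model(ou_component(10, a = 1, b = 1, rho = -0.6),
#'                      n_steps = 1000, seed = 1)
#' model_moments(m)
#' @export
synthetic_model <- function(components, mu_p = 0, mu_w = 0, delta = 1,
                            n_steps, seed = 1L) {
  components <- as_tibble(components)
  needed <- c("theta", "a", "b", "rho")
  if (!all(needed %in% names(components)) || nrow(components) == 0L) {
    stop_validation("`components` must have columns theta, a, b, rho and at least one row.")
  }
  for (i in seq_len(nrow(components))) {
    ou_component(components$theta[i], components$a[i], components$b[i],
                 components$rho[i])
  }
  if (nrow(components) > 1L && any(diff(components$theta) <= 0)) {
    stop_validation("component relaxation times must be strictly increasing.")
  }
  if (!is.numeric(delta) || delta <= 0) {
    stop_validation("`delta` must be positive.")
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 2) {
    stop_size("`n_steps` must be at least 2.")
  }
  structure(
    list(
      components = components,
      mu_p = as.numeric(mu_p),
      mu_w = as.numeric(mu_w),
      delta = as.numeric(delta),
      n_steps = as.integer(n_steps),
      seed = as.integer(seed)
    ),
    class = "synthetic_model"
  )
}

#' @export
print.synthetic_model <- function(x, ...) {
  cat(sprintf(
    "<synthetic_model> %d component%s, n_steps = %d, delta = %g, seed = %d\n",
    nrow(x$components), if (nrow(x$components) == 1) "" else "s",
    x$n_steps, x$delta, x$seed
  ))
  print(x$components)
  invisible(x)
}

#' Closed-form stationary moments of a synthetic model
#'
#' @param model A [synthetic_model()].
#' @return A one-row tibble with `var_p`, `var_pw`, `cov`, `var_tot` and the
#'   implied full-process correlation `r_inf = cov / sqrt(var_p * var_pw)`
#'   (NA when either variance vanishes). `var_tot` equals
#'   `var_p + var_pw + 2 * cov` by construction.
#' @export
model_moments <- function(model) {
  cmp <- model$components
  var_p <- sum(cmp$a^2)
  var_pw <- sum(cmp$b^2)
  cv <- sum(cmp$rho * cmp$a * cmp$b)
  tibble(
    var_p = var_p,
    var_pw = var_pw,
    cov = cv,
    var_tot = var_p + var_pw + 2 * cv,
    r_inf = if (var_p > 0 && var_pw > 0) cv / sqrt(var_p * var_pw) else NA_real_
  )
}

#' Stationary variance of the total energy
#'
#' The variance decomposition identity in closed form:
#' `Var(e_tot) = sum(a^2 + b^2 + 2 * rho * a * b)` over components, equal to
#' `Var(e_p) + Var(e_pw) + 2 Cov(e_p, e_pw)`.
#'
#' @param model A [synthetic_model()].
#' @return The stationary variance of `e_p + e_pw` (kcal^2/mol^2).
#' @export
expected_total_variance <- function(model) {
  cmp <- model$components
  sum(cmp$a^2 + cmp$b^2 + 2 * cmp$rho * cmp$a * cmp$b)
}

# One stationary unit-variance OU path via the exact discrete update
# x(t+delta) = phi x(t) + sqrt(1 - phi^2) xi, phi = exp(-delta/theta),
# with x(0) from the stationary N(0, 1). Innovations are consumed in a
# fixed order so the path is reproducible bit for bit.
ou_path <- function(n_steps, phi) {
  z <- rnorm(n_steps)
  if (n_steps == 1L) return(z)
  x <- stats::filter(sqrt(1 - phi^2) * z[-1L], phi, method = "recursive",
                     init = z[1L])
  c(z[1L], as.numeric(x))
}

#' Simulate coupled energy series from a synthetic model
#'
#' Draws, for each component, two independent stationary unit-variance OU
#' paths with the exact discretisation (no burn-in: the initial state is
#' stationary, so closed-form moments hold from the first frame) and mixes
#' them into `e_p` and `e_pw` as described in [synthetic_model()].
#'
#' @param model A [synthetic_model()].
#' @param trajectory_id Identifier for the resulting series.
#' @param seed Optional override of `model$seed`.
#' @return An [energy_series()] tibble of `model$n_steps` frames.
#' @export
simulate_series <- function(model, trajectory_id = "synthetic1", seed = NULL) {
  if (!inherits(model, "synthetic_model")) {
    stop_validation("`model` must be a `synthetic_model`.")
  }
  seed <- if (is.null(seed)) model$seed else as.integer(seed)
  cmp <- model$components
  n <- model$n_steps
  withr::with_seed(seed, {
    e_p <- rep(model$mu_p, n)
    e_pw <- rep(model$mu_w, n)
    for (k in seq_len(nrow(cmp))) {
      phi <- exp(-model$delta / cmp$theta[k])
      x <- ou_path(n, phi)
      y <- ou_path(n, phi)
      e_p <- e_p + cmp$a[k] * x
      e_pw <- e_pw + cmp$b[k] * (cmp$rho[k] * x + sqrt(1 - cmp$rho[k]^2) * y)
    }
    energy_series(e_p, e_pw, delta = model$delta, trajectory_id = trajectory_id)
  })
}

#' Simulate a set of independent replicate trajectories
#'
#' @param model A [synthetic_model()].
#' @param n_traj Number of replicate trajectories.
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @return An `energy_series` tibble with `n_traj` trajectories
#'   (`synthetic1 ... synthetic<n>`).
#' @export
simulate_trajectory_set <- function(model, n_traj, seed = model$seed) {
  parts <- lapply(seq_len(n_traj), function(i) {
    simulate_series(model, trajectory_id = sprintf("synthetic%d", i),
                    seed = seed + i - 1L)
  })
  trajectory_set(parts)
}

#' Expected windowed variance of a stationary OU mode
#'
#' Exact expectation of the population-form sample variance of `n` points
#' spaced `stride` apart on a stationary OU process with variance `v` and
#' lag correlation `exp(-h / theta)`:
#' `E[s^2] = v * (1 - (1/n^2) * sum_{i,j} exp(-|i - j| * stride / theta))`.
#' The double sum is telescoped to a single sum over lags. This is the
#' oracle against which windowed roughness estimates are checked: it
#' accounts for the autocorrelation that makes windowed variances smaller
#' than the full stationary variance when the window span is short compared
#' with `theta`.
#'
#' @param theta Relaxation time (> 0).
#' @param v Stationary variance of the mode (energy^2).
#' @param n Points per window (>= 2).
#' @param stride Spacing between window points (time units, > 0); the time
#'   scale tau of the analysis.
#' @return Expected population sample variance (energy^2).
#' @examples
#' expected_window_variance(theta = 100, v = 1, n = 64, stride = 10)
#' @export
expected_window_variance <- function(theta, v, n, stride) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) stop_size("`n` must be at least 2.")
  if (theta <= 0 || stride <= 0) stop_validation("`theta` and `stride` must be positive.")
  n <- as.integer(n)
  h <- seq_len(n - 1L)
  s <- n + 2 * sum((n - h) * exp(-h * stride / theta))
  v * (1 - s / n^2)
}
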