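# Independent, deliberately naive reference implementations used as oracles.
# They share no code with the package: plain loops and explicit enumeration.

# Population variance by explicit loop accumulation.
loop_sigma <- function(x) {
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - mu)^2
  sqrt(acc / length(x))
}

# Expected windowed OU variance by brute-force double summation.
bf_expected_window_variance <- function(theta, v, n, stride) {
  acc <- 0
  for (i in 1:n) {
    for (j in 1:n) acc <- acc + exp(-abs(i - j) * stride / theta)
  }
  v * (1 - acc / n^2)
}

# Loop-based window extraction.
loop_extract <- function(e_p, e_pw, start, stride, n) {
  xp <- numeric(n)
  xw <- numeric(n)
  for (i in 1:n) {
    pos <- start + (i - 1) * stride + 1
    xp[i] <- e_p[pos]
    xw[i] <- e_pw[pos]
  }
  list(e_p = xp, e_pw = xw)
}

# Brute-force window planner: enumerate admissible starts by testing every
# candidate, apportion by explicit largest-remainder, place by rounding.
oracle_plan <- function(lengths, stride, n, max_windows) {
  admissible <- lapply(lengths, function(L) {
    ok <- integer(0)
    for (st in 0:(L - 1)) {
      if (st + (n - 1) * stride <= L - 1) ok <- c(ok, st)
    }
    ok
  })
  caps <- vapply(admissible, length, integer(1))
  if (sum(caps) == 0) return(NULL)
  total <- min(max_windows, sum(caps))
  quota <- total * caps / sum(caps)
  w <- pmin(floor(quota), caps)
  remainder <- total - sum(w)
  frac <- quota - floor(quota)
  frac[w >= caps] <- -1
  ord <- order(-frac, seq_along(frac))
  for (i in ord) {
    if (remainder == 0) break
    if (w[i] < caps[i]) {
      w[i] <- w[i] + 1
      remainder <- remainder - 1
    }
  }
  out <- list()
  for (t in seq_along(lengths)) {
    if (w[t] == 0) next
    starts <- integer(0)
    for (i in 0:(w[t] - 1)) starts <- c(starts, as.integer(round(i * caps[t] / w[t])))
    starts <- unique(starts)
    out[[length(out) + 1]] <- data.frame(
      trajectory_id = names(lengths)[t], start = starts,
      stride = as.integer(stride), n = as.integer(n),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Plain data.frame with only names/class/row.names attributes, for
# attribute-insensitive frame comparisons.
strip_df <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "class", "row.names")]
  rownames(d) <- NULL
  d
}

# Small random trajectory set on delta = 1.
random_trajectory_set <- function(n_traj, len_range = c(50, 400)) {
  parts <- lapply(seq_len(n_traj), function(i) {
    L <- sample(len_range[1]:len_range[2], 1)
    energy_series(rnorm(L), rnorm(L), delta = 1,
                  trajectory_id = sprintf("t%02d", i))
  })
  trajectory_set(parts)
}

# Single-component OU model shorthand.
one_ou_model <- function(theta, a, b, rho, n_steps, seed, delta = 1) {
  synthetic_model(ou_component(theta, a, b, rho),
                  delta = delta, n_steps = n_steps, seed = seed)
}
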