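#' Pearson correlation of one window (population moments)
#'
#' The product-moment coefficient computed from population-form (divide by
#' n) moments over the window points. When either window has zero variance
#' the coefficient is undefined and `NA` is returned — never a number.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return The correlation in \[-1, 1\], or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop_size(sprintf("windows differ in length (%d vs %d).", length(x), length(y)))
  }
  if (length(x) < 2L) stop_size("a window needs at least 2 points.")
  cx <- x - mean(x)
  cy <- y - mean(y)
  vx <- mean(cx^2)
  vy <- mean(cy^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  r <- mean(cx * cy) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Population standard deviation of a window
#'
#' Energy-landscape roughness of one window in its common form
#' `sqrt(<E^2> - <E>^2)`, i.e. divide-by-n moments, computed by the
#' numerically stable centred two-pass sum and clipped at zero against
#' negative round-off. With population moments the sample decomposition
#' Var(e_tot) = Var(e_p) + Var(e_pw) + 2 Cov holds as an exact identity.
#'
#' @param x Numeric vector of at least 2 energies.
#' @return The population standard deviation (same units as `x`).
#' @export
sigma_pop <- function(x) {
  if (length(x) < 2L) stop_size("a window needs at least 2 points.")
  c_ <- x - mean(x)
  sqrt(max(0, mean(c_^2)))
}

quadrant_levels <- c("I", "II", "III", "IV")

# Quadrant of the (delta_sigma, r) plane. Ties delta_sigma == 0 count as
# roughening (with delta_sigma > 0); undefined r gives NA.
classify_quadrant <- function(delta_sigma, r) {
  q <- rep(NA_character_, length(r))
  def <- !is.na(r)
  q[def & delta_sigma >= 0 & r > 0] <- "I"
  q[def & delta_sigma >= 0 & r <= 0] <- "IV"
  q[def & delta_sigma < 0 & r < 0] <- "III"
  q[def & delta_sigma < 0 & r >= 0] <- "II"
  factor(q, levels = quadrant_levels)
}

#' Per-window correlation and roughness statistics
#'
#' For each planned window this computes the Pearson correlation `r`
#' between the two energy components, population standard deviations
#' `sigma_p`, `sigma_pw` and `sigma_tot` (of `e_p + e_pw`, formed
#' elementwise), `delta_sigma = sigma_tot - sigma_p`, and the quadrant of
#' the `(delta_sigma, r)` plane:
#'
#' * I  — `delta_sigma >= 0`, `r > 0`: water roughens, energies reinforce;
#' * IV — `delta_sigma >= 0`, `r <= 0`: water roughens despite (or without)
#'   anticorrelation — the slaving-like case;
#' * III — `delta_sigma < 0`, `r < 0`: water smooths the landscape;
#' * II — `delta_sigma < 0`, `r >= 0`: algebraically impossible whenever
#'   `sigma_pw > 0`. If round-off ever produces it the run fails loudly.
#'
#' The variance decomposition identity
#' `sigma_tot^2 = sigma_p^2 + sigma_pw^2 + 2 r sigma_p sigma_pw`
#' holds for every window with defined `r` to within `1e-9` relative.
#'
#' @param series An [energy_series()] tibble.
#' @param plan A window plan from [plan_windows()].
#' @return A tibble with one row per window: the plan columns plus `r`,
#'   `sigma_p`, `sigma_pw`, `sigma_tot`, `delta_sigma`, `quadrant`.
#' @export
window_stats <- function(series, plan) {
  if (nrow(plan) == 0L) stop_size("empty window plan.")
  groups <- split(seq_len(nrow(plan)), plan$trajectory_id)
  res <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows_plan <- groups[[g]]
    id <- plan$trajectory_id[rows_plan[1L]]
    traj_rows <- which(series$trajectory_id == id)
    if (length(traj_rows) == 0L) {
      stop_validation(sprintf("window plan names unknown trajectory '%s'.", id))
    }
    starts <- plan$start[rows_plan]
    s <- plan$stride[rows_plan[1L]]
    n <- plan$n[rows_plan[1L]]
    if (any(starts < 0L) || max(starts) + (n - 1L) * s >= length(traj_rows)) {
      abort(sprintf("window plan exceeds trajectory '%s'.", id),
            class = "roughscape_index_error")
    }
    idx <- outer(starts, s * (seq_len(n) - 1L), "+") + 1L
    mp <- matrix(series$e_p[traj_rows][idx], nrow = length(starts))
    mw <- matrix(series$e_pw[traj_rows][idx], nrow = length(starts))
    res[[g]] <- cbind(as_tibble(plan)[rows_plan, ], pair_moments(mp, mw))
  }
  out <- bind_rows(res)[order(unlist(groups, use.names = FALSE)), ]
  bad <- !is.na(out$quadrant) & out$quadrant == "II" & out$sigma_pw > 0
  if (any(bad)) {
    abort(sprintf(
      "%d window(s) fell in quadrant II (delta_sigma < 0 with r >= 0 and sigma_pw > 0): algebraically impossible; inspect the input for numerical corruption.",
      sum(bad)
    ), class = "roughscape_quadrant_error")
  }
  as_tibble(out)
}

# Row-wise population moments of paired window matrices (windows x points).
pair_moments <- function(mp, mw) {
  cp <- mp - rowMeans(mp)
  cw <- mw - rowMeans(mw)
  vp <- rowMeans(cp^2)
  vw <- rowMeans(cw^2)
  cv <- rowMeans(cp * cw)
  mt <- mp + mw
  ct <- mt - rowMeans(mt)
  vt <- rowMeans(ct^2)
  r <- ifelse(vp > 0 & vw > 0, cv / sqrt(vp * vw), NA_real_)
  r <- pmin(1, pmax(-1, r))
  sigma_p <- sqrt(pmax(0, vp))
  sigma_tot <- sqrt(pmax(0, vt))
  ds <- sigma_tot - sigma_p
  tibble(
    r = r,
    sigma_p = sigma_p,
    sigma_pw = sqrt(pmax(0, vw)),
    sigma_tot = sigma_tot,
    delta_sigma = ds,
    quadrant = classify_quadrant(ds, r)
  )
}

#' Statistics of a single window pair
#'
#' Convenience scalar form of [window_stats()] for two raw windows.
#'
#' @param e_p,e_pw Numeric vectors of equal length (>= 2).
#' @return A one-row tibble with `r`, `sigma_p`, `sigma_pw`, `sigma_tot`,
#'   `delta_sigma`, `quadrant`.
#' @export
window_pair_stats <- function(e_p, e_pw) {
  if (length(e_p) != length(e_pw)) {
    stop_size(sprintf("windows differ in length (%d vs %d).", length(e_p), length(e_pw)))
  }
  if (length(e_p) < 2L) stop_size("a window needs at least 2 points.")
  out <- pair_moments(matrix(e_p, nrow = 1L), matrix(e_pw, nrow = 1L))
  if (!is.na(out$quadrant) && out$quadrant == "II" && out$sigma_pw > 0) {
    abort("window fell in quadrant II (algebraically impossible with sigma_pw > 0).",
          class = "roughscape_quadrant_error")
  }
  out
}

# Equal-width histogram over [min, max]; the last bin includes its right
# edge. Degenerate zero-range input puts everything in the first bin.
hist_counts <- function(x, bins) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) {
    return(list(breaks = numeric(0), counts = integer(0)))
  }
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) hi <- lo + 1
  breaks <- seq(lo, hi, length.out = bins + 1L)
  width <- (hi - lo) / bins
  idx <- pmin(bins, floor((x - lo) / width) + 1L)
  list(breaks = breaks, counts = tabulate(idx, nbins = bins))
}

#' Aggregate window statistics at one time scale
#'
#' Pools all windows of one scale into the scale-level summary: mean
#' correlation over defined-`r` windows; mean roughness over all windows
#' (and, since windows with one constant component are excluded from `r`
#' but not from roughness, also over defined-`r` windows only); the
#' roughening probability `p_rough = P(sigma_tot >= sigma_p)` and its
#' complement `p_smooth` (ties count as roughening); quadrant occupancy
#' percentages over defined-`r` windows; and equal-width histograms of
#' `r` and the three roughness measures.
#'
#' @param stats A window-statistics tibble from [window_stats()].
#' @param tau Time scale of these windows.
#' @param m Window exponent used.
#' @param hist_bins Number of equal-width histogram bins per statistic.
#' @return A one-row tibble of class `scale_summary`; histograms live in
#'   the list-column `histograms` (named list of `breaks`/`counts` pairs).
#' @export
summarize_scale <- function(stats, tau, m, hist_bins = 50L) {
  if (nrow(stats) == 0L) stop_size("no windows to summarise.")
  def <- !is.na(stats$r)
  smooth <- stats$sigma_tot < stats$sigma_p
  qtab <- table(factor(stats$quadrant[def], levels = quadrant_levels))
  ndef <- sum(def)
  pct <- if (ndef > 0) 100 * as.numeric(qtab) / ndef else rep(NA_real_, 4L)
  tibble(
    tau = tau,
    m = as.integer(m),
    window_count = nrow(stats),
    defined_r_count = ndef,
    mean_r = if (ndef > 0) mean(stats$r[def]) else NA_real_,
    mean_sigma_p = mean(stats$sigma_p),
    mean_sigma_pw = mean(stats$sigma_pw),
    mean_sigma_tot = mean(stats$sigma_tot),
    mean_sigma_p_defined = if (ndef > 0) mean(stats$sigma_p[def]) else NA_real_,
    mean_sigma_pw_defined = if (ndef > 0) mean(stats$sigma_pw[def]) else NA_real_,
    mean_sigma_tot_defined = if (ndef > 0) mean(stats$sigma_tot[def]) else NA_real_,
    p_rough = mean(!smooth),
    p_smooth = mean(smooth),
    pct_I = pct[1L],
    pct_III = pct[3L],
    pct_IV = pct[4L],
    histograms = list(list(
      r = hist_counts(stats$r[def], hist_bins),
      sigma_p = hist_counts(stats$sigma_p, hist_bins),
      sigma_pw = hist_counts(stats$sigma_pw, hist_bins),
      sigma_tot = hist_counts(stats$sigma_tot, hist_bins)
    ))
  )
}
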