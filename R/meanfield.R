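#' Empirical gain function of the GIF neuron
#'
#' Estimates the rate-current relation \eqn{r = g(\langle I \rangle,
#' \sigma_I)} by simulating groups of independent, initially non-adapted
#' neurons driven by a current with mean \eqn{\langle I \rangle} and
#' fluctuations obtained by filtering white noise with the exponential PSC
#' kernel, scaled so the stationary standard deviation of the current equals
#' \eqn{\sigma_I}. Rates are counted in successive windows of `window_ms`:
#' the first window gives the non-adapted gain, later windows the
#' progressively adapted gain.
#'
#' @param params A [gif_params()] object.
#' @param currents Strictly increasing grid of mean currents (pA).
#' @param sigma_I Stationary current fluctuation (pA), non-negative.
#' @param tau_syn PSC time constant used to filter the noise (ms).
#' @param n_neurons Independent neurons per current and trial.
#' @param n_trials Trial repetitions (fresh neurons each).
#' @param n_windows Number of successive windows to record.
#' @param window_ms Window length (ms).
#' @param dt Integration step (ms); must not exceed `window_ms`.
#' @param seed Optional integer seed.
#' @return A `gain_curve`: rate estimates (Hz) and standard errors per
#'   current and window.
#' @export
estimate_gain <- function(params, currents, sigma_I = 20, tau_syn = 16.3,
                          n_neurons = 50, n_trials = 10, n_windows = 5,
                          window_ms = 10, dt = 0.1, seed = NULL) {
  stopifnot(inherits(params, "gif_params"))
  if (is.unsorted(currents, strictly = TRUE))
    stop("'currents' must be strictly increasing")
  if (sigma_I < 0) stop("'sigma_I' must be non-negative")
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  if (window_ms < dt) stop("window must be at least one step")
  if (!is.null(seed)) set.seed(seed)
  n_tot <- n_neurons * n_trials
  window_steps <- round(window_ms / dt)
  rates <- se <- matrix(0, length(currents), n_windows,
                        dimnames = list(NULL, paste0("window", 1:n_windows)))
  for (ci in seq_along(currents)) {
    counts <- sim_gain_cpp(
      n_neurons = n_tot, n_steps = window_steps * n_windows, dt = dt,
      Cm = params$C, gL = params$g_L, EL = params$E_L,
      ref_steps = as.integer(round(params$t_ref / dt)),
      Vreset = params$V_reset, lam0 = params$lambda_0,
      dV = params$delta_V, VTstar = params$V_T_star,
      eta_amp = vapply(params$eta, `[[`, 0, "amplitude"),
      eta_tau = vapply(params$eta, `[[`, 0, "time_constant"),
      gam_amp = vapply(params$gamma, `[[`, 0, "amplitude"),
      gam_tau = vapply(params$gamma, `[[`, 0, "time_constant"),
      Imean = currents[ci], sigmaI = sigma_I, tau_alpha = tau_syn,
      window_steps = window_steps)
    r <- counts / (window_ms / 1000)       # Hz per neuron and window
    rates[ci, ] <- colMeans(r)
    se[ci, ] <- apply(r, 2, stats::sd) / sqrt(n_tot)
  }
  structure(list(currents = currents, sigma_I = sigma_I, tau_syn = tau_syn,
                 window_ms = window_ms, rates = rates, se = se,
                 n_neurons = n_tot),
            class = "gain_curve")
}

#' @export
print.gain_curve <- function(x, ...) {
  cat(sprintf(
    "empirical gain curve: %d currents in [%.4g, %.4g] pA, sigma_I = %.4g pA\n",
    length(x$currents), min(x$currents), max(x$currents), x$sigma_I))
  cat(sprintf("  %d neurons, %d windows of %g ms; initial-window rates %.3g-%.3g Hz\n",
              x$n_neurons, ncol(x$rates), x$window_ms,
              min(x$rates[, 1]), max(x$rates[, 1])))
  invisible(x)
}

#' Network feedback line
#'
#' Mean-field relation between the population rate and the mean synaptic
#' current it generates: \eqn{\langle I \rangle = N p q \bar w r} with
#' \eqn{q = \int_0^\infty \alpha(t) dt = \tau_{syn}} for a unit-amplitude
#' exponential PSC. The feedback coefficient is \eqn{C_{fb} = N p q \bar w}
#' (pA ms); inverting gives the feedback line \eqn{r = \langle I \rangle /
#' C_{fb}} through the origin.
#'
#' @param N Population size.
#' @param p Connection probability within the population.
#' @param tau_syn PSC time constant (ms).
#' @param w_bar Mean synaptic weight (pA, PSC convention).
#' @return A `feedback_line` with `C_fb` (pA ms), `q`, and `slope_hz_per_pA`
#'   (= 1000/C_fb). A zero `w_bar` is flagged degenerate.
#' @export
network_feedback <- function(N, p, tau_syn, w_bar) {
  stopifnot(N > 0, p > 0, tau_syn > 0)
  q <- tau_syn
  C_fb <- N * p * q * w_bar
  structure(list(N = N, p = p, q = q, w_bar = w_bar, C_fb = C_fb,
                 slope_hz_per_pA = if (C_fb != 0) 1000 / C_fb else Inf,
                 degenerate = w_bar == 0),
            class = "feedback_line")
}

#' @export
print.feedback_line <- function(x, ...) {
  cat(sprintf("feedback line: N = %g, p = %.3g, q = %.4g pA ms/pA, w_bar = %.4g pA\n",
              x$N, x$p, x$q, x$w_bar))
  cat(sprintf("  C_fb = %.6g pA ms (slope %.4g Hz/pA)%s\n", x$C_fb,
              x$slope_hz_per_pA, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fixed points of gain curve and feedback line
#'
#' Intersects the (monotone-interpolated) non-adapted gain curve with the
#' feedback line \eqn{r = \langle I \rangle / C_{fb}}. The gain samples are
#' made monotone by isotonic regression and interpolated with a monotone
#' piecewise-cubic spline, which avoids spurious intersections; sign changes
#' of the difference are bracketed on a fine grid and refined by bisection.
#' One intersection is the low point; three intersections are labeled low,
#' switch (unstable) and high.
#'
#' @param gain A `gain_curve` (or a list with `currents` and a rate vector
#'   `rates`), rates in Hz.
#' @param line A `feedback_line`.
#' @param window Which gain window to use (1 = non-adapted).
#' @param n_grid Bracketing grid resolution.
#' @return A `fixed_point_set`: data frame of `current` (pA), `rate` (Hz)
#'   and `label`, plus `regime` ("one_point" or "three_point").
#' @export
find_fixed_points <- function(gain, line, window = 1, n_grid = 2000) {
  stopifnot(inherits(line, "feedback_line"))
  if (line$degenerate) stop("degenerate feedback line (w_bar = 0)")
  x <- gain$currents
  y <- if (is.matrix(gain$rates)) gain$rates[, window] else gain$rates
  iso <- stats::isoreg(x, y)
  g <- stats::splinefun(x, iso$yf, method = "monoH.FC")
  f <- function(I) g(I) - 1000 * I / line$C_fb
  grid <- seq(min(x), max(x), length.out = n_grid)
  fg <- f(grid)
  roots <- numeric(0)
  if (abs(fg[1]) < 1e-12) roots <- grid[1]
  sgn <- sign(fg)
  flips <- which(sgn[-1] * sgn[-n_grid] < 0)
  for (k in flips)
    roots <- c(roots, stats::uniroot(f, c(grid[k], grid[k + 1]),
                                     tol = 1e-10)$root)
  zero_runs <- which(sgn == 0)
  roots <- sort(unique(c(roots, grid[zero_runs])))
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > (max(x) - min(x)) * 1e-6)]
  # a pair of crossings closer than one knot spacing brackets a shallow
  # excursion of the interpolant around the line (a near-tangency): no net
  # sign change, so the pair cancels
  knot <- max(diff(x))
  while (length(roots) > 3) {
    gaps <- diff(roots)
    k <- which.min(gaps)
    if (gaps[k] >= knot) break
    roots <- roots[-c(k, k + 1)]
  }
  if (length(roots) > 3)
    stop(sprintf("found %d intersections; non-physical gain curve or interpolation artifact",
                 length(roots)))
  labels <- switch(as.character(length(roots)),
                   "0" = character(0), "1" = "low", "2" = c("low", "switch"),
                   "3" = c("low", "switch", "high"))
  structure(list(points = data.frame(current = roots, rate = g(roots),
                                     label = labels),
                 regime = if (length(roots) >= 3) "three_point" else "one_point",
                 C_fb = line$C_fb),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf("fixed points (C_fb = %.5g pA ms): %s regime\n", x$C_fb, x$regime))
  if (nrow(x$points))
    print(transform(x$points, current = signif(current, 5),
                    rate = signif(rate, 5)), row.names = FALSE)
  invisible(x)
}

#' Sweep the feedback coefficient
#'
#' Classifies the fixed-point regime for a range of `C_fb` values against a
#' fixed gain curve, tracking the high-point rate and switch-point current
#' where they exist.
#'
#' @param gain A `gain_curve`.
#' @param C_fb_values Feedback coefficients (pA ms) to test.
#' @param window Gain window (1 = non-adapted).
#' @return Data frame with `C_fb`, `regime`, `r_high` (Hz), `I_switch` (pA).
#' @export
feedback_sweep <- function(gain, C_fb_values, window = 1) {
  rows <- lapply(C_fb_values, function(cfb) {
    line <- network_feedback(1, 1, 1, cfb)   # C_fb = cfb directly
    fp <- find_fixed_points(gain, line, window = window)
    pts <- fp$points
    data.frame(C_fb = cfb, regime = fp$regime,
               r_high = if ("high" %in% pts$label)
                 pts$rate[pts$label == "high"] else NA_real_,
               I_switch = if ("switch" %in% pts$label)
                 pts$current[pts$label == "switch"] else NA_real_)
  })
  do.call(rbind, rows)
}

#' Export a gain curve to CSV
#'
#' @param gain A `gain_curve`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gain_curve <- function(gain, file) {
  df <- data.frame(current_pA = gain$currents, gain$rates,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
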