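#' Gaussian smoothing of trace matrices
#'
#' FFT-based convolution of each column with a Gaussian kernel (standard
#' deviation `sd_samples`, support cut at four standard deviations); edges
#' are padded by replicating the first/last sample.
#'
#' @param X Numeric matrix, one trace per column (or a vector).
#' @param sd_samples Kernel standard deviation in samples.
#' @return Smoothed matrix of the same shape.
#' @keywords internal
gaussian_smooth <- function(X, sd_samples) {
  X <- as.matrix(X)
  if (sd_samples <= 0) return(X)
  hw <- ceiling(4 * sd_samples)
  kern <- stats::dnorm(seq(-hw, hw), sd = sd_samples)
  kern <- kern / sum(kern)
  nr <- nrow(X)
  pad <- rbind(X[rep(1, hw), , drop = FALSE], X,
               X[rep(nr, hw), , drop = FALSE])
  np <- nrow(pad) + length(kern) - 1
  kf <- stats::fft(c(kern, numeric(np - length(kern))))
  pf <- stats::mvfft(rbind(pad, matrix(0, np - nrow(pad), ncol(X))))
  out <- Re(stats::mvfft(pf * kf, inverse = TRUE)) / np
  out[(2 * hw + 1):(2 * hw + nr), , drop = FALSE]
}

#' Detect up-states in a membrane-potential trace
#'
#' The trace is smoothed with a Gaussian kernel (width `smooth_width_ms`,
#' interpreted as the kernel standard deviation) and thresholded
#' `threshold_mV` above the neuron's quiescent potential; contiguous
#' super-threshold runs are up-states, with the down-to-up transition at the
#' run start and the up-to-down transition at the run end.
#'
#' The reference level is the resting potential `E_L` when
#' `baseline = "resting"`. With the default `baseline = "auto"` the
#' quiescent (down-state) potential is estimated from the trace itself as
#' the 0.1 quantile of the smoothed trace, floored at `E_L`. The two
#' coincide for neurons without tonic drive; under steady background input
#' (e.g. the assembly noise channels, whose mean depolarizes their targets
#' by more than 10 mV) the down-state potential sits well above `E_L`, and
#' a threshold referenced to `E_L` would classify such neurons as
#' permanently "up".
#'
#' @param trace Membrane potential (mV) at uniform sampling.
#' @param E_L Resting potential of the neuron (mV).
#' @param dt_ms Sampling interval of `trace` (ms).
#' @param threshold_mV Detection threshold above the baseline (mV).
#' @param smooth_width_ms Gaussian kernel standard deviation (ms).
#' @param t0 Time of the first sample (ms), used for reported times.
#' @param drop_censored Drop up-states that touch the ends of the trace
#'   (their durations are censored).
#' @param baseline "auto" (down-state estimate, floored at `E_L`) or
#'   "resting" (`E_L` itself).
#' @return A data frame (`start`, `end`, `duration`, all ms) of class
#'   `updown_segmentation`, with the transition times, threshold and
#'   smoothing width as attributes.
#' @export
detect_up_states <- function(trace, E_L, dt_ms = 1, threshold_mV = 10,
                             smooth_width_ms = 20, t0 = 0,
                             drop_censored = TRUE,
                             baseline = c("auto", "resting")) {
  baseline <- match.arg(baseline)
  if (all(!is.finite(trace))) stop("trace contains no finite samples")
  sm <- drop(gaussian_smooth(trace, smooth_width_ms / dt_ms))
  base <- if (baseline == "resting") E_L
          else max(E_L, unname(stats::quantile(sm, 0.1)))
  above <- sm >= base + threshold_mV
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (drop_censored)
    keep <- keep & starts > 1 & ends < length(above)
  up <- data.frame(start = t0 + (starts[keep] - 1) * dt_ms,
                   end = t0 + ends[keep] * dt_ms)
  up$duration <- up$end - up$start
  structure(up, class = c("updown_segmentation", "data.frame"),
            transitions_up = up$start, transitions_down = up$end,
            threshold_mV = threshold_mV, smooth_width_ms = smooth_width_ms,
            E_L = E_L, baseline_mV = base,
            t_range = c(t0, t0 + length(trace) * dt_ms))
}

#' Segment all recorded neurons of a simulation
#'
#' Applies [detect_up_states()] to each neuron's recorded voltage trace,
#' using that neuron's own resting potential, over the analysis window
#' (default: everything after a 1 s burn-in).
#'
#' @param sim A `sim_result`.
#' @param neurons Indices of neurons to segment (default all).
#' @param from,to Analysis window (ms).
#' @param ... Passed to [detect_up_states()].
#' @return Named list of segmentations, one per requested neuron.
#' @export
segment_result <- function(sim, neurons = seq_len(nrow(sim$V)), from = 1000,
                           to = sim$duration, ...) {
  stopifnot(inherits(sim, "sim_result"))
  k0 <- floor(from / sim$record_dt) + 1
  k1 <- min(ncol(sim$V), floor(to / sim$record_dt))
  segs <- lapply(neurons, function(i)
    detect_up_states(sim$V[i, k0:k1], E_L = sim$E_L[i],
                     dt_ms = sim$record_dt, t0 = (k0 - 1) * sim$record_dt,
                     ...))
  names(segs) <- as.character(neurons)
  segs
}

#' Down-state durations implied by a segmentation
#'
#' Gaps between consecutive up-states of one neuron.
#'
#' @param seg An `updown_segmentation`.
#' @return Numeric vector of down-state durations (ms); empty with fewer
#'   than two up-states.
#' @export
down_state_durations <- function(seg) {
  if (nrow(seg) < 2) return(numeric(0))
  seg$start[-1] - seg$end[-nrow(seg)]
}

#' Duration statistics and coefficient of variation
#'
#' CV = std/mean with the population (1/n) standard deviation, over a set of
#' durations pooled from one or several segmentations.
#'
#' @param x Numeric durations (ms), or an `updown_segmentation`, or a list
#'   of them (durations pooled).
#' @return List with `mean`, `sd`, `cv` and `n`.
#' @export
duration_cv <- function(x) {
  if (inherits(x, "updown_segmentation")) x <- x$duration
  if (is.list(x)) x <- unlist(lapply(x, function(s)
    if (inherits(s, "updown_segmentation")) s$duration else s))
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least two durations for a CV")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  list(mean = m, sd = s, cv = s / m, n = length(x))
}

#' Per-neuron up-state duration CVs averaged over a neuron set
#'
#' Computes the CV of up-state durations separately for each neuron (needing
#' at least `min_states` up-states) and averages; the pooled-duration CV is
#' also returned.
#'
#' @param segs List of `updown_segmentation`s.
#' @param min_states Minimum up-state count per neuron.
#' @return List with `mean_cv` (average of per-neuron CVs), `per_neuron`,
#'   `pooled_cv` and `n_neurons`.
#' @export
mean_duration_cv <- function(segs, min_states = 2) {
  per <- vapply(segs, function(s) {
    if (nrow(s) < min_states) return(NA_real_)
    duration_cv(s$duration)$cv
  }, 0)
  pooled <- unlist(lapply(segs, function(s) s$duration))
  list(mean_cv = mean(per, na.rm = TRUE), per_neuron = per,
       pooled_cv = if (length(pooled) >= 2) duration_cv(pooled)$cv else NA_real_,
       n_neurons = sum(!is.na(per)))
}

bin_events <- function(times_list, bin_ms, t_range) {
  breaks <- seq(t_range[1], t_range[2], by = bin_ms)
  if (breaks[length(breaks)] < t_range[2])
    breaks <- c(breaks, breaks[length(breaks)] + bin_ms)
  vapply(times_list, function(tt) {
    tt <- tt[tt >= t_range[1] & tt < breaks[length(breaks)]]
    tabulate(findInterval(tt, breaks), nbins = length(breaks) - 1)
  }, numeric(length(breaks) - 1))
}

pair_summary <- function(M, labels, skip_zero_var = TRUE) {
  keep <- apply(M, 2, stats::sd) > 0
  n_skipped <- sum(!keep)
  Mk <- M[, keep, drop = FALSE]
  lk <- labels[keep]
  cc <- stats::cor(Mk)
  ut <- upper.tri(cc)
  overall <- mean(cc[ut])
  lev <- unique(labels)
  class_means <- vapply(lev, function(g) {
    idx <- which(lk == g)
    if (length(idx) < 2) return(NA_real_)
    sub <- cc[idx, idx]
    mean(sub[upper.tri(sub)])
  }, 0)
  class_pairs <- vapply(lev, function(g) {
    k <- sum(lk == g); k * (k - 1) / 2
  }, 0)
  list(overall_mean = overall, n_pairs = sum(ut & TRUE),
       class_mean = stats::setNames(class_means, lev),
       class_pairs = stats::setNames(class_pairs, lev),
       n_skipped = n_skipped, cor_matrix = cc, labels = lk)
}

#' Pairwise Pearson correlation of up/down transition times
#'
#' Each neuron's transition times (down-to-up or up-to-down) are binarized
#' into `bin_ms` bins (two transitions are coincident if they fall in the
#' same bin); Pearson correlations are computed for every pair of neurons
#' with at least one transition. Neurons with a zero-variance indicator are
#' skipped and counted.
#'
#' @param segs List of `updown_segmentation`s on a common time base.
#' @param direction "up" (down-to-up transitions) or "down".
#' @param bin_ms Bin width (ms).
#' @param labels Optional per-neuron class labels for class-wise means.
#' @return A `correlation_summary` list: `overall_mean`, per-class means and
#'   pair counts, skipped-neuron count, and the correlation matrix.
#' @export
transition_correlation <- function(segs, direction = c("up", "down"),
                                   bin_ms = 20, labels = NULL) {
  direction <- match.arg(direction)
  t_range <- attr(segs[[1]], "t_range")
  times <- lapply(segs, function(s)
    attr(s, if (direction == "up") "transitions_up" else "transitions_down"))
  M <- bin_events(times, bin_ms, t_range)
  M[M > 1] <- 1
  if (is.null(labels)) labels <- rep("all", length(segs))
  out <- pair_summary(M, as.character(labels))
  out$bin_ms <- bin_ms
  out$signal <- paste0("transitions_", direction)
  class(out) <- "correlation_summary"
  out
}

#' Pairwise Pearson correlations of spike trains or subthreshold voltage
#'
#' Spike trains are binned into `bin_ms` counts; subthreshold voltages have
#' spike epochs (spike time to end of the refractory period) excised by
#' linear interpolation and are then averaged per bin. Pairs involving a
#' zero-variance signal (e.g. silent neurons) are skipped and counted.
#'
#' @param sim A `sim_result`.
#' @param kind "spikes" or "subthreshold".
#' @param bin_ms Bin width (ms).
#' @param neurons Indices of neurons to include (default all).
#' @param from,to Analysis window (ms), defaulting to post-burn-in.
#' @param labels Optional labels (default: the simulation's group labels).
#' @return A `correlation_summary` (see [transition_correlation()]).
#' @export
pairwise_pearson <- function(sim, kind = c("spikes", "subthreshold"),
                             bin_ms = 10, neurons = seq_along(sim$spikes),
                             from = 1000, to = sim$duration, labels = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  kind <- match.arg(kind)
  if (is.null(labels)) labels <- as.character(sim$groups)[neurons]
  if (kind == "spikes") {
    M <- bin_events(sim$spikes[neurons], bin_ms, c(from, to))
  } else {
    k0 <- floor(from / sim$record_dt) + 1
    k1 <- min(ncol(sim$V), floor(to / sim$record_dt))
    tm <- (seq(k0, k1) - 1) * sim$record_dt
    per_bin <- max(1L, round(bin_ms / sim$record_dt))
    n_bins <- floor(length(tm) / per_bin)
    M <- vapply(neurons, function(i) {
      v <- remove_spike_epochs(sim$V[i, k0:k1], sim$spikes[[i]],
                               sim$t_ref[i], sim$record_dt,
                               t0 = (k0 - 1) * sim$record_dt)
      colMeans(matrix(v[seq_len(n_bins * per_bin)], nrow = per_bin))
    }, numeric(n_bins))
  }
  out <- pair_summary(M, labels)
  out$bin_ms <- bin_ms
  out$signal <- kind
  class(out) <- "correlation_summary"
  out
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("pairwise Pearson correlations (%s, %g ms bins)\n",
              x$signal, x$bin_ms))
  cat(sprintf("  all pairs: mean %.3f over %d pairs (%d neurons skipped)\n",
              x$overall_mean, x$n_pairs, x$n_skipped))
  for (g in names(x$class_mean))
    if (!is.na(x$class_mean[g]))
      cat(sprintf("  %-10s mean %.3f (%d pairs)\n", g, x$class_mean[g],
                  as.integer(x$class_pairs[g])))
  invisible(x)
}

#' Excise spike epochs from a voltage trace
#'
#' Replaces samples from each spike time to the end of the neuron's
#' refractory period by linear interpolation between the neighbouring
#' subthreshold samples, yielding the subthreshold membrane potential.
#'
#' @param v Voltage samples (mV).
#' @param spikes Spike times (ms).
#' @param t_ref Refractory period (ms).
#' @param dt_ms Sampling interval (ms).
#' @param t0 Time of the first sample (ms).
#' @return Numeric vector, same length as `v`.
#' @export
remove_spike_epochs <- function(v, spikes, t_ref, dt_ms = 1, t0 = 0) {
  if (length(spikes) == 0) return(v)
  n <- length(v)
  bad <- rep(FALSE, n)
  k_start <- pmax(1, floor((spikes - t0) / dt_ms) + 1)
  k_end <- pmin(n, ceiling((spikes + t_ref - t0) / dt_ms) + 1)
  for (j in seq_along(k_start))
    if (k_start[j] <= n && k_end[j] >= 1) bad[k_start[j]:k_end[j]] <- TRUE
  if (all(bad)) return(v)
  if (any(bad)) {
    good <- which(!bad)
    v[bad] <- stats::approx(good, v[good], xout = which(bad), rule = 2)$y
  }
  v
}

#' Firing-rate distribution summary
#'
#' Per-neuron firing rates with a lognormality check: skewness of the rate
#' distribution and a Shapiro-Wilk normality statistic on the log-rates of
#' active neurons.
#'
#' @param spikes List of spike-time vectors (ms) or a `sim_result`.
#' @param duration Observation time (ms); taken from the result (minus the
#'   1 s burn-in) when a `sim_result` is given.
#' @param from Analysis start (ms) when a `sim_result` is given.
#' @return List with `rates` (Hz), `skewness`, `log_normality` (Shapiro-Wilk
#'   test on log rates, `NULL` if fewer than 3 active neurons), and
#'   `histogram`.
#' @export
rate_distribution <- function(spikes, duration = NULL, from = 1000) {
  if (inherits(spikes, "sim_result")) {
    rates <- firing_rates(spikes, from = from)
  } else {
    if (is.null(duration) || duration <= 0) stop("'duration' must be positive")
    rates <- lengths(spikes) / (duration / 1000)
  }
  active <- rates[rates > 0]
  m <- mean(rates); s <- stats::sd(rates)
  skew <- if (s > 0) mean((rates - m)^3) / s^3 else 0
  log_norm <- NULL
  if (length(active) >= 3 && stats::sd(log(active)) > 0)
    log_norm <- stats::shapiro.test(log(active[seq_len(min(5000,
                                                           length(active)))]))
  list(rates = rates, skewness = skew, log_normality = log_norm,
       n_active = length(active),
       histogram = graphics::hist(rates, plot = FALSE))
}
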