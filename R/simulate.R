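#' External Poisson input specification
#'
#' Per-group external drive. In the spontaneous (oscillatory) state every
#' neuron receives one 100 Hz Poisson source; assemblies get 30 pA synapses
#' (tau 16.3 ms), non-hubs 10 pA, inhibitory neurons 80 pA (tau 6.9 ms). In
#' the active state each neuron additionally receives 70 sources at 5 Hz
#' with weights +25 pA (assemblies), +5 pA (non-hubs) and -25 pA
#' (inhibitory).
#'
#' @param model A `hub_network` (defines the group labels).
#' @param state "spontaneous" or "active" (the barrage table).
#' @return Data frame with columns `group`, `rate` (Hz per source),
#'   `n_sources`, `weight` (pA, signed), `tau_syn` (ms).
#' @export
poisson_noise <- function(model, state = c("spontaneous", "active")) {
  state <- match.arg(state)
  asm <- paste0("assembly", seq_along(model$assembly_groups))
  grp <- c(asm, "nonhub", "inh")
  if (state == "spontaneous") {
    data.frame(group = grp, rate = 100, n_sources = 1,
               weight = c(rep(30, length(asm)), 10, 80),
               tau_syn = c(rep(16.3, length(asm)), 16.3, 6.9),
               stringsAsFactors = FALSE)
  } else {
    data.frame(group = grp, rate = 5, n_sources = 70,
               weight = c(rep(25, length(asm)), 5, -25),
               tau_syn = c(rep(16.3, length(asm)), 16.3, 6.9),
               stringsAsFactors = FALSE)
  }
}

#' Stimulation protocol descriptor
#'
#' @param kind "none", "step_current" (a fixed-amplitude current injected
#'   into a random subset of all neurons, the optogenetics surrogate) or
#'   "poisson_barrage" (extra Poisson input to every neuron, the active
#'   state).
#' @param fraction Fraction of neurons stimulated (step current only).
#' @param amplitude Step amplitude in pA.
#' @param onset,duration Stimulus window (ms).
#' @param inputs For `poisson_barrage`: a noise table as from
#'   [poisson_noise()].
#' @return A `stimulus_protocol` object.
#' @export
stimulus_protocol <- function(kind = c("none", "step_current",
                                       "poisson_barrage"),
                              fraction = 0.15, amplitude = 100,
                              onset = 0, duration = 300, inputs = NULL) {
  kind <- match.arg(kind)
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  structure(list(kind = kind, fraction = fraction, amplitude = amplitude,
                 onset = onset, duration = duration, inputs = inputs),
            class = "stimulus_protocol")
}

build_neuron_arrays <- function(neurons) {
  n <- length(neurons)
  n_eta <- max(vapply(neurons, function(p) length(p$eta), 0L))
  n_gam <- max(vapply(neurons, function(p) length(p$gamma), 0L))
  pad <- function(ks, nk, field) {
    v <- vapply(ks, function(k) k[[field]], 0)
    c(v, rep(if (field == "amplitude") 0 else 1, nk - length(v)))
  }
  list(C = vapply(neurons, `[[`, 0, "C"),
       g_L = vapply(neurons, `[[`, 0, "g_L"),
       E_L = vapply(neurons, `[[`, 0, "E_L"),
       t_ref = vapply(neurons, `[[`, 0, "t_ref"),
       V_reset = vapply(neurons, `[[`, 0, "V_reset"),
       lambda_0 = vapply(neurons, `[[`, 0, "lambda_0"),
       delta_V = vapply(neurons, `[[`, 0, "delta_V"),
       V_T_star = vapply(neurons, `[[`, 0, "V_T_star"),
       eta_amp = vapply(neurons, function(p) pad(p$eta, n_eta, "amplitude"),
                        numeric(n_eta)),
       eta_tau = vapply(neurons, function(p) pad(p$eta, n_eta, "time_constant"),
                        numeric(n_eta)),
       gam_amp = vapply(neurons, function(p) pad(p$gamma, n_gam, "amplitude"),
                        numeric(n_gam)),
       gam_tau = vapply(neurons, function(p) pad(p$gamma, n_gam, "time_constant"),
                        numeric(n_gam)))
}

#' Simulate a network of GIF neurons
#'
#' Clock-driven simulation of a `hub_network`: exponential post-synaptic
#' currents with per-class time constants, a global 1 ms transmission delay,
#' external Poisson noise, and optionally a stimulation protocol. Neuron
#' parameters default to the packaged class parameters with plus/minus 15
#' percent uniform heterogeneity drawn per neuron.
#'
#' All randomness (heterogenization, stimulated-subset choice, Poisson
#' arrivals, spike sampling) derives from R's RNG, so `seed` makes the run
#' bit-reproducible.
#'
#' @param model A `hub_network` from [build_network()] or [read_network()].
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms); must not exceed the 1 ms delay.
#' @param heterogeneity Uniform parameter spread passed to [heterogenize()];
#'   set 0 for identical neurons (the homogeneous variant).
#' @param noise Noise table as from [poisson_noise()]; `NULL` for none.
#' @param protocol A [stimulus_protocol()] or `NULL`.
#' @param seed Optional integer seed.
#' @param record_dt Voltage recording resolution (ms); use `dt` for
#'   step-resolution traces.
#' @param record_threshold Also record the dynamic threshold traces.
#' @param neurons Optional list of per-neuron [gif_params()] overriding the
#'   default heterogenized parameters.
#' @param base_params Named list with elements `exc` and `inh` used as the
#'   class base parameters before heterogenization (for kernel sweeps).
#' @return A `sim_result`: per-neuron spike times (ms), voltage traces at
#'   `record_dt` resolution (neurons by samples), per-neuron resting
#'   potentials, labels, protocol metadata and the seed.
#' @export
run_network <- function(model, duration = 10000, dt = 0.1,
                        heterogeneity = 0.15,
                        noise = poisson_noise(model), protocol = NULL,
                        seed = NULL, record_dt = 1,
                        record_threshold = FALSE, neurons = NULL,
                        base_params = NULL) {
  stopifnot(inherits(model, "hub_network"))
  if (dt <= 0) stop("'dt' must be positive")
  if (dt > model$delay)
    stop("'dt' must not exceed the transmission delay (events would be lost)")
  if (!is.null(seed)) set.seed(seed)
  n <- model$layout$n_total
  if (is.null(base_params))
    base_params <- list(exc = gif_parameters("exc"),
                        inh = gif_parameters("inh"))
  if (is.null(neurons)) {
    neurons <- lapply(model$classes, function(cl) {
      if (heterogeneity > 0) heterogenize(base_params[[cl]], heterogeneity)
      else base_params[[cl]]
    })
  }
  if (length(neurons) != n) stop("need one parameter set per neuron")
  arr <- build_neuron_arrays(neurons)

  # synaptic tau groups: per (sender class, receiver class) plus noise taus
  W <- model$weights
  tab <- model$conn_table
  sender <- rep(seq_len(n), diff(W@p))
  receiver <- W@i + 1L
  key <- paste(model$classes[sender], model$classes[receiver])
  tau_of_key <- stats::setNames(tab$tau_syn, paste(tab$sender, tab$receiver))
  syn_tau <- unname(tau_of_key[key])
  group_tau <- sort(unique(c(syn_tau,
                             if (!is.null(noise)) noise$tau_syn,
                             if (!is.null(protocol) &&
                                 protocol$kind == "poisson_barrage")
                               protocol$inputs$tau_syn)))
  sg <- match(syn_tau, group_tau) - 1L

  channels <- list()
  n_steps <- round(duration / dt)
  add_channel <- function(spec_tab, on, off) {
    rate <- w <- tau <- rep(0, n)
    for (r in seq_len(nrow(spec_tab))) {
      idx <- which(as.character(model$groups) == spec_tab$group[r])
      rate[idx] <- spec_tab$rate[r] * spec_tab$n_sources[r]
      w[idx] <- spec_tab$weight[r]
      tau[idx] <- spec_tab$tau_syn[r]
    }
    g <- ifelse(tau > 0, match(tau, group_tau) - 1L, 0L)
    list(rate = rate, w = w, g = as.integer(g), on = as.integer(on),
         off = as.integer(off))
  }
  if (!is.null(noise)) channels <- c(channels, list(add_channel(noise, 0, n_steps)))

  stim_amp <- rep(0, n); stim_on <- 0L; stim_off <- 0L
  stimulated <- integer(0)
  if (!is.null(protocol) && protocol$kind != "none") {
    if (protocol$kind == "step_current") {
      stimulated <- sort(sample.int(n, round(protocol$fraction * n)))
      stim_amp[stimulated] <- protocol$amplitude
      stim_on <- as.integer(round(protocol$onset / dt))
      stim_off <- as.integer(round((protocol$onset + protocol$duration) / dt))
    } else {
      channels <- c(channels, list(add_channel(
        protocol$inputs, round(protocol$onset / dt),
        round((protocol$onset + protocol$duration) / dt))))
    }
  }

  out <- sim_network_cpp(
    n_steps = n_steps, dt = dt,
    delay_steps = as.integer(round(model$delay / dt)),
    Cm = arr$C, gL = arr$g_L, EL = arr$E_L,
    ref_steps = as.integer(round(arr$t_ref / dt)), Vreset = arr$V_reset,
    lam0 = arr$lambda_0, dV = arr$delta_V, VTstar = arr$V_T_star,
    eta_amp = arr$eta_amp, eta_tau = arr$eta_tau,
    gam_amp = arr$gam_amp, gam_tau = arr$gam_tau,
    sp = W@p, si = W@i, sw = W@x, sg = sg, group_tau = group_tau,
    noise_channels = channels, stim_amp = stim_amp,
    stim_on = stim_on, stim_off = stim_off,
    record_every = as.integer(round(record_dt / dt)),
    record_VT = record_threshold)

  spikes <- split(out$spike_t, factor(out$spike_id, levels = seq_len(n)))
  names(spikes) <- NULL
  structure(list(spikes = spikes, V = out$V, VT = out$VT,
                 record_dt = out$record_dt, dt = dt, duration = duration,
                 classes = model$classes, groups = model$groups,
                 hubs = model$hubs, E_L = arr$E_L,
                 t_ref = arr$t_ref, seed = seed,
                 protocol = protocol, stimulated = stimulated,
                 mode = model$mode),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  n <- length(x$spikes)
  total <- sum(lengths(x$spikes))
  cat(sprintf("sim_result: %d neurons, %.3g s at dt = %.3g ms (%s)\n",
              n, x$duration / 1000, x$dt,
              if (is.null(x$protocol)) "spontaneous" else x$protocol$kind))
  cat(sprintf("  %d spikes (%.2f Hz network mean); V recorded every %.3g ms\n",
              total, 1000 * total / (n * x$duration), x$record_dt))
  invisible(x)
}

#' Firing rates per neuron from a simulation
#'
#' @param sim A `sim_result`.
#' @param from,to Analysis window (ms); defaults to the whole run after a
#'   1 s burn-in.
#' @return Numeric vector of rates (Hz), one per neuron.
#' @export
firing_rates <- function(sim, from = 1000, to = sim$duration) {
  stopifnot(inherits(sim, "sim_result"), to > from)
  vapply(sim$spikes, function(s) sum(s >= from & s < to), 0) /
    ((to - from) / 1000)
}

#' Optogenetics-like step-current stimulation experiment
#'
#' Builds the requested layer variant, injects a 100 pA step current into a
#' random 15 percent of all neurons for 300 ms, and summarizes the response
#' of the non-stimulated excitatory population: depolarization relative to
#' the pre-stimulus baseline and spike counts, split into weight-hubs and
#' non-hubs. The `long_lasting` flag reports whether the mean depolarization
#' of non-stimulated excitatory neurons during the stimulus exceeds
#' `depol_threshold`.
#'
#' @param layer One of "L5_dense" (dense hub assemblies), "L23_sparse"
#'   (layer 2/3, sparse hub connectivity), "L5_no_hub" (assembly with strong
#'   internal but normal inward weights), "L5_sparse_hub" (hub assemblies at
#'   20 percent density).
#' @param seed Optional integer seed.
#' @param onset Stimulus onset (ms); preceded by a settling period.
#' @param stim_duration,amplitude,fraction Stimulus parameters.
#' @param tail Extra simulated time after the stimulus (ms).
#' @param depol_threshold Depolarization (mV) defining a long-lasting
#'   response.
#' @param dt Integration step (ms).
#' @return List with `result` (the `sim_result`) and `summary`.
#' @export
optogenetic_protocol <- function(layer = c("L5_dense", "L23_sparse",
                                           "L5_no_hub", "L5_sparse_hub"),
                                 seed = NULL, onset = 1500,
                                 stim_duration = 300, amplitude = 100,
                                 fraction = 0.15, tail = 700,
                                 depol_threshold = 5, dt = 0.1) {
  layer <- match.arg(layer)
  if (!is.null(seed)) set.seed(seed)
  model <- switch(layer,
    L5_dense = build_network(population_layout("L5"), "heterogeneous"),
    L23_sparse = build_network(population_layout("L23"), "heterogeneous"),
    L5_no_hub = build_network(population_layout("L5"), "no_hub"),
    L5_sparse_hub = build_network(population_layout("L5"), "sparse_hub"))
  proto <- stimulus_protocol("step_current", fraction = fraction,
                             amplitude = amplitude, onset = onset,
                             duration = stim_duration)
  sim <- run_network(model, duration = onset + stim_duration + tail, dt = dt,
                     protocol = proto, seed = NULL)
  s <- summarize_step_response(sim, depol_threshold = depol_threshold)
  list(result = sim, summary = s, layer = layer)
}

#' Summarize the response to a step-current stimulus
#'
#' @param sim A `sim_result` from a `step_current` protocol.
#' @param baseline_ms Length of the pre-stimulus baseline window.
#' @param post_ms Length of the post-stimulus window.
#' @param depol_threshold Depolarization (mV) defining a long-lasting
#'   response.
#' @return List of depolarization (mV above baseline, during and after the
#'   stimulus) and spike counts of non-stimulated excitatory neurons, split
#'   by hub status, plus the `long_lasting` flag.
#' @export
summarize_step_response <- function(sim, baseline_ms = 500, post_ms = 200,
                                    depol_threshold = 5) {
  stopifnot(inherits(sim, "sim_result"),
            !is.null(sim$protocol), sim$protocol$kind == "step_current")
  onset <- sim$protocol$onset
  offset <- onset + sim$protocol$duration
  n <- length(sim$spikes)
  exc <- which(sim$classes == "exc")
  nonstim <- setdiff(exc, sim$stimulated)
  ns_hub <- intersect(nonstim, sim$hubs)
  ns_nonhub <- setdiff(nonstim, sim$hubs)
  tidx <- function(from, to) {
    k <- seq(floor(from / sim$record_dt), ceiling(to / sim$record_dt) - 1)
    k[k >= 0 & k < ncol(sim$V)] + 1
  }
  win_mean <- function(idx, from, to)
    rowMeans(sim$V[idx, tidx(from, to), drop = FALSE])
  base <- win_mean(nonstim, onset - baseline_ms, onset)
  during <- win_mean(nonstim, onset, offset)
  post <- win_mean(nonstim, offset, offset + post_ms)
  depol <- during - base
  counts <- function(idx, from, to)
    vapply(sim$spikes[idx], function(s) sum(s >= from & s < to), 0)
  list(depol_during = mean(depol),
       depol_post = mean(post - base),
       depol_during_hub = mean(depol[match(ns_hub, nonstim)]),
       depol_during_nonhub = mean(depol[match(ns_nonhub, nonstim)]),
       spikes_during_hub = sum(counts(ns_hub, onset, offset)),
       spikes_during_nonhub = sum(counts(ns_nonhub, onset, offset)),
       spikes_post = sum(counts(nonstim, offset, offset + post_ms)),
       long_lasting = mean(depol) >= depol_threshold)
}

#' Active-state (Poisson barrage) experiment
#'
#' Runs the network with its spontaneous noise and, during
#' `[onset, offset)`, an additional barrage of 70 Poisson sources at 5 Hz
#' per neuron (weights +25/+5/-25 pA onto assemblies, non-hubs and
#' inhibitory neurons). Summarizes class-wise firing rates inside the
#' window, pairwise spike correlations inside the window, and whether
#' up/down oscillations are detected before and after the barrage.
#'
#' @param model A `hub_network`.
#' @param onset,offset Barrage window (ms).
#' @param duration Total simulated time (ms).
#' @param seed Optional integer seed.
#' @param dt Integration step (ms).
#' @param corr_bin Bin (ms) for the spike-correlation summary.
#' @return List with `result` and `summary` (rates in Hz).
#' @export
active_state_protocol <- function(model, onset = 3000, offset = 5000,
                                  duration = 8000, seed = NULL, dt = 0.1,
                                  corr_bin = 10) {
  stopifnot(offset > onset)
  proto <- stimulus_protocol("poisson_barrage", onset = onset,
                             duration = offset - onset,
                             inputs = poisson_noise(model, "active"))
  sim <- run_network(model, duration = duration, dt = dt, protocol = proto,
                     seed = seed)
  win_s <- (offset - onset) / 1000
  rate_in <- vapply(sim$spikes, function(s) sum(s >= onset & s < offset), 0) / win_s
  grp <- as.character(sim$groups)
  rates <- c(exc = mean(rate_in[sim$classes == "exc"]),
             inh = mean(rate_in[sim$classes == "inh"]),
             vapply(split(rate_in, grp), mean, 0))
  corr <- pairwise_pearson(sim, kind = "spikes", bin_ms = corr_bin,
                           from = onset, to = offset)
  seg_pre <- segment_result(sim, from = 1000, to = onset)
  seg_post <- segment_result(sim, from = offset, to = duration)
  list(result = sim,
       summary = list(rates = rates,
                      spike_correlation = corr$overall_mean,
                      oscillating_before = any(vapply(seg_pre, nrow, 0L) > 0),
                      oscillating_after = any(vapply(seg_post, nrow, 0L) > 0)))
}

#' Sweep an adaptation-kernel parameter
#'
#' Re-simulates the reference network while varying one excitatory
#' adaptation parameter: the time constant of the slow threshold kernel
#' (`gamma2_tau`, ms) or the amplitude of the fast threshold kernel
#' (`gamma1_amp`, mV). Up- and down-state durations of excitatory neurons
#' are pooled across neurons and trials.
#'
#' @param values Parameter values to test (original units).
#' @param kernel Which parameter to vary.
#' @param n_trials Simulations per value (fresh network each).
#' @param duration Simulated time per trial (ms).
#' @param layout Network layout.
#' @param seed Optional integer seed.
#' @param dt Integration step (ms).
#' @return Data frame with one row per value: mean/sd of up- and down-state
#'   durations (ms) and the number of contributing intervals.
#' @export
adaptation_sweep <- function(values, kernel = c("gamma2_tau", "gamma1_amp"),
                             n_trials = 1, duration = 10000,
                             layout = population_layout("L5"), seed = NULL,
                             dt = 0.1) {
  kernel <- match.arg(kernel)
  if (length(values) == 0) stop("'values' must be non-empty")
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(values, function(v) {
    ups <- downs <- numeric(0)
    for (trial in seq_len(n_trials)) {
      exc <- gif_parameters("exc")
      if (kernel == "gamma2_tau") exc$gamma[[2]]$time_constant <- v
      else exc$gamma[[1]]$amplitude <- v
      model <- build_network(layout, "heterogeneous")
      sim <- run_network(model, duration = duration, dt = dt,
                         base_params = list(exc = exc,
                                            inh = gif_parameters("inh")))
      segs <- segment_result(sim, neurons = which(sim$classes == "exc"))
      ups <- c(ups, unlist(lapply(segs, function(s) s$duration)))
      downs <- c(downs, unlist(lapply(segs, down_state_durations)))
    }
    data.frame(value = v,
               up_mean = mean(ups), up_sd = stats::sd(ups),
               down_mean = mean(downs), down_sd = stats::sd(downs),
               n_up = length(ups), n_down = length(downs))
  })
  do.call(rbind, rows)
}

#' Write simulation outputs to a directory
#'
#' Spikes as CSV (`neuron_id`, `time_ms`, `class`, `group`), voltage traces
#' as CSV (one column per recorded neuron, first column time in ms), and a
#' YAML manifest with protocol metadata and the seed.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @param traces Indices of neurons whose voltage traces to write (default
#'   all recorded).
#' @return `dir`, invisibly.
#' @export
write_sim_result <- function(sim, dir, traces = seq_len(nrow(sim$V))) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- rep(seq_along(sim$spikes), lengths(sim$spikes))
  utils::write.csv(data.frame(neuron_id = ids,
                              time_ms = unlist(sim$spikes),
                              class = sim$classes[ids],
                              group = as.character(sim$groups)[ids]),
                   file.path(dir, "spikes.csv"), row.names = FALSE)
  tm <- seq(0, by = sim$record_dt, length.out = ncol(sim$V))
  tr <- data.frame(time_ms = tm, t(sim$V[traces, , drop = FALSE]))
  names(tr)[-1] <- paste0("n", traces)
  utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  yaml::write_yaml(list(duration = sim$duration, dt = sim$dt,
                        record_dt = sim$record_dt, seed = sim$seed,
                        protocol = if (is.null(sim$protocol)) "spontaneous"
                                   else unclass(sim$protocol)[
                                     c("kind", "fraction", "amplitude",
                                       "onset", "duration")],
                        stimulated = as.integer(sim$stimulated)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
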