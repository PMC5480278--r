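#' Exponential spike-triggered kernel
#'
#' Kernels of the form \eqn{b\,e^{-t/\tau}} describe the stereotypical
#' after-effects of a spike: the adaptation current \eqn{\eta(t)} (amplitude
#' in pA) and the moving firing threshold \eqn{\gamma(t)} (amplitude in mV).
#' Contributions from successive spikes accumulate linearly.
#'
#' @param amplitude Kernel amplitude at lag 0 (pA for \eqn{\eta}, mV for
#'   \eqn{\gamma}). May be negative.
#' @param time_constant Decay time constant in ms; must be positive.
#' @return An object of class `exp_kernel`.
#' @examples
#' k <- exp_kernel(56.7, 57.8)
#' eval_kernel(k, c(-1, 0, 57.8))
#' @export
exp_kernel <- function(amplitude, time_constant) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  if (!is.numeric(time_constant) || length(time_constant) != 1L ||
      !is.finite(time_constant) || time_constant <= 0) {
    stop("'time_constant' must be a single positive number (ms)")
  }
  structure(list(amplitude = amplitude, time_constant = time_constant),
            class = "exp_kernel")
}

#' Evaluate an exponential kernel at given lags
#'
#' @param kernel An [exp_kernel()].
#' @param t Lags in ms (vectorized). Negative lags evaluate to 0 (causality).
#' @return Numeric vector of kernel values.
#' @export
eval_kernel <- function(kernel, t) {
  stopifnot(inherits(kernel, "exp_kernel"))
  ifelse(t >= 0, kernel$amplitude * exp(-t / kernel$time_constant), 0)
}

#' GIF neuron parameter set
#'
#' Container for the constants of the stochastic generalized
#' integrate-and-fire neuron: passive membrane (`C`, `g_L`, `E_L`), reset and
#' refractoriness (`V_reset`, `t_ref`), spike-triggered adaptation current
#' kernels (`eta`, pA), threshold-movement kernels (`gamma`, mV), and the
#' exponential escape-rate parameters (`lambda_0`, `delta_V`, `V_T_star`).
#'
#' @param C Membrane capacitance (pF), positive.
#' @param g_L Leak conductance (nS), positive.
#' @param E_L Resting (leak reversal) potential (mV).
#' @param t_ref Absolute refractory period (ms), non-negative.
#' @param V_reset Post-spike reset potential (mV).
#' @param eta List of [exp_kernel()]s for the adaptation current (pA).
#' @param gamma List of [exp_kernel()]s for the threshold movement (mV).
#' @param lambda_0 Stochastic intensity at threshold (kHz), positive.
#' @param delta_V Sharpness of the exponential escape rate (mV), positive.
#' @param V_T_star Baseline firing threshold (mV).
#' @param cell_class Optional label ("exc", "inh", ...).
#' @return An object of class `gif_params`.
#' @seealso [gif_parameters()] for the packaged per-class defaults.
#' @export
gif_params <- function(C, g_L, E_L, t_ref, V_reset, eta, gamma,
                       lambda_0, delta_V, V_T_star, cell_class = NA_character_) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm))
    as.numeric(x)
  }
  C <- num1(C, "C"); g_L <- num1(g_L, "g_L"); E_L <- num1(E_L, "E_L")
  t_ref <- num1(t_ref, "t_ref"); V_reset <- num1(V_reset, "V_reset")
  lambda_0 <- num1(lambda_0, "lambda_0"); delta_V <- num1(delta_V, "delta_V")
  V_T_star <- num1(V_T_star, "V_T_star")
  if (C <= 0) stop("'C' must be positive")
  if (g_L <= 0) stop("'g_L' must be positive")
  if (t_ref < 0) stop("'t_ref' must be non-negative")
  if (lambda_0 <= 0) stop("'lambda_0' must be positive")
  if (delta_V <= 0) stop("'delta_V' must be positive")
  as_kernels <- function(x, nm) {
    if (inherits(x, "exp_kernel")) x <- list(x)
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), "exp_kernel")))
      stop(sprintf("'%s' must be a list of exp_kernel objects", nm))
    x
  }
  structure(list(C = C, g_L = g_L, E_L = E_L, t_ref = t_ref,
                 V_reset = V_reset, eta = as_kernels(eta, "eta"),
                 gamma = as_kernels(gamma, "gamma"), lambda_0 = lambda_0,
                 delta_V = delta_V, V_T_star = V_T_star,
                 cell_class = cell_class),
            class = "gif_params")
}

#' @export
print.gif_params <- function(x, ...) {
  cat(sprintf("GIF neuron parameters (%s)\n",
              if (is.na(x$cell_class)) "unlabelled" else x$cell_class))
  cat(sprintf("  C = %.4g pF, g_L = %.4g nS (tau_m = %.4g ms), E_L = %.4g mV\n",
              x$C, x$g_L, membrane_tau(x), x$E_L))
  cat(sprintf("  V_reset = %.4g mV, t_ref = %.4g ms\n", x$V_reset, x$t_ref))
  cat(sprintf("  escape rate: lambda_0 = %.4g kHz, delta_V = %.4g mV, V_T* = %.4g mV\n",
              x$lambda_0, x$delta_V, x$V_T_star))
  fmt <- function(ks) paste(vapply(ks, function(k)
    sprintf("%.4g exp(-t/%.4g)", k$amplitude, k$time_constant), ""), collapse = " + ")
  cat("  eta(t)   =", fmt(x$eta), "pA\n")
  cat("  gamma(t) =", fmt(x$gamma), "mV\n")
  invisible(x)
}

#' Packaged GIF parameters per cell class
#'
#' Reads the default parameter files shipped with the package (one YAML file
#' per cell class, values extracted from mouse barrel cortex recordings).
#'
#' @param cell_class "exc" (excitatory/pyramidal) or "inh"
#'   (inhibitory/fast-spiking).
#' @param file Optional path to a YAML file with the same layout, overriding
#'   the packaged defaults.
#' @return A [gif_params()] object.
#' @examples
#' p <- gif_parameters("exc")
#' membrane_tau(p)   # C/g_L, about 22.5 ms
#' @export
gif_parameters <- function(cell_class = c("exc", "inh"), file = NULL) {
  if (is.null(file)) {
    cell_class <- match.arg(cell_class)
    file <- system.file("extdata", "parameters", paste0(cell_class, ".yaml"),
                        package = "hubsim", mustWork = TRUE)
  }
  y <- yaml::read_yaml(file)
  kern <- function(entries) lapply(entries, function(e)
    exp_kernel(e$amplitude, e$time_constant))
  gif_params(C = y$C, g_L = y$g_L, E_L = y$E_L, t_ref = y$t_ref,
             V_reset = y$V_reset, eta = kern(y$eta), gamma = kern(y$gamma),
             lambda_0 = y$lambda_0, delta_V = y$delta_V,
             V_T_star = y$V_T_star, cell_class = y$cell_class)
}

#' Write GIF parameters to YAML
#'
#' @param params A [gif_params()] object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gif_parameters <- function(params, file) {
  stopifnot(inherits(params, "gif_params"))
  y <- list(cell_class = params$cell_class, C = params$C, g_L = params$g_L,
            E_L = params$E_L, t_ref = params$t_ref, V_reset = params$V_reset,
            lambda_0 = params$lambda_0, delta_V = params$delta_V,
            V_T_star = params$V_T_star,
            eta = lapply(params$eta, function(k)
              list(amplitude = k$amplitude, time_constant = k$time_constant)),
            gamma = lapply(params$gamma, function(k)
              list(amplitude = k$amplitude, time_constant = k$time_constant)))
  yaml::write_yaml(y, file)
  invisible(file)
}

#' Membrane time constant
#'
#' @param params A [gif_params()] object.
#' @return \eqn{\tau_m = C/g_L} in ms.
#' @export
membrane_tau <- function(params) {
  stopifnot(inherits(params, "gif_params"))
  params$C / params$g_L
}

#' Stochastic firing intensity of the GIF neuron
#'
#' Exponential escape rate
#' \eqn{\lambda(t) = \lambda_0 \exp\{(V - V_T)/\Delta V\}}: the neuron fires
#' stochastically, with intensity \eqn{\lambda_0} when the membrane potential
#' sits exactly at the (dynamic) threshold.
#'
#' @param V Membrane potential (mV), vectorized.
#' @param threshold Current value of the dynamic threshold \eqn{V_T} (mV).
#' @param params A [gif_params()] object (uses `lambda_0`, `delta_V`).
#' @return Intensity in kHz (strictly increasing in `V`).
#' @export
firing_intensity <- function(V, threshold, params) {
  stopifnot(inherits(params, "gif_params"))
  if (any(!is.finite(V))) stop("non-finite membrane potential: numerical blow-up")
  if (any(!is.finite(threshold))) stop("non-finite threshold")
  params$lambda_0 * exp((V - threshold) / params$delta_V)
}

#' Initial state of a GIF neuron
#'
#' @param params A [gif_params()] object.
#' @return A `gif_state` list: membrane potential at rest, no adaptation, no
#'   threshold offset, empty spike history.
#' @export
gif_init_state <- function(params) {
  stopifnot(inherits(params, "gif_params"))
  structure(list(V = params$E_L, t = 0,
                 z_eta = numeric(length(params$eta)),
                 z_gamma = numeric(length(params$gamma)),
                 refractory_remaining = 0, spike_history = numeric(0)),
            class = "gif_state")
}

#' Summed adaptation current / threshold offset of a state
#'
#' @param state A `gif_state`.
#' @return Named vector with the summed eta (pA) and gamma (mV) contributions.
#' @export
gif_state_sums <- function(state) {
  c(adaptation_current = sum(state$z_eta), threshold_offset = sum(state$z_gamma))
}

#' Advance a single GIF neuron by one time step
#'
#' Reference (pure R) integrator for one neuron: forward Euler for the
#' passive equation, exact exponential decay for the kernel state variables,
#' Bernoulli spike sampling with per-step probability
#' \eqn{1 - \exp(-\lambda\,dt)}, intensity evaluated at the start-of-step
#' potential. On a spike the potential is reset, the refractory clock is
#' loaded, every kernel is incremented by its amplitude, and integration
#' restarts immediately; during the absolute refractory period the
#' potential evolves but spiking is suppressed, while kernels keep
#' decaying. This stepper is the oracle against which the
#' compiled network core is checked; use [run_network()] for populations.
#'
#' @param state A `gif_state` (see [gif_init_state()]).
#' @param I_input Input current over the step (pA).
#' @param dt Time step (ms); must be positive and at most `t_ref` so that at
#'   most one spike can occur per step.
#' @param params A [gif_params()] object.
#' @return A list with elements `state` (updated) and `spiked` (logical).
#' @export
gif_step <- function(state, I_input, dt, params) {
  stopifnot(inherits(state, "gif_state"), inherits(params, "gif_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("'dt' must be positive")
  if (params$t_ref > 0 && dt > params$t_ref)
    stop("'dt' must not exceed the refractory period (one spike per step)")
  eta_sum <- sum(state$z_eta)
  gamma_sum <- sum(state$z_gamma)
  spiked <- FALSE
  if (state$refractory_remaining > 0) {
    # absolutely refractory: spiking suppressed, but integration has restarted
    state$refractory_remaining <- max(0, state$refractory_remaining - dt)
    state$V <- state$V + dt / params$C *
      (-params$g_L * (state$V - params$E_L) - eta_sum + I_input)
  } else {
    lam <- firing_intensity(state$V, params$V_T_star + gamma_sum, params)
    hazard <- min(lam * dt, 1e3)
    spiked <- stats::runif(1) < -expm1(-hazard)
    if (spiked) {
      state$V <- params$V_reset
      state$refractory_remaining <- params$t_ref
      state$spike_history <- c(state$spike_history, state$t)
      state$z_eta <- state$z_eta +
        vapply(params$eta, function(k) k$amplitude, 0)
      state$z_gamma <- state$z_gamma +
        vapply(params$gamma, function(k) k$amplitude, 0)
    } else {
      state$V <- state$V + dt / params$C *
        (-params$g_L * (state$V - params$E_L) - eta_sum + I_input)
    }
  }
  state$z_eta <- state$z_eta *
    exp(-dt / vapply(params$eta, function(k) k$time_constant, 0))
  state$z_gamma <- state$z_gamma *
    exp(-dt / vapply(params$gamma, function(k) k$time_constant, 0))
  state$t <- state$t + dt
  list(state = state, spiked = spiked)
}

#' Randomly perturb all neuron parameters
#'
#' Models cell-to-cell heterogeneity: every numeric parameter (including each
#' kernel amplitude and time constant) is independently multiplied by a draw
#' from \eqn{U[1-f, 1+f]}. Signs are preserved by construction.
#'
#' @param params A [gif_params()] object.
#' @param fraction Relative spread \eqn{f}, in `[0, 1)`; networks use 0.15
#'   (plus/minus 15 percent) by default.
#' @return A new [gif_params()] object.
#' @export
heterogenize <- function(params, fraction = 0.15) {
  stopifnot(inherits(params, "gif_params"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1)
    stop("'fraction' must be in [0, 1)")
  u <- function() stats::runif(1, 1 - fraction, 1 + fraction)
  perturb_kernel <- function(k) exp_kernel(k$amplitude * u(), k$time_constant * u())
  gif_params(C = params$C * u(), g_L = params$g_L * u(),
             E_L = params$E_L * u(), t_ref = params$t_ref * u(),
             V_reset = params$V_reset * u(),
             eta = lapply(params$eta, perturb_kernel),
             gamma = lapply(params$gamma, perturb_kernel),
             lambda_0 = params$lambda_0 * u(), delta_V = params$delta_V * u(),
             V_T_star = params$V_T_star * u(), cell_class = params$cell_class)
}

#' Peak voltage response to a unit exponential current
#'
#' Closed-form peak of the passive membrane response to an exponential
#' post-synaptic current of unit amplitude (1 pA) and time constant
#' `tau_syn`:
#' \deqn{V_{peak} = \frac{1}{C}\left(\frac{1}{\tau_{syn}}-\frac{1}{\tau_m}\right)^{-1}
#'   \left(e^{-\hat t/\tau_m} - e^{-\hat t/\tau_{syn}}\right),\quad
#'   \hat t = \frac{\ln(\tau_m/\tau_{syn})}{1/\tau_{syn}-1/\tau_m}.}
#' For \eqn{\tau_{syn} = \tau_m} the alpha-function limit
#' \eqn{\tau_m e^{-1}/C} is used.
#'
#' @param tau_syn Synaptic time constant (ms), positive.
#' @param params Receiving neuron's [gif_params()] (passive part only).
#' @return Peak depolarization in mV per pA of current amplitude.
#' @export
psp_peak_factor <- function(tau_syn, params) {
  stopifnot(inherits(params, "gif_params"))
  if (!is.numeric(tau_syn) || length(tau_syn) != 1L || tau_syn <= 0)
    stop("'tau_syn' must be a single positive number (ms)")
  tau_m <- membrane_tau(params)
  k <- 1 / tau_syn - 1 / tau_m
  if (abs(k) * tau_m < 1e-9) return(tau_m * exp(-1) / params$C)
  t_hat <- log(tau_m / tau_syn) / k
  (1 / params$C) * (1 / k) * (exp(-t_hat / tau_m) - exp(-t_hat / tau_syn))
}

#' Convert between PSP and PSC weight conventions
#'
#' Synaptic weights can be quoted as the peak post-synaptic potential (PSP,
#' mV) or as the amplitude of the exponential post-synaptic current (PSC,
#' pA). The two are related linearly through the passive membrane of the
#' receiving neuron; see [psp_peak_factor()]. The round trip
#' `psc_to_psp(psp_to_psc(x))` is the identity to machine precision.
#'
#' @param psp_peak Peak PSP amplitude(s) in mV.
#' @param psc_amplitude PSC amplitude(s) in pA.
#' @param tau_syn Synaptic time constant (ms).
#' @param params Receiving neuron's [gif_params()].
#' @return Converted weight(s): pA for `psp_to_psc`, mV for `psc_to_psp`.
#' @examples
#' exc <- gif_parameters("exc")
#' psp_to_psc(0.66, 16.3, exc)   # about 7.9 pA
#' @export
psp_to_psc <- function(psp_peak, tau_syn, params) {
  psp_peak / psp_peak_factor(tau_syn, params)
}

#' @rdname psp_to_psc
#' @export
psc_to_psp <- function(psc_amplitude, tau_syn, params) {
  psc_amplitude * psp_peak_factor(tau_syn, params)
}
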