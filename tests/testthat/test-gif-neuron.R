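exc <- gif_parameters("exc")
inh <- gif_parameters("inh")

test_that("firing intensity follows the exponential escape rate", {
  # at threshold the intensity equals lambda_0
  expect_equal(firing_intensity(exc$V_T_star, exc$V_T_star, exc), exc$lambda_0)
  # one delta_V above threshold multiplies it by e
  expect_equal(firing_intensity(exc$V_T_star + exc$delta_V, exc$V_T_star, exc),
               exc$lambda_0 * exp(1))
  # excitatory neuron at rest: closed-form evaluation, in Hz
  lam_hz <- 1000 * firing_intensity(-67.0, -39.6, exc)
  expect_equal(lam_hz, 1e4 * exp(-27.4 / 1.4))
  expect_lt(lam_hz, 1e-4)          # essentially silent at rest
  expect_error(firing_intensity(NaN, exc$V_T_star, exc), "non-finite")
  # strictly increasing in V
  v <- seq(-80, -30, 5)
  expect_true(all(diff(firing_intensity(v, exc$V_T_star, exc)) > 0))
})

test_that("kernels evaluate causally and decay exponentially", {
  k <- exp_kernel(56.7, 57.8)
  expect_equal(eval_kernel(k, 0), 56.7)
  expect_equal(eval_kernel(k, 57.8), 56.7 * exp(-1))
  expect_equal(eval_kernel(k, -5), 0)
  expect_error(exp_kernel(1, 0), "positive")
})

test_that("passive integration matches the closed-form RC solution", {
  dt <- 0.1
  st <- gif_init_state(exc)
  st$V <- exc$E_L + 10        # start displaced, no input
  v <- numeric(300)
  set.seed(1)
  for (k in seq_len(300)) {
    st <- gif_step(st, 0, dt, exc)$state
    v[k] <- st$V
  }
  t <- seq_len(300) * dt
  expect_lt(max(abs(v - passive_voltage(t, exc, 0, exc$E_L + 10)) / 10),
            1e-3)              # < 0.1% of the initial displacement
  # after one membrane time constant the displacement has decayed by 1/e
  k_tau <- round(membrane_tau(exc) / dt)
  expect_equal((v[k_tau] - exc$E_L) / 10, exp(-1), tolerance = 5e-3)
})

test_that("constant current drives V to E_L + I/g_L", {
  dt <- 0.1
  st <- gif_init_state(exc)
  set.seed(1)
  for (k in seq_len(3000)) st <- gif_step(st, 37, dt, exc)$state
  expect_equal(st$V, exc$E_L + 10, tolerance = 1e-3)  # 37 pA / 3.7 nS
})

test_that("a spike resets, loads kernels with summed amplitudes, and is refractory", {
  st <- gif_init_state(exc)
  st$V <- 0                    # far above threshold: spike certain
  set.seed(1)
  out <- gif_step(st, 0, 0.1, exc)
  expect_true(out$spiked)
  s <- out$state
  expect_equal(s$V, exc$V_reset)
  sums <- gif_state_sums(s)
  # amplitudes at lag dt (one decay step applied after the spike)
  expect_equal(sums[["adaptation_current"]],
               56.7 * exp(-0.1 / 57.8) - 6.9 * exp(-0.1 / 218.2))
  expect_equal(sums[["threshold_offset"]],
               11.7 * exp(-0.1 / 53.8) + 1.8 * exp(-0.1 / 640.0))
  expect_equal(s$refractory_remaining, exc$t_ref)
  # no spike possible while refractory even at high V
  s$V <- 0
  out2 <- gif_step(s, 0, 0.1, exc)
  expect_false(out2$spiked)
})

test_that("kernel state variables equal explicit sums over spike history", {
  dt <- 0.1
  st <- gif_init_state(exc)
  set.seed(42)
  for (k in seq_len(20000)) st <- gif_step(st, 250, dt, exc)$state
  expect_gt(length(st$spike_history), 5)
  expect_lt(length(st$spike_history), 100)
  lags <- st$t - st$spike_history
  eta_sum <- sum(vapply(exc$eta, function(k) sum(eval_kernel(k, lags)), 0))
  gam_sum <- sum(vapply(exc$gamma, function(k) sum(eval_kernel(k, lags)), 0))
  sums <- gif_state_sums(st)
  expect_equal(sums[["adaptation_current"]], eta_sum, tolerance = 1e-12)
  expect_equal(sums[["threshold_offset"]], gam_sum, tolerance = 1e-12)
})

test_that("per-step spike probability is 1 - exp(-lambda dt)", {
  dt <- 0.1
  st <- gif_init_state(exc)
  st$V <- exc$V_T_star - 2      # moderately excitable
  lam <- firing_intensity(st$V, exc$V_T_star, exc)
  p <- -expm1(-lam * dt)
  n <- 20000
  set.seed(7)
  spikes <- vapply(seq_len(n), function(i) gif_step(st, 0, dt, exc)$spiked,
                   TRUE)
  phat <- mean(spikes)
  expect_lt(abs(phat - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("heterogenization stays inside the stated bounds", {
  set.seed(1)
  expect_identical(heterogenize(exc, 0), exc)
  flat <- function(p) c(p$C, p$g_L, p$E_L, p$t_ref, p$V_reset, p$lambda_0,
                        p$delta_V, p$V_T_star,
                        vapply(c(p$eta, p$gamma), `[[`, 0, "amplitude"),
                        vapply(c(p$eta, p$gamma), `[[`, 0, "time_constant"))
  base <- flat(exc)
  for (rep in 1:50) {
    h <- flat(heterogenize(exc, 0.15))
    expect_true(all(abs(h / base - 1) <= 0.15 + 1e-12))
    expect_true(all(sign(h) == sign(base)))
  }
  # law of large numbers on the uniform multiplier
  draws <- vapply(seq_len(2e4), function(i) heterogenize(exc, 0.15)$C, 0)
  expect_equal(mean(draws), exc$C, tolerance = 0.005 * exc$C)
  expect_error(heterogenize(exc, 1.2), "fraction")
})

test_that("PSP/PSC conversion reproduces the measured class means within 3%", {
  pairs <- connection_table("L5")
  for (r in seq_len(nrow(pairs))) {
    recv <- if (pairs$receiver[r] == "exc") exc else inh
    expect_equal(psp_to_psc(pairs$psp_mean[r], pairs$tau_syn[r], recv),
                 pairs$psc_mean[r], tolerance = 0.03)
  }
})

test_that("PSP/PSC conversion is linear, invertible, and handles tau_syn = tau_m", {
  expect_equal(psp_to_psc(0, 16.3, exc), 0)
  w <- c(0.1, 0.66, 2.5)
  expect_equal(psc_to_psp(psp_to_psc(w, 16.3, exc), 16.3, exc), w,
               tolerance = 1e-12)
  # alpha-function limit: peak factor continuous at tau_syn = tau_m
  tm <- membrane_tau(exc)
  expect_equal(psp_peak_factor(tm, exc), psp_peak_factor(tm * (1 + 1e-7), exc),
               tolerance = 1e-5)
  expect_equal(psp_peak_factor(tm, exc), tm * exp(-1) / exc$C)
  expect_error(psp_to_psc(1, -2, exc), "tau_syn")
})

test_that("packaged parameter files round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  write_gif_parameters(inh, f)
  p2 <- gif_parameters(file = f)
  expect_equal(p2, inh)
})
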