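exc <- gif_parameters("exc")

test_that("an isolated excitatory neuron at rest stays silent", {
  model <- single_neuron_model("exc")
  sim <- run_network(model, duration = 10000, heterogeneity = 0,
                     noise = NULL, seed = 11)
  expect_identical(lengths(sim$spikes), 1L * 0L)
  expect_equal(max(abs(sim$V - exc$E_L)), 0)
})

test_that("a presynaptic spike arrives as a current jump after the 1 ms delay", {
  model <- two_neuron_model(w_pA = 20)
  proto <- stimulus_protocol("step_current", fraction = 0.5,
                             amplitude = 3000, onset = 50, duration = 1)
  # find a seed under which neuron 1 is the stimulated one
  for (seed in 1:10) {
    sim <- run_network(model, duration = 150, dt = 0.1, heterogeneity = 0,
                       noise = NULL, protocol = proto, record_dt = 0.1,
                       seed = seed)
    if (identical(sim$stimulated, 1L) && length(sim$spikes[[1]]) == 1) break
  }
  expect_identical(sim$stimulated, 1L)
  t_sp <- sim$spikes[[1]][1]
  I <- reconstruct_current(sim$V[2, ], 0.1, exc)
  tt <- (seq_along(I) - 1) * 0.1
  k <- which(I > 1)[1]
  expect_equal(tt[k], t_sp + 1)            # alpha(Delta) = 1 at lag Delta
  expect_equal(I[k], 20, tolerance = 1e-8) # jump of exactly w
  # exponential decay with tau_syn = 16.3 ms afterwards
  expect_equal(I[k + 163], 20 * exp(-1), tolerance = 1e-6)
})

test_that("synaptic accumulation is linear in the input spike trains", {
  # response to two presynaptic spikes equals the sum of single-spike
  # responses (same delivery times)
  model <- two_neuron_model(w_pA = 15)
  proto <- stimulus_protocol("step_current", fraction = 0.5,
                             amplitude = 800, onset = 40, duration = 30)
  for (seed in 1:10) {
    sim <- run_network(model, duration = 200, dt = 0.1, heterogeneity = 0,
                       noise = NULL, protocol = proto, record_dt = 0.1,
                       seed = seed)
    if (identical(sim$stimulated, 1L) && length(sim$spikes[[1]]) >= 2) break
  }
  sp <- sim$spikes[[1]]
  I <- reconstruct_current(sim$V[2, ], 0.1, exc)
  tt <- (seq_along(I) - 1) * 0.1
  manual <- rowSums(vapply(sp, function(s)
    ifelse(tt >= s + 1, 15 * exp(-(tt - s - 1) / 16.3), 0), numeric(length(tt))))
  # exact while the receiver stays subthreshold (it does: peak << threshold)
  expect_equal(I, manual, tolerance = 1e-6)
})

test_that("identical seeds give bit-identical runs", {
  set.seed(20)
  model <- build_network(small_layout(), "heterogeneous")
  s1 <- run_network(model, duration = 800, seed = 99)
  s2 <- run_network(model, duration = 800, seed = 99)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$V, s2$V)
  s3 <- run_network(model, duration = 800, seed = 100)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("dt must not exceed the transmission delay", {
  model <- two_neuron_model()
  expect_error(run_network(model, duration = 10, dt = 2), "delay")
  expect_error(run_network(model, duration = 10, dt = -1), "positive")
})

test_that("zero-amplitude stimulation leaves the baseline unchanged", {
  set.seed(21)
  model <- build_network(small_layout(), "heterogeneous")
  proto <- stimulus_protocol("step_current", amplitude = 0, onset = 1500,
                             duration = 300)
  s0 <- run_network(model, duration = 2300, seed = 5, protocol = proto)
  s <- summarize_step_response(s0, baseline_ms = 500)
  expect_lt(abs(s$depol_during), 3)       # no systematic depolarization
  expect_false(isTRUE(s$long_lasting))
  # a zero-weight barrage is equally inert
  barrage <- poisson_noise(model, "active")
  barrage$weight <- 0
  proto2 <- stimulus_protocol("poisson_barrage", onset = 1000,
                              duration = 500, inputs = barrage)
  s1 <- run_network(model, duration = 2300, seed = 6, protocol = proto2)
  s2 <- run_network(model, duration = 2300, seed = 7)
  n1 <- sum(lengths(s1$spikes)); n2 <- sum(lengths(s2$spikes))
  expect_gt(n1, n2 / 3); expect_lt(n1, 3 * n2 + 10)
})

test_that("Poisson noise channels hit their target groups at the right scale", {
  # single neuron, only noise: mean current = rate * w * tau
  model <- single_neuron_model("exc")
  noise <- data.frame(group = "nonhub", rate = 100, n_sources = 1,
                      weight = 10, tau_syn = 16.3)
  sim <- run_network(model, duration = 20000, heterogeneity = 0,
                     noise = noise, record_dt = 1, seed = 31)
  expect_lt(length(sim$spikes[[1]]), 10)  # +4.4 mV mean: only rare tail spikes
  v_mean <- mean(sim$V[1, 5000:20000])
  expect_equal(v_mean, exc$E_L + 0.1 * 10 * 16.3 / exc$g_L, tolerance = 0.05)
})

test_that("sparse hub assemblies abolish non-hub up-states and spiking", {
  set.seed(22)
  model <- build_network(population_layout("L5"), "sparse_hub")
  sim <- run_network(model, duration = 6000, seed = 77)
  nonhub <- setdiff(which(model$classes == "exc"), model$hubs)
  # non-hub neurons are essentially silent (an order of magnitude below
  # the ~3 Hz of the oscillating configuration)
  expect_lt(mean(firing_rates(sim)[nonhub]), 0.5)
  # the slow oscillation is abolished: no sustained depolarized states
  # remain, only smoothing-scale blips from residual hub avalanches
  segs <- segment_result(sim, neurons = nonhub)
  d <- unlist(lapply(segs, function(s) s$duration))
  expect_true(length(d) == 0 || max(d) < 150)
  expect_lt(sum(d) / (length(nonhub) * 5000), 0.01)   # < 1% of time "up"
})

test_that("adaptation sweep validates inputs and aggregates durations", {
  expect_error(adaptation_sweep(numeric(0)), "non-empty")
  expect_error(adaptation_sweep(640, n_trials = 0), "n_trials")
  sw <- adaptation_sweep(c(300, 640), kernel = "gamma2_tau", n_trials = 1,
                         duration = 4000, layout = small_layout(), seed = 12)
  expect_identical(nrow(sw), 2L)
  expect_true(all(sw$n_up > 0))
  expect_true(all(is.finite(sw$up_mean)))
})

test_that("simulation outputs round-trip to CSV/YAML", {
  set.seed(23)
  model <- build_network(small_layout(), "heterogeneous")
  sim <- run_network(model, duration = 600, seed = 3)
  dir <- tempfile()
  write_sim_result(sim, dir, traces = 1:3)
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  expect_identical(nrow(sp), sum(lengths(sim$spikes)))
  tr <- utils::read.csv(file.path(dir, "traces.csv"))
  expect_identical(ncol(tr), 4L)
  expect_equal(tr$n2, sim$V[2, ])
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$duration, 600)
  unlink(dir, recursive = TRUE)
})
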