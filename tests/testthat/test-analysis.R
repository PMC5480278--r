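# naive reference detector: threshold the raw (already smooth) trace
naive_segments <- function(x, thr, dt = 1) {
  r <- rle(x >= thr)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & starts > 1 & ends < length(x)
  (ends[keep] - starts[keep] + 1) * dt
}

test_that("square-wave traces are segmented within the smoothing tolerance", {
  for (width in c(10, 20, 40)) {
    x <- rep(-67, 3000)
    x[1200:1699] <- -52                 # one 500 ms excursion of +15 mV
    seg <- detect_up_states(x, E_L = -67, smooth_width_ms = width,
                            baseline = "resting")
    expect_identical(nrow(seg), 1L)
    expect_lt(abs(seg$duration - 500), 2 * width)
    expect_equal(naive_segments(x, -57), 500)
    # idempotent under re-smoothing: segmenting the smoothed trace again
    sm <- drop(hubsim:::gaussian_smooth(x, width))
    seg2 <- detect_up_states(sm, E_L = -67, smooth_width_ms = width,
                             baseline = "resting")
    expect_identical(nrow(seg2), 1L)
    expect_lt(abs(seg2$duration - seg$duration), 2 * width)
  }
})

test_that("constant and degenerate traces are handled", {
  expect_identical(nrow(detect_up_states(rep(-67, 500), E_L = -67,
                                         baseline = "resting")), 0L)
  expect_error(detect_up_states(rep(NA_real_, 100), E_L = -67), "finite")
})

test_that("the auto baseline tracks tonic depolarization", {
  # a trace riding 13 mV above E_L with +15 mV excursions: the literal
  # resting-potential rule sees one permanent up-state, the auto baseline
  # recovers the excursions
  x <- rep(-54, 4000)
  x[c(500:899, 2000:2399, 3200:3599)] <- -39
  lit <- detect_up_states(x, E_L = -67, baseline = "resting",
                          drop_censored = FALSE)
  expect_identical(nrow(lit), 1L)        # everything above E_L + 10
  auto <- detect_up_states(x, E_L = -67, baseline = "auto")
  expect_identical(nrow(auto), 3L)
  expect_true(all(abs(auto$duration - 400) < 40))
})

test_that("duration statistics use the population standard deviation", {
  expect_equal(duration_cv(c(100, 200, 300))$cv, sqrt(2 / 3) * 100 / 200,
               tolerance = 1e-12)
  expect_equal(duration_cv(c(100, 200, 300))$cv, 0.4082, tolerance = 1e-3)
  expect_equal(duration_cv(rep(250, 10))$cv, 0)
  expect_error(duration_cv(100), "at least two")
})

test_that("transition correlations behave at the limits", {
  x <- rep(-67, 5000)
  x[c(1000:1399, 2500:2899, 4000:4399)] <- -50
  a <- detect_up_states(x, -67, baseline = "resting")
  b <- detect_up_states(x, -67, baseline = "resting")
  tc <- transition_correlation(list(a, b), "up")
  expect_equal(tc$overall_mean, 1)
  tc_dn <- transition_correlation(list(a, b), "down")
  expect_equal(tc_dn$overall_mean, 1)
  # independent transition trains decorrelate
  set.seed(8)
  mk <- function() {
    x <- rep(-67, 60000)
    starts <- sort(round(stats::runif(40, 100, 58500)))
    for (s in starts) x[s:(s + 250)] <- -50
    detect_up_states(x, -67, baseline = "resting")
  }
  segs <- replicate(30, mk(), simplify = FALSE)
  tc0 <- transition_correlation(segs, "up")
  expect_lt(abs(tc0$overall_mean), 0.05)
})

test_that("pair summaries skip zero-variance signals and pool class means", {
  set.seed(9)
  model <- build_network(small_layout(), "heterogeneous")
  sim <- run_network(model, duration = 3000, seed = 41)
  pc <- pairwise_pearson(sim, "spikes", bin_ms = 10)
  expect_true(all(abs(pc$cor_matrix[upper.tri(pc$cor_matrix)]) <= 1 + 1e-12))
  # pooled mean is the pair-count weighted combination over class blocks
  cc <- pc$cor_matrix
  lab <- pc$labels
  blocks <- outer(lab, lab, paste)
  ut <- upper.tri(cc)
  pooled <- sum(tapply(cc[ut], blocks[ut], sum)) / sum(ut)
  expect_equal(pooled, pc$overall_mean, tolerance = 1e-12)
  # a silent neuron is skipped and counted
  sim$spikes[[3]] <- numeric(0)
  pc2 <- pairwise_pearson(sim, "spikes", bin_ms = 10)
  expect_gte(pc2$n_skipped, 1)
})

test_that("a spike train correlates perfectly with itself and Poisson pairs decorrelate", {
  set.seed(10)
  tr <- sort(stats::runif(50, 1000, 11000))
  sim <- structure(list(spikes = list(tr, tr), duration = 11000,
                        record_dt = 1, V = matrix(-67, 2, 11001),
                        classes = c("exc", "exc"),
                        groups = factor(c("nonhub", "nonhub")),
                        E_L = c(-67, -67), t_ref = c(4, 4), hubs = integer(0)),
                   class = "sim_result")
  pc <- pairwise_pearson(sim, "spikes", bin_ms = 10)
  expect_equal(pc$overall_mean, 1)
  # two independent 5 Hz Poisson trains over 10 s
  cors <- vapply(1:20, function(i) {
    s1 <- cumsum(stats::rexp(100, 5e-3)); s1 <- s1[s1 < 10000] + 1000
    s2 <- cumsum(stats::rexp(100, 5e-3)); s2 <- s2[s2 < 10000] + 1000
    sim$spikes <- list(s1, s2); sim$duration <- 11000
    pairwise_pearson(sim, "spikes", bin_ms = 10)$overall_mean
  }, 0)
  expect_lt(mean(abs(cors)), 0.05)
})

test_that("spike epochs are excised by interpolation for subthreshold traces", {
  v <- rep(-60, 200)
  v[100:106] <- -36.7                    # a spike epoch
  out <- remove_spike_epochs(v, spikes = 99, t_ref = 6, dt_ms = 1)
  expect_true(all(out == -60))
  expect_identical(remove_spike_epochs(v, numeric(0), 4), v)
})

test_that("rate distributions flag lognormal shape and silent networks", {
  set.seed(11)
  rates <- stats::rlnorm(400, log(3), 0.8)
  spikes <- lapply(rates, function(r)
    sort(stats::runif(stats::rpois(1, r * 60), 0, 60000)))
  rd <- rate_distribution(spikes, duration = 60000, from = 0)
  expect_gt(rd$skewness, 0.5)
  expect_gt(rd$log_normality$p.value, 0.05)   # non-rejecting at 5%
  silent <- rate_distribution(lapply(1:10, function(i) numeric(0)),
                              duration = 5000)
  expect_true(all(silent$rates == 0))
  expect_null(silent$log_normality)
})
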