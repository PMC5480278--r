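specs <- weight_specs()

test_that("lognormal sampling matches its closed-form moments", {
  set.seed(1)
  degenerate <- lognormal_spec(0.3, 0, 0.5)
  expect_equal(sample_lognormal(degenerate, 5), rep(0.5 * exp(0.3), 5))
  w <- sample_lognormal(specs$fitted, 1e6)
  expect_true(all(w > 0))
  # mean weight of the fitted distribution is 0.66 mV (within MC error)
  expect_equal(mean(w), 0.66, tolerance = 0.015)
  expect_equal(stats::median(w), 0.419 * exp(0.005), tolerance = 0.01)
  expect_error(sample_lognormal(specs$fitted, 0), ">= 1")
})

test_that("moment matching inverts the lognormal mean/sd map", {
  sp <- lognormal_from_moments(36.5, 33.5)
  expect_equal(spec_mean(sp), 36.5, tolerance = 1e-12)
  expect_equal(spec_sd(sp), 33.5, tolerance = 1e-12)
})

test_that("inward correlations rescale rows and compose sigmas", {
  set.seed(2)
  n <- 300
  W <- matrix(0, n, n)
  conn <- matrix(stats::runif(n * n) < 0.2, n, n); diag(conn) <- FALSE
  W[conn] <- sample_lognormal(specs$base, sum(conn))
  expect_equal(apply_inward_correlation(W, rep(1, n)), W)
  a <- sample_lognormal(specs$inward, n)
  W2 <- apply_inward_correlation(W, a)
  expect_equal(W2[5, ], W[5, ] * a[5])
  # sigma of log weights after the transform: sqrt(0.924^2 + 0.15^2) = 0.936
  expect_equal(stats::sd(log(W2[W2 > 0])), 0.936, tolerance = 0.02)
  # inward-sum histogram becomes right-skewed relative to the base matrix
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  expect_gt(skew(rowSums(W2)), skew(rowSums(W)))
  expect_error(apply_inward_correlation(W, a[-1]), "multiplier")
})

test_that("weight-hub labeling picks the largest inward sums deterministically", {
  toy <- matrix(0, 5, 5)
  toy[1, 2] <- 1; toy[2, c(1, 3, 4)] <- 3; toy[3, 5] <- 3; toy[4, 1] <- 7
  # row sums: 1, 9, 3, 7, 0
  expect_identical(label_weight_hubs(toy, 2), c(2L, 4L))
  expect_identical(label_weight_hubs(toy, 0), integer(0))
  expect_error(label_weight_hubs(toy, 6), "exceeds")
  # ties break toward the lowest index
  tie <- matrix(0, 3, 3); tie[1, 2] <- 2; tie[3, 1] <- 2
  expect_identical(label_weight_hubs(tie, 1), 1L)
})

test_that("closed-form replaced fraction reproduces the reference values", {
  expect_equal(replaced_fraction(0.209, 0.50, 0.19), 0.071, tolerance = 0.005)
  expect_equal(replaced_fraction(0.35, 0.50, 0.19), 0.20, tolerance = 0.005)
  expect_equal(replaced_fraction(0.3, 0.19, 0.19), 0)
  expect_error(replaced_fraction(0.2, 0.5, 0), "p_bar")
})

test_that("rewiring reaches the target density and conserves synapse counts", {
  set.seed(3)
  n <- 200
  W <- matrix(0, n, n)
  conn <- matrix(stats::runif(n * n) < 0.19, n, n); diag(conn) <- FALSE
  W[conn] <- sample_lognormal(specs$base, sum(conn))
  groups <- list(1:20, 21:33)
  before <- sum(W > 0)
  rw <- rewire_assemblies(W, groups, 0.5, specs$base)
  expect_identical(sum(rw$W > 0), before)              # exact conservation
  for (g in groups) {
    blk <- rw$W[g, g]; diag(blk) <- NA
    expect_equal(sum(blk > 0, na.rm = TRUE),
                 round(0.5 * length(g) * (length(g) - 1)))
  }
  # empirical replaced fraction matches the closed form within granularity
  f_hub <- length(unlist(groups)) / n
  expect_equal(rw$n_rewired / before,
               replaced_fraction(f_hub, 0.5, before / (n * (n - 1))),
               tolerance = 0.1)
  # mean weight rises slightly (weak synapses replaced by fresh draws into
  # denser hub blocks)
  expect_gt(mean(rw$W[rw$W > 0]), 0.97 * mean(W[W > 0]))
  # target equal to current density leaves the matrix untouched
  dens <- sum(W[1:20, 1:20] > 0) / (20 * 19)
  rw0 <- rewire_assemblies(W, list(1:20), dens, specs$base)
  expect_identical(rw0$n_rewired, 0L)
  expect_equal(rw0$W, W)
})

test_that("infeasible rewiring fails loudly", {
  set.seed(4)
  n <- 12
  W <- matrix(0, n, n)
  W[1, 2] <- 1                    # almost empty graph
  expect_error(rewire_assemblies(W, list(1:10), 1, specs$base),
               "removable")
})

test_that("homogeneous partition solves the constraint equations", {
  part <- homogeneous_partition(95, 359, 0.5, 0.19)
  # average-probability equation holds exactly
  N <- 454
  expect_equal((95^2 * 0.5 + 359^2 * part$p_nh + 2 * 95 * 359 * part$p_nh) /
                 N^2, 0.19, tolerance = 1e-12)
  expect_equal(round(100 * part$p_nh), 18)
  expect_equal(part$w_nh, 0.34, tolerance = 0.03)
  expect_equal(part$w_h, 1.42, tolerance = 0.02)
  expect_equal(part$f_nh + part$f_h, 1)
  expect_true(part$w_nh <= part$w_star && part$w_star <= part$w_h)
  # classification boundary carries the weak probability mass
  m <- spec_meanlog(part$spec)
  expect_equal(stats::plnorm(part$w_star, m, part$spec$sigma) /
                 stats::plnorm(part$w_max, m, part$spec$sigma),
               part$f_nh, tolerance = 1e-9)
  # mixture mean conserves the (truncated) distribution mean
  mix <- part$f_nh * part$w_nh + part$f_h * part$w_h
  trunc_mean <- exp(m + part$spec$sigma^2 / 2) *
    stats::pnorm((log(part$w_max) - m - part$spec$sigma^2) / part$spec$sigma) /
    stats::plnorm(part$w_max, m, part$spec$sigma)
  expect_equal(mix, trunc_mean, tolerance = 1e-9)
  # PSC equivalent of the strong weight
  expect_equal(psp_to_psc(part$w_h, 16.3, gif_parameters("exc")), 16.9,
               tolerance = 0.02)
  # degenerate case: p_h equal to the overall probability
  part0 <- homogeneous_partition(95, 359, 0.19, 0.19)
  expect_equal(part0$p_nh, 0.19, tolerance = 1e-12)
  expect_error(homogeneous_partition(400, 54, 0.9, 0.19), "outside")
})

test_that("built networks match the class-wise connection statistics", {
  set.seed(5)
  ly <- population_layout("L5")
  model <- build_network(ly, "heterogeneous")
  W <- model$weights
  expect_true(all(Matrix::diag(W) == 0))
  tab <- model$conn_table
  idx <- list(exc = 1:454, inh = 455:544)
  for (r in seq_len(nrow(tab))) {
    blk <- W[idx[[tab$receiver[r]]], idx[[tab$sender[r]]]]
    n_pairs <- prod(dim(blk)) - if (tab$sender[r] == tab$receiver[r])
      nrow(blk) else 0
    phat <- Matrix::nnzero(blk) / n_pairs
    tol <- 3 * sqrt(tab$p[r] * (1 - tab$p[r]) / n_pairs)
    expect_lt(abs(phat - tab$p[r]), tol)
    # inhibitory senders act with negative sign
    if (tab$sender[r] == "inh") expect_true(all(blk@x <= 0))
    else expect_true(all(blk@x >= 0))
  }
  # hub assemblies have the elevated density
  for (g in model$assembly_groups) {
    blk <- model$exc_psp[g, g]
    expect_equal(Matrix::nnzero(blk) / (length(g) * (length(g) - 1)), 0.5,
                 tolerance = 0.02)
  }
  # fitted-lognormal moment check on the exc block (pre-rewiring scale)
  w <- model$exc_psp@x
  expect_equal(mean(w), spec_mean(specs$fitted), tolerance = 0.05)
  expect_equal(stats::sd(w), spec_sd(specs$fitted), tolerance = 0.15)
  expect_error(build_network(ly, "fancy"), "arg")
})

test_that("inward-sum skewness separates hub modes", {
  set.seed(6)
  ly <- population_layout("L5")
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  m_hub <- build_network(ly, "heterogeneous")
  m_flat <- build_network(ly, "no_hub")
  expect_gt(skew(Matrix::rowSums(m_hub$exc_psp)),
            skew(Matrix::rowSums(m_flat$exc_psp)))
})

test_that("network export and import round-trip through MTX + CSV + YAML", {
  set.seed(7)
  model <- build_network(small_layout(), "heterogeneous")
  dir <- tempfile()
  write_network(model, dir)
  expect_true(all(file.exists(file.path(dir,
    c("weights.mtx", "neurons.csv", "network.yaml")))))
  m2 <- read_network(dir)
  expect_equal(as.matrix(m2$weights), as.matrix(model$weights))
  expect_identical(m2$hubs, model$hubs)
  expect_identical(as.character(m2$groups), as.character(model$groups))
  expect_equal(m2$a, model$a)
  expect_equal(as.matrix(m2$exc_psp), as.matrix(model$exc_psp),
               tolerance = 1e-10)
  unlink(dir, recursive = TRUE)
})
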