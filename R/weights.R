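#' Lognormal synaptic-weight specification
#'
#' Parameterization used for synaptic weight distributions: if `w` follows
#' the spec, then \eqn{\ln w \sim N(\ln w_m + \mu, \sigma^2)} where `w_m` is
#' the median. The closed-form mean is \eqn{w_m e^{\mu + \sigma^2/2}}.
#'
#' @param mu Dimensionless location offset.
#' @param sigma Dimensionless log-scale, non-negative.
#' @param median Median weight `w_m` (mV), positive.
#' @return An object of class `lognormal_spec`.
#' @export
lognormal_spec <- function(mu, sigma, median) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            is.numeric(median), length(median) == 1L, is.finite(median))
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (median <= 0) stop("'median' must be positive")
  structure(list(mu = mu, sigma = sigma, median = median),
            class = "lognormal_spec")
}

#' @export
print.lognormal_spec <- function(x, ...) {
  cat(sprintf(
    "lognormal weight spec: mu = %.4g, sigma = %.4g, median = %.4g mV (mean %.4g, sd %.4g)\n",
    x$mu, x$sigma, x$median, spec_mean(x), spec_sd(x)))
  invisible(x)
}

#' Moments and log-scale parameters of a weight spec
#'
#' @param spec A [lognormal_spec()].
#' @return `spec_meanlog`: the log-scale mean \eqn{\ln w_m + \mu};
#'   `spec_mean`/`spec_sd`: closed-form mean and standard deviation.
#' @export
spec_meanlog <- function(spec) {
  stopifnot(inherits(spec, "lognormal_spec"))
  log(spec$median) + spec$mu
}

#' @rdname spec_meanlog
#' @export
spec_mean <- function(spec) exp(spec_meanlog(spec) + spec$sigma^2 / 2)

#' @rdname spec_meanlog
#' @export
spec_sd <- function(spec) spec_mean(spec) * sqrt(expm1(spec$sigma^2))

#' Moment-matched lognormal spec
#'
#' Builds the [lognormal_spec()] whose mean and standard deviation equal the
#' given values; used for connection classes for which only summary moments
#' are reported.
#'
#' @param mean,sd Target mean and standard deviation (same units), positive.
#' @return A [lognormal_spec()] with `mu = 0` and the matching median/sigma.
#' @export
lognormal_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  sigma2 <- log1p((sd / mean)^2)
  lognormal_spec(mu = 0, sigma = sqrt(sigma2), median = mean * exp(-sigma2 / 2))
}

#' Reference weight specifications for the excitatory population
#'
#' Three related lognormal specs: `base` for the initial weight matrix
#' \eqn{\hat w_{ij}}, `inward` for the per-neuron inward multipliers
#' \eqn{a_i} (median 1), and `fitted` for the resulting overall distribution
#' matched to experimental EPSP amplitudes (mean 0.66 mV, sd 0.76 mV). The
#' product of `base` and `inward` draws is again lognormal with
#' \eqn{\sigma = \sqrt{0.924^2 + 0.15^2} = 0.936}.
#'
#' @return Named list of [lognormal_spec()]s.
#' @export
weight_specs <- function() {
  list(base   = lognormal_spec(mu = 0.141,   sigma = 0.924, median = 0.372),
       inward = lognormal_spec(mu = 1.4e-4,  sigma = 0.15,  median = 1),
       fitted = lognormal_spec(mu = 0.005,   sigma = 0.936, median = 0.419))
}

#' Sample synaptic weights
#'
#' @param spec A [lognormal_spec()].
#' @param n Number of i.i.d. draws, at least 1.
#' @return Positive weights (mV), length `n`.
#' @export
sample_lognormal <- function(spec, n) {
  stopifnot(inherits(spec, "lognormal_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  stats::rlnorm(n, meanlog = spec_meanlog(spec), sdlog = spec$sigma)
}

#' Apply inward weight correlations
#'
#' Multiplies all weights received by neuron `i` (row `i` of the
#' receiver-by-sender excitatory weight matrix) by its inward multiplier
#' \eqn{a_i}: \eqn{w_{ij} = \hat w_{ij} a_i}. Neurons with a large
#' multiplier receive many strong synapses and become weight-hub candidates.
#'
#' @param W_hat Dense or sparse receiver-by-sender weight matrix (mV); zero
#'   entries mark absent synapses.
#' @param a Positive per-neuron multipliers, length `nrow(W_hat)`.
#' @return The rescaled weight matrix, same storage as `W_hat`.
#' @export
apply_inward_correlation <- function(W_hat, a) {
  if (length(a) != nrow(W_hat))
    stop("length(a) must equal nrow(W_hat) (one multiplier per receiver)")
  if (any(a <= 0)) stop("inward multipliers must be positive")
  W_hat * a   # recycles down columns: row i scaled by a[i]
}

#' Label weight-hub neurons
#'
#' Weight-hubs are the neurons with the largest summed inward synaptic
#' weights (row sums of the receiver-by-sender weight matrix). Deterministic
#' given the weights; ties are broken toward the lowest index.
#'
#' @param weights Receiver-by-sender weight matrix (mV).
#' @param n_hubs Number of hubs to label, at most `nrow(weights)`.
#' @return Sorted integer indices of the hub neurons.
#' @export
label_weight_hubs <- function(weights, n_hubs) {
  n <- nrow(weights)
  if (n_hubs > n) stop("'n_hubs' exceeds the number of neurons")
  if (n_hubs == 0) return(integer(0))
  inward <- Matrix::rowSums(weights)
  sort(order(-inward, seq_len(n))[seq_len(n_hubs)])
}

#' Closed-form fraction of synapses replaced by assembly rewiring
#'
#' Raising the connection probability among the hub fraction `f_hub` of
#' excitatory neurons from the network-wide `p_bar` to `p_h`, while holding
#' the total synapse count fixed, replaces the fraction
#' \eqn{f_{hub}^2 (p_h/\bar p - 1)} of all excitatory synapses.
#'
#' @param f_hub Fraction of excitatory neurons that are hubs, in `[0, 1]`.
#' @param p_h Target within-assembly connection probability.
#' @param p_bar Overall connection probability, in `(0, 1]`.
#' @return Replaced fraction (dimensionless).
#' @examples
#' replaced_fraction(0.209, 0.50, 0.19)   # about 0.071
#' @export
replaced_fraction <- function(f_hub, p_h, p_bar) {
  if (!is.numeric(p_bar) || any(p_bar <= 0) || any(p_bar > 1))
    stop("'p_bar' must be in (0, 1]")
  if (any(f_hub < 0) || any(f_hub > 1)) stop("'f_hub' must be in [0, 1]")
  f_hub^2 * (p_h / p_bar - 1)
}

#' Homogeneous two-population weight partition
#'
#' Splits an excitatory population into `N_h` weight-hubs and `N_nh`
#' non-hubs with homogeneous weights per subpopulation, constrained so that
#' the overall connection probability stays at `p_bar` and the two-element
#' weight distribution approximates the full lognormal: the non-hub
#' probability solves
#' \deqn{\bar p = \frac{N_h^2 p_h + N_{nh}^2 p_{nh} + 2 N_h N_{nh}
#'   p_{nh}}{(N_h + N_{nh})^2},}
#' the weak fraction is
#' \eqn{f_{nh} = (N_{nh}^2 + N_h N_{nh}) p_{nh} / ((N_h+N_{nh})^2 \bar p)},
#' the classification boundary `w_star` solves
#' \eqn{\int_0^{w^*} p(w)\,dw = f_{nh}} numerically, and `w_nh`, `w_h` are
#' the conditional means of the weight distribution below and above the
#' boundary.
#'
#' The weight density is the lognormal `spec` restricted to `(0, w_max]`.
#' The default `w_max = 5` mV caps the distribution at the upper end of
#' experimentally reported EPSP amplitudes, keeping the strong-weight class
#' inside the observed range; `w_max = Inf` uses the unbounded lognormal.
#'
#' @param N_h,N_nh Hub and non-hub population sizes.
#' @param p_h Hub-to-hub connection probability.
#' @param p_bar Overall connection probability.
#' @param spec Weight [lognormal_spec()]; default the fitted overall spec.
#' @param w_max Upper truncation of the weight density (mV).
#' @return An object of class `partition_result` with fields `p_nh`, `f_nh`,
#'   `f_h`, `w_star`, `w_nh`, `w_h` (all PSP weights in mV).
#' @examples
#' part <- homogeneous_partition(95, 359, 0.5, 0.19)
#' round(100 * part$p_nh)         # 18 percent
#' round(c(part$w_nh, part$w_h), 2)
#' @export
homogeneous_partition <- function(N_h, N_nh, p_h, p_bar,
                                  spec = weight_specs()$fitted, w_max = 5) {
  stopifnot(N_h >= 1, N_nh >= 1, inherits(spec, "lognormal_spec"), w_max > 0)
  N <- N_h + N_nh
  p_nh <- (p_bar * N^2 - N_h^2 * p_h) / (N_nh^2 + 2 * N_h * N_nh)
  if (!is.finite(p_nh) || p_nh <= 0 || p_nh > 1)
    stop(sprintf("average-probability constraint gives p_nh = %.4g outside (0, 1]",
                 p_nh))
  f_nh <- (N_nh^2 + N_h * N_nh) * p_nh / (N^2 * p_bar)
  f_h <- 1 - f_nh
  m <- spec_meanlog(spec); s <- spec$sigma
  Z <- stats::plnorm(w_max, m, s)   # truncation mass
  # classification boundary: P(w <= w*) / Z = f_nh, solved numerically
  w_star <- stats::uniroot(function(w) stats::plnorm(w, m, s) / Z - f_nh,
                           lower = 1e-12, upper = min(w_max, 1e6),
                           tol = 1e-12)$root
  # conditional means of the (truncated) lognormal below/above the boundary
  partial_mean <- function(a, b) {   # E[w; a < w <= b] unnormalized
    exp(m + s^2 / 2) * (stats::pnorm((log(b) - m - s^2) / s) -
                        stats::pnorm((log(a) - m - s^2) / s))
  }
  w_nh <- partial_mean(0, w_star) / (f_nh * Z)
  w_h <- partial_mean(w_star, w_max) / (f_h * Z)
  structure(list(p_nh = p_nh, f_nh = f_nh, f_h = f_h, w_star = w_star,
                 w_nh = w_nh, w_h = w_h, N_h = N_h, N_nh = N_nh, p_h = p_h,
                 p_bar = p_bar, spec = spec, w_max = w_max),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("homogeneous partition: N_h = %d, N_nh = %d, p_h = %.3g, p_bar = %.3g\n",
              x$N_h, x$N_nh, x$p_h, x$p_bar))
  cat(sprintf("  p_nh = %.4g, f_nh = %.4g, w* = %.4g mV\n", x$p_nh, x$f_nh, x$w_star))
  cat(sprintf("  w_nh = %.4g mV, w_h = %.4g mV\n", x$w_nh, x$w_h))
  invisible(x)
}

#' Rewire excitatory connectivity into dense hub assemblies
#'
#' Raises the connection probability inside each hub group to `p_h` while
#' conserving the total number of synapses: unconnected within-group pairs
#' receive new synapses (weights drawn from `weight_spec`, scaled by the
#' receiver's inward multiplier when `a` is supplied), and an equal number
#' of synapses is removed, sampled uniformly from the removable set. With a
#' single group the removable set is every connected pair involving at least
#' one non-hub; with several groups, between-group hub-hub pairs are
#' removable as well.
#'
#' Groups whose density already meets or exceeds `p_h` are left untouched
#' (the target is reached "from below"; no synapses are deleted inside
#' groups).
#'
#' @param W Dense receiver-by-sender excitatory weight matrix (mV, zero =
#'   absent). Modified copies are returned; the input is not changed.
#' @param groups List of integer index vectors, one per assembly (disjoint).
#' @param p_h Target within-group connection probability (of ordered pairs).
#' @param weight_spec [lognormal_spec()] for new synapse weights.
#' @param a Optional per-receiver inward multipliers (see
#'   [apply_inward_correlation()]).
#' @return List with `W` (rewired matrix), `n_rewired` (synapses replaced),
#'   `added`, `removed` (two-column index matrices).
#' @export
rewire_assemblies <- function(W, groups, p_h, weight_spec = weight_specs()$base,
                              a = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(ncol(W) == n, is.list(groups))
  idx_all <- unlist(groups)
  if (anyDuplicated(idx_all)) stop("assembly groups must be disjoint")
  if (length(idx_all) && (min(idx_all) < 1 || max(idx_all) > n))
    stop("group indices out of range")
  if (p_h < 0 || p_h > 1) stop("'p_h' must be a probability")
  hubs <- sort(idx_all)
  added <- matrix(integer(0), 0, 2); removed <- matrix(integer(0), 0, 2)
  new_w <- numeric(0)
  for (g in groups) {
    ng <- length(g)
    if (ng < 2) next
    block <- W[g, g, drop = FALSE]
    diag(block) <- NA   # exclude autapses
    connected <- which(!is.na(block) & block != 0, arr.ind = TRUE)
    open <- which(!is.na(block) & block == 0, arr.ind = TRUE)
    target <- round(p_h * ng * (ng - 1))
    n_add <- target - nrow(connected)
    if (n_add <= 0) next
    if (n_add > nrow(open)) n_add <- nrow(open)
    pick <- open[sample.int(nrow(open), n_add), , drop = FALSE]
    recv <- g[pick[, 1]]; send <- g[pick[, 2]]
    w <- sample_lognormal(weight_spec, n_add)
    if (!is.null(a)) w <- w * a[recv]
    W[cbind(recv, send)] <- w
    added <- rbind(added, cbind(recv, send))
    new_w <- c(new_w, w)
  }
  n_rewired <- nrow(added)
  if (n_rewired > 0) {
    # removable synapses: >=1 non-hub endpoint, plus between-group hub pairs
    # when there are several groups
    conn <- which(W != 0, arr.ind = TRUE)
    is_hub <- logical(n); is_hub[hubs] <- TRUE
    grp_id <- integer(n)
    for (k in seq_along(groups)) grp_id[groups[[k]]] <- k
    rh <- is_hub[conn[, 1]]; sh <- is_hub[conn[, 2]]
    non_hub_pair <- !(rh & sh)
    between_groups <- rh & sh & (grp_id[conn[, 1]] != grp_id[conn[, 2]])
    removable <- which(non_hub_pair | (length(groups) > 1 & between_groups))
    if (length(removable) < n_rewired)
      stop(sprintf(
        "cannot conserve synapse count: %d removals needed but only %d removable synapses",
        n_rewired, length(removable)))
    drop <- conn[removable[sample.int(length(removable), n_rewired)], ,
                 drop = FALSE]
    W[drop] <- 0
    removed <- drop
  }
  list(W = W, n_rewired = n_rewired, added = added, removed = removed)
}
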