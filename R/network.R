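#' Population layout of a single cortical layer
#'
#' Neuron counts and assembly sizes for one simulated layer. Defaults follow
#' mouse barrel cortex: layer 5A holds 454 excitatory and 90 inhibitory
#' neurons with three hub assemblies of 45, 30 and 20 neurons; layer 2/3
#' holds 1691 excitatory and 230 inhibitory neurons (hubs present but not
#' densified there).
#'
#' @param layer "L5" or "L23" (sets the defaults below).
#' @param n_exc,n_inh Population sizes.
#' @param assembly_sizes Integer vector of hub-assembly sizes; their sum is
#'   the number of weight-hub neurons.
#' @return An object of class `population_layout`.
#' @export
population_layout <- function(layer = c("L5", "L23"), n_exc = NULL,
                              n_inh = NULL, assembly_sizes = NULL) {
  layer <- match.arg(layer)
  if (is.null(n_exc)) n_exc <- switch(layer, L5 = 454L, L23 = 1691L)
  if (is.null(n_inh)) n_inh <- switch(layer, L5 = 90L, L23 = 230L)
  if (is.null(assembly_sizes)) assembly_sizes <- c(45L, 30L, 20L)
  n_exc <- as.integer(n_exc); n_inh <- as.integer(n_inh)
  assembly_sizes <- as.integer(assembly_sizes)
  if (sum(assembly_sizes) > n_exc)
    stop("assemblies cannot contain more neurons than the excitatory population")
  structure(list(layer = layer, n_exc = n_exc, n_inh = n_inh,
                 assembly_sizes = assembly_sizes,
                 n_hubs = sum(assembly_sizes), n_total = n_exc + n_inh),
            class = "population_layout")
}

#' Connection statistics per class pair
#'
#' Pairwise connection probability, synaptic time constant, and weight
#' moments (both PSP and PSC convention) for the four sender-receiver class
#' combinations, as measured in mouse barrel cortex. For layer 2/3 the
#' excitatory-to-excitatory probability and mean weight are lowered to 16.8
#' percent and 0.37 mV.
#'
#' @param layer "L5" or "L23".
#' @return A data frame with one row per ordered class pair.
#' @export
connection_table <- function(layer = c("L5", "L23")) {
  layer <- match.arg(layer)
  tab <- data.frame(
    sender   = c("exc", "exc", "inh", "inh"),
    receiver = c("exc", "inh", "exc", "inh"),
    p        = c(0.19, 0.37, 0.50, 0.35),
    tau_syn  = c(16.3, 6.9, 1.3, 6.9),
    psp_mean = c(0.66, 0.55, 0.48, 0.48),
    psp_sd   = c(0.76, 0.51, 0.44, 0.49),
    psc_mean = c(7.9, 9.9, 36.5, 8.7),
    psc_sd   = c(9.1, 9.2, 33.5, 8.9),
    stringsAsFactors = FALSE)
  if (layer == "L23") {
    tab$p[1] <- 0.168
    scale <- 0.37 / 0.66
    tab$psp_mean[1] <- 0.37
    tab$psp_sd[1] <- tab$psp_sd[1] * scale
    tab$psc_mean[1] <- tab$psc_mean[1] * scale
    tab$psc_sd[1] <- tab$psc_sd[1] * scale
  }
  tab
}

er_block <- function(n_recv, n_send, p, square = FALSE) {
  # Erdos-Renyi adjacency; square blocks exclude the diagonal (no autapses)
  m <- matrix(stats::runif(n_recv * n_send) < p, n_recv, n_send)
  if (square) diag(m) <- FALSE
  m
}

#' Construct a layer network model
#'
#' Samples Erdos-Renyi connectivity per connection class and builds the
#' excitatory weight structure according to `mode`:
#' \describe{
#'   \item{heterogeneous}{Base lognormal weights times per-neuron inward
#'     multipliers; hubs labeled by largest inward weight sums, randomly
#'     split into assemblies and rewired to density `p_h` (the reference
#'     configuration).}
#'   \item{homogeneous}{Two-element weight structure from
#'     [homogeneous_partition()]: hub receivers get `w_h`, non-hub receivers
#'     `w_nh`; within-assembly probability `p_h`, all other pairs `p_nh`.
#'     Non-excitatory weights are set to their class means.}
#'   \item{no_hub}{Base weights without inward multipliers (no weight-hubs);
#'     randomly chosen groups are still rewired to density `p_h` and their
#'     internal weights strengthened by the hub-conditional inward factor,
#'     so the assembly has strong internal but normal inward weights.}
#'   \item{sparse_hub}{As heterogeneous but with sparse assemblies
#'     (`p_h = 0.2`).}
#' }
#' Non-excitatory connection classes always draw weights from a lognormal
#' moment-matched to the measured class mean/sd (PSC convention). Weights of
#' inhibitory senders act with negative sign on the receiver.
#'
#' @param layout A [population_layout()].
#' @param mode Weight-structure variant, see Details.
#' @param p_h Within-assembly connection probability (ignored for
#'   `homogeneous`, which takes it too; default 0.5, or 0.2 for
#'   `sparse_hub`).
#' @param specs Weight specs as from [weight_specs()].
#' @param table Connection statistics as from [connection_table()].
#' @return An object of class `hub_network`: sparse signed PSC weight matrix
#'   (pA, receiver by sender), excitatory PSP matrix (mV), per-neuron class
#'   and group labels, hub indices, inward multipliers, synaptic time
#'   constants and the 1 ms transmission delay.
#' @export
build_network <- function(layout,
                          mode = c("heterogeneous", "homogeneous", "no_hub",
                                   "sparse_hub"),
                          p_h = NULL, specs = weight_specs(),
                          table = connection_table(layout$layer)) {
  stopifnot(inherits(layout, "population_layout"))
  mode <- match.arg(mode)
  if (is.null(p_h)) p_h <- if (mode == "sparse_hub") 0.2 else 0.5
  ne <- layout$n_exc; ni <- layout$n_inh; n <- ne + ni
  p_bar <- table$p[table$sender == "exc" & table$receiver == "exc"]
  n_hubs <- layout$n_hubs
  a <- NULL

  if (mode == "homogeneous") {
    part <- homogeneous_partition(n_hubs, ne - n_hubs, p_h, p_bar, specs$fitted)
    hubs <- sort(sample.int(ne, n_hubs))
    groups <- split(sample(hubs), rep(seq_along(layout$assembly_sizes),
                                      layout$assembly_sizes))
    groups <- lapply(groups, sort)
    adj <- er_block(ne, ne, part$p_nh, square = TRUE)
    for (g in groups) {
      blk <- er_block(length(g), length(g), p_h, square = TRUE)
      adj[g, g] <- blk
    }
    w_recv <- ifelse(seq_len(ne) %in% hubs, part$w_h, part$w_nh)
    W_exc <- adj * w_recv   # recycled down columns: receiver-wise weights
  } else {
    adj <- er_block(ne, ne, p_bar, square = TRUE)
    W_exc <- matrix(0, ne, ne)
    W_exc[adj] <- sample_lognormal(specs$base, sum(adj))
    if (mode %in% c("heterogeneous", "sparse_hub")) {
      a <- sample_lognormal(specs$inward, ne)
      W_exc <- apply_inward_correlation(W_exc, a)
      hubs <- label_weight_hubs(W_exc, n_hubs)
    } else {            # no_hub: no inward correlations, random groups
      hubs <- sort(sample.int(ne, n_hubs))
    }
    if (layout$layer == "L23") {
      # L2/3: weight-hubs stay at the background density; no assemblies are
      # formed, so no neurons carry an assembly label (or assembly noise)
      groups <- list()
    } else {
      groups <- split(sample(hubs), rep(seq_along(layout$assembly_sizes),
                                        layout$assembly_sizes))
      groups <- lapply(groups, sort)
      rw <- rewire_assemblies(W_exc, groups, p_h, specs$base, a = a)
      W_exc <- rw$W
      if (mode == "no_hub") {
        # strong internal weights, normal (uncorrelated) inward weights:
        # scale within-group synapses by the conditional mean multiplier of
        # the hub fraction under the inward spec
        f_hub <- n_hubs / ne
        sc <- hub_inward_factor(specs$inward, f_hub)
        for (g in groups) W_exc[g, g] <- W_exc[g, g] * sc
      }
    }
  }

  classes <- rep(c("exc", "inh"), c(ne, ni))
  group_of <- rep("nonhub", n)
  group_of[(ne + 1):n] <- "inh"
  for (k in seq_along(groups)) group_of[groups[[k]]] <- paste0("assembly", k)
  group_of <- factor(group_of,
                     levels = c(paste0("assembly", seq_along(groups)),
                                "nonhub", "inh"))

  # assemble the full signed PSC matrix (receiver x sender)
  exc_params <- gif_parameters("exc")
  psc_exc <- W_exc / psp_peak_factor(
    table$tau_syn[table$sender == "exc" & table$receiver == "exc"], exc_params)
  W <- matrix(0, n, n)
  W[1:ne, 1:ne] <- psc_exc
  blocks <- list(c("exc", "inh"), c("inh", "exc"), c("inh", "inh"))
  for (b in blocks) {
    row <- table[table$sender == b[1] & table$receiver == b[2], ]
    send_idx <- if (b[1] == "exc") 1:ne else (ne + 1):n
    recv_idx <- if (b[2] == "exc") 1:ne else (ne + 1):n
    adj_b <- er_block(length(recv_idx), length(send_idx), row$p,
                      square = b[1] == b[2])
    wb <- if (mode == "homogeneous") {
      rep(row$psc_mean, sum(adj_b))
    } else {
      sample_lognormal(lognormal_from_moments(row$psc_mean, row$psc_sd),
                       sum(adj_b))
    }
    blk <- matrix(0, length(recv_idx), length(send_idx))
    blk[adj_b] <- if (b[1] == "inh") -wb else wb
    W[recv_idx, send_idx] <- blk
  }

  structure(list(layout = layout, mode = mode, p_h = p_h,
                 weights = methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                                   "generalMatrix"), "CsparseMatrix"),
                 exc_psp = methods::as(methods::as(Matrix::Matrix(W_exc, sparse = TRUE),
                                                   "generalMatrix"), "CsparseMatrix"),
                 classes = classes, groups = group_of, hubs = hubs,
                 assembly_groups = groups, a = a, delay = 1,
                 conn_table = table),
            class = "hub_network")
}

#' Conditional inward-multiplier mean of the hub fraction
#'
#' Mean of the inward multiplier `a` conditioned on lying in the top
#' `f_hub` quantile of its lognormal distribution; used to set "strong
#' internal" assembly weights in the no-hub control at the level hub
#' assemblies reach through inward correlations.
#'
#' @param spec Inward-multiplier [lognormal_spec()].
#' @param f_hub Hub fraction in `(0, 1)`.
#' @return Scalar factor (> 1 for `f_hub < 1/2`).
#' @export
hub_inward_factor <- function(spec, f_hub) {
  stopifnot(inherits(spec, "lognormal_spec"), f_hub > 0, f_hub < 1)
  m <- spec_meanlog(spec); s <- spec$sigma
  z <- stats::qnorm(1 - f_hub)
  exp(m + s^2 / 2) * stats::pnorm(s - z) / f_hub
}

#' @export
print.hub_network <- function(x, ...) {
  ly <- x$layout
  cat(sprintf("hub_network (%s, %s): %d exc + %d inh neurons\n",
              ly$layer, x$mode, ly$n_exc, ly$n_inh))
  cat(sprintf("  %d weight-hubs in %d assemblies (%s), p_h = %.3g\n",
              ly$n_hubs, length(x$assembly_groups),
              paste(ly$assembly_sizes, collapse = "/"), x$p_h))
  dens <- Matrix::nnzero(x$exc_psp) / (ly$n_exc * (ly$n_exc - 1))
  cat(sprintf("  exc->exc density %.3f, mean PSP weight %.3f mV\n",
              dens, mean(x$exc_psp@x)))
  invisible(x)
}

#' Export / import a network model
#'
#' Writes the signed PSC weight matrix in Matrix Market (MTX) sparse format,
#' a CSV sidecar with per-neuron metadata (1-based id, class, group label,
#' hub flag, inward multiplier), and a YAML file with layout, mode and
#' connection statistics. `read_network()` reverses the operation.
#'
#' @param model A `hub_network`.
#' @param dir Output directory (created if needed).
#' @return `write_network()`: `dir` invisibly; `read_network()`: a
#'   `hub_network` (without the mV-convention excitatory matrix, which is
#'   recomputed from the PSC weights).
#' @export
write_network <- function(model, dir) {
  stopifnot(inherits(model, "hub_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(model$weights, file.path(dir, "weights.mtx"))
  ly <- model$layout
  meta <- data.frame(id = seq_len(ly$n_total), class = model$classes,
                     group = as.character(model$groups),
                     hub = seq_len(ly$n_total) %in% model$hubs,
                     a = c(if (is.null(model$a)) rep(NA, ly$n_exc) else model$a,
                           rep(NA, ly$n_inh)))
  utils::write.csv(meta, file.path(dir, "neurons.csv"), row.names = FALSE)
  yaml::write_yaml(list(layer = ly$layer, n_exc = ly$n_exc, n_inh = ly$n_inh,
                        assembly_sizes = as.integer(ly$assembly_sizes),
                        mode = model$mode, p_h = model$p_h,
                        delay = model$delay,
                        connection_table = model$conn_table),
                   file.path(dir, "network.yaml"))
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "network.yaml"))
  W <- methods::as(methods::as(Matrix::readMM(file.path(dir, "weights.mtx")),
                               "generalMatrix"), "CsparseMatrix")
  meta <- utils::read.csv(file.path(dir, "neurons.csv"))
  ly <- population_layout(cfg$layer, cfg$n_exc, cfg$n_inh, cfg$assembly_sizes)
  tab <- as.data.frame(cfg$connection_table)
  hubs <- meta$id[meta$hub]
  groups <- factor(meta$group,
                   levels = c(paste0("assembly",
                                     seq_along(cfg$assembly_sizes)),
                              "nonhub", "inh"))
  asm <- lapply(paste0("assembly", seq_along(cfg$assembly_sizes)),
                function(g) meta$id[meta$group == g])
  exc_params <- gif_parameters("exc")
  tau_ee <- tab$tau_syn[tab$sender == "exc" & tab$receiver == "exc"]
  W_exc <- W[1:cfg$n_exc, 1:cfg$n_exc] * psp_peak_factor(tau_ee, exc_params)
  structure(list(layout = ly, mode = cfg$mode, p_h = cfg$p_h, weights = W,
                 exc_psp = W_exc, classes = meta$class, groups = groups,
                 hubs = hubs, assembly_groups = asm,
                 a = if (all(is.na(meta$a))) NULL else meta$a[1:cfg$n_exc],
                 delay = cfg$delay, conn_table = tab),
            class = "hub_network")
}
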