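# Shared fixtures: tiny networks and closed-form oracles.

# closed-form passive membrane: V(t) for constant current from V0
passive_voltage <- function(t, params, I = 0, V0 = params$E_L) {
  v_inf <- params$E_L + I / params$g_L
  v_inf + (V0 - v_inf) * exp(-t / membrane_tau(params))
}

# hand-built two-neuron network: sender 1 -> receiver 2 with one synapse
two_neuron_model <- function(w_pA = 20) {
  ly <- population_layout("L5", n_exc = 2, n_inh = 0,
                          assembly_sizes = integer(0))
  W <- Matrix::sparseMatrix(i = 2, j = 1, x = w_pA, dims = c(2, 2))
  exc <- gif_parameters("exc")
  structure(list(layout = ly, mode = "heterogeneous", p_h = 0.5,
                 weights = methods::as(W, "CsparseMatrix"),
                 exc_psp = W * psp_peak_factor(16.3, exc),
                 classes = c("exc", "exc"),
                 groups = factor(c("nonhub", "nonhub"),
                                 levels = c("nonhub", "inh")),
                 hubs = integer(0), assembly_groups = list(), a = NULL,
                 delay = 1, conn_table = connection_table("L5")),
            class = "hub_network")
}

single_neuron_model <- function(class = "exc") {
  ly <- population_layout("L5", n_exc = as.integer(class == "exc"),
                          n_inh = as.integer(class == "inh"),
                          assembly_sizes = integer(0))
  W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1))
  structure(list(layout = ly, mode = "heterogeneous", p_h = 0.5,
                 weights = methods::as(W, "CsparseMatrix"), exc_psp = W,
                 classes = class,
                 groups = factor(if (class == "exc") "nonhub" else "inh",
                                 levels = c("nonhub", "inh")),
                 hubs = integer(0), assembly_groups = list(), a = NULL,
                 delay = 1, conn_table = connection_table("L5")),
            class = "hub_network")
}

# reconstruct the input current a neuron received from its dt-resolution
# voltage trace by inverting the Euler update (exact for subthreshold steps)
reconstruct_current <- function(v, dt, params) {
  params$C * diff(v) / dt + params$g_L * (v[-length(v)] - params$E_L)
}

# small L5-like layout for fast network-level tests
small_layout <- function() population_layout("L5", n_exc = 120, n_inh = 24,
                                             assembly_sizes = c(12, 8, 5))
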