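#' K-means clustering (Lloyd's algorithm, reimplemented)
#'
#' Centers are initialized as `K` distinct random data rows; each sample is
#' assigned to the nearest center by Euclidean distance, centers are reset
#' to their members' means, and the two steps repeat until the assignment is
#' stable. A cluster that empties during iteration is re-seeded from the
#' point farthest from its center. The best of `n_restarts` runs by total
#' within-cluster sum of squares is returned; results are deterministic
#' given the RNG state.
#'
#' @param X Numeric matrix, one sample per row.
#' @param K Number of clusters, at most `nrow(X)`.
#' @param n_restarts Independent restarts.
#' @param max_iter Iteration cap per restart.
#' @param init Optional `K` by `ncol(X)` matrix of starting centers used for
#'   one additional restart (warm start).
#' @return A `kmeans_result`: `cluster` (1..K per row), `centers`,
#'   `withinss` per cluster, `tot_withinss`, `iter`, and the per-iteration
#'   `objective` trace of the winning restart (non-increasing).
#' @export
kmeans_lloyd <- function(X, K, n_restarts = 50, max_iter = 100, init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (K > n) stop("'K' cannot exceed the number of samples")
  if (any(!is.finite(X))) stop("features must be finite")
  run_once <- function(centers) {
    assign_old <- rep(0L, n)
    objective <- numeric(0)
    for (iter in seq_len(max_iter)) {
      d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
        2 * X %*% t(centers)
      assign_new <- max.col(-d2, ties.method = "first")
      for (k in seq_len(K)) {
        if (!any(assign_new == k)) {     # empty cluster: re-seed farthest point
          far <- which.max(d2[cbind(seq_len(n), assign_new)])
          centers[k, ] <- X[far, ]
          assign_new[far] <- k
        }
      }
      obj <- sum((X - centers[assign_new, , drop = FALSE])^2)
      if (length(objective) && obj > objective[length(objective)] + 1e-8)
        stop("internal error: k-means objective increased")
      objective <- c(objective, obj)
      if (all(assign_new == assign_old)) break
      assign_old <- assign_new
      for (k in seq_len(K))
        centers[k, ] <- colMeans(X[assign_new == k, , drop = FALSE])
    }
    withinss <- vapply(seq_len(K), function(k)
      sum((X[assign_new == k, , drop = FALSE] -
             matrix(centers[k, ], sum(assign_new == k), ncol(X),
                    byrow = TRUE))^2), 0)
    list(cluster = assign_new, centers = centers, withinss = withinss,
         tot_withinss = sum(withinss), iter = iter, objective = objective)
  }
  best <- NULL
  starts <- replicate(n_restarts,
                      X[sample.int(n, K), , drop = FALSE], simplify = FALSE)
  if (!is.null(init)) starts <- c(starts, list(as.matrix(init)))
  for (centers in starts) {
    res <- run_once(centers)
    if (is.null(best) || res$tot_withinss < best$tot_withinss) best <- res
  }
  structure(c(best, list(K = K, n_restarts = length(starts))),
            class = "kmeans_result")
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("k-means (Lloyd): K = %d, %d restarts, objective %.6g (%d iterations)\n",
              x$K, x$n_restarts, x$tot_withinss, x$iter))
  cat("  cluster sizes:", paste(tabulate(x$cluster, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Choose K by the elbow heuristic
#'
#' Runs [kmeans_lloyd()] over `K_range` and selects the K after which the
#' clustering error stops decreasing abruptly: the K maximizing the discrete
#' second difference (curvature) of the error curve. Each K warm-starts one
#' restart from the previous best centers plus the farthest point, which
#' makes the error curve non-increasing.
#'
#' @param X Feature matrix.
#' @param K_range Candidate cluster counts (at least two values).
#' @param n_restarts Restarts per K.
#' @return List with `K` (selected), `errors` (named vector of objectives)
#'   and `curvature`.
#' @export
elbow_method <- function(X, K_range = 2:8, n_restarts = 50) {
  X <- as.matrix(X)
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) < 2) stop("'K_range' must contain at least two values")
  errors <- numeric(length(K_range))
  prev <- NULL
  fits <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    init <- NULL
    if (!is.null(prev) && nrow(prev$centers) == K - 1) {
      resid <- rowSums((X - prev$centers[prev$cluster, , drop = FALSE])^2)
      init <- rbind(prev$centers, X[which.max(resid), ])
    }
    fit <- kmeans_lloyd(X, K, n_restarts = n_restarts, init = init)
    errors[i] <- fit$tot_withinss
    fits[[i]] <- fit
    prev <- fit
  }
  names(errors) <- K_range
  curvature <- rep(NA_real_, length(K_range))
  if (length(K_range) >= 3)
    for (i in 2:(length(K_range) - 1))
      curvature[i] <- errors[i - 1] - 2 * errors[i] + errors[i + 1]
  K_sel <- if (all(is.na(curvature))) K_range[which.min(errors)]
           else K_range[which.max(curvature)]
  list(K = K_sel, errors = errors, curvature = curvature, fits = fits)
}

#' Optimal cluster-to-truth label matching
#'
#' Exact assignment of predicted cluster labels to ground-truth labels
#' maximizing agreement, by enumeration of permutations (exact Hungarian
#' solution for the small K used here).
#'
#' @param pred Integer predicted clusters (1..K).
#' @param truth Ground-truth labels (coerced to factor).
#' @return List with `accuracy`, the relabeled predictions (`matched`), the
#'   permutation used, and the confusion matrix (truth by matched).
#' @export
match_labels <- function(pred, truth) {
  truth <- as.integer(factor(truth))
  K <- max(max(pred), max(truth))
  if (K > 7) stop("permutation matching supports at most 7 clusters")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best_acc <- -1; best_perm <- seq_len(K)
  for (p in perms(seq_len(K))) {
    acc <- mean(p[pred] == truth)
    if (acc > best_acc) { best_acc <- acc; best_perm <- p }
  }
  matched <- best_perm[pred]
  list(accuracy = best_acc, matched = matched, permutation = best_perm,
       confusion = table(truth = truth, predicted = matched))
}

#' Per-neuron activity features for hub identification
#'
#' Firing rate plus mean and CV of up-state durations per neuron, the
#' feature set used by the two-stage clustering.
#'
#' @param sim A `sim_result`.
#' @param segs Segmentations from [segment_result()] for the same neurons;
#'   computed if `NULL`.
#' @param neurons Indices (default: all excitatory neurons).
#' @param from Analysis start (ms, burn-in excluded).
#' @return Data frame with `neuron`, `rate` (Hz), `up_mean` (ms), `up_cv`,
#'   `n_up`.
#' @export
activity_features <- function(sim, segs = NULL,
                              neurons = which(sim$classes == "exc"),
                              from = 1000) {
  stopifnot(inherits(sim, "sim_result"))
  if (is.null(segs)) segs <- segment_result(sim, neurons = neurons, from = from)
  rate <- firing_rates(sim, from = from)[neurons]
  up <- t(vapply(segs, function(s) {
    if (nrow(s) < 2) return(c(NA_real_, NA_real_, nrow(s)))
    d <- duration_cv(s$duration)
    c(d$mean, d$cv, nrow(s))
  }, numeric(3)))
  data.frame(neuron = neurons, rate = rate, up_mean = up[, 1],
             up_cv = up[, 2], n_up = as.integer(up[, 3]))
}

#' Two-stage identification of weight-hub neurons and their assemblies
#'
#' Stage 1 clusters all analyzable excitatory neurons (K = 2) on firing
#' rate and CV of up-state durations; the cluster with the lower mean CV is
#' taken as the weight-hubs. Stage 2 clusters the identified hubs (K = 3 by
#' default, or chosen by [elbow_method()]) on the mean and CV of up-state
#' durations. When construction-time labels are available, accuracies are
#' scored with optimal label matching.
#'
#' @param sim A `sim_result`.
#' @param features Optional precomputed [activity_features()].
#' @param truth_hubs Optional ground-truth hub indices (defaults to the hub
#'   labels stored in the simulation).
#' @param truth_assembly Optional factor of assembly labels per neuron
#'   (defaults to the stored group labels).
#' @param K2 Number of assemblies for stage 2; `NULL` selects it with the
#'   elbow method.
#' @param standardize Z-score features before clustering (the two features
#'   are on different scales).
#' @param n_restarts Restarts per clustering.
#' @return List with stage-1 and stage-2 cluster results, hub indices,
#'   accuracies (when truth is available), selected K, and the indices of
#'   neurons excluded for having fewer than two up-states.
#' @export
identify_hubs <- function(sim, features = NULL, truth_hubs = sim$hubs,
                          truth_assembly = sim$groups, K2 = 3,
                          standardize = TRUE, n_restarts = 50) {
  stopifnot(inherits(sim, "sim_result"))
  if (is.null(features)) features <- activity_features(sim)
  ok <- stats::complete.cases(features[, c("rate", "up_cv")])
  excluded <- features$neuron[!ok]
  feat <- features[ok, ]
  zscore <- function(M) {
    M <- as.matrix(M)
    s <- apply(M, 2, stats::sd)
    if (any(s == 0)) stop("degenerate features: zero variance")
    scale(M)
  }
  X1 <- feat[, c("rate", "up_cv")]
  if (standardize) X1 <- zscore(X1)
  s1 <- kmeans_lloyd(as.matrix(X1), 2, n_restarts = n_restarts)
  cv_means <- tapply(feat$up_cv, s1$cluster, mean)
  hub_cluster <- as.integer(names(which.min(cv_means)))
  hubs_found <- feat$neuron[s1$cluster == hub_cluster]

  acc1 <- NULL
  if (!is.null(truth_hubs)) {
    truth1 <- feat$neuron %in% truth_hubs
    pred1 <- s1$cluster == hub_cluster
    acc1 <- mean(pred1 == truth1)
  }

  feat_h <- feat[s1$cluster == hub_cluster, ]
  X2 <- feat_h[, c("up_mean", "up_cv")]
  if (standardize) X2 <- zscore(X2)
  elbow <- NULL
  if (is.null(K2)) {
    elbow <- elbow_method(as.matrix(X2), K_range = 2:6,
                          n_restarts = n_restarts)
    K2 <- elbow$K
  }
  s2 <- kmeans_lloyd(as.matrix(X2), K2, n_restarts = n_restarts)

  acc2 <- NULL; conf2 <- NULL
  if (!is.null(truth_assembly)) {
    lab <- as.character(truth_assembly)[feat_h$neuron]
    in_asm <- grepl("^assembly", lab)
    if (sum(in_asm) >= 2 && length(unique(lab[in_asm])) <= K2) {
      m <- match_labels(s2$cluster[in_asm], lab[in_asm])
      acc2 <- m$accuracy
      conf2 <- m$confusion
    }
  }
  list(stage1 = s1, stage2 = s2, hubs_found = sort(hubs_found),
       hub_cluster = hub_cluster, K2 = K2, elbow = elbow,
       accuracy_stage1 = acc1, accuracy_stage2 = acc2,
       confusion_stage2 = conf2, excluded = excluded, features = features)
}

#' Write identified labels to CSV
#'
#' @param id Result of [identify_hubs()].
#' @param sim The `sim_result` it was computed from (for ground truth).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_hub_labels <- function(id, sim, file) {
  feat <- id$features
  hub_pred <- feat$neuron %in% id$hubs_found
  asm <- rep(NA_integer_, nrow(feat))
  asm[match(id$hubs_found, feat$neuron)] <- id$stage2$cluster
  utils::write.csv(data.frame(neuron = feat$neuron, hub_predicted = hub_pred,
                              assembly_predicted = asm,
                              hub_truth = feat$neuron %in% sim$hubs,
                              group_truth = as.character(sim$groups)[feat$neuron]),
                   file, row.names = FALSE)
  invisible(file)
}
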