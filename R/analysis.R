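#' Record internal activation trajectories
#'
#' Runs the network over a sequence and returns, for each requested
#' convolutional layer, the per-step activations of a seeded random
#' subset of its units (a units x steps matrix). With `units = NULL` or
#' `units` equal to the layer size, no sampling takes place.
#'
#' @param params,arch trained network.
#' @param seq an `mstnn_video` or frame array.
#' @param conv integer vector of convolutional-layer ordinals (1 = the
#'   first/fastest conv layer).
#' @param units number of units to sample per layer (`NULL` = all).
#' @param seed seed for the unit sample.
#' @return a list of `mstnn_trace` objects: matrices (units x T) with the
#'   sampled unit indices as rownames and attributes `conv` and `tau`.
#' @export
record_activations <- function(params, arch, seq, conv = NULL, units = NULL,
                               seed = 1L) {
  plan <- arch_plan(arch)
  nb <- length(plan$blocks)
  if (is.null(conv)) conv <- seq_len(nb)
  if (any(conv < 1 | conv > nb))
    stop("conv layer ordinal out of range 1..", nb)
  out <- forward_sequence(params, arch, seq, record = TRUE)
  lapply(seq_along(conv), function(j) {
    i <- conv[j]
    v <- out$v[[i]]
    dm <- dim(v)
    nunits <- prod(dm[1:3])
    m <- matrix(v, nunits, dm[4])
    rownames(m) <- seq_len(nunits)
    if (!is.null(units) && units < nunits) {
      keep <- with_seed(derive_seed(seed, "units", i),
                        sort(sample.int(nunits, units)))
      m <- m[keep, , drop = FALSE]
    }
    structure(m, class = c("mstnn_trace", "matrix"), conv = i,
              tau = plan$blocks[[i]]$tau)
  })
}

#' Mean per-step activation change of a layer
#'
#' The average absolute one-step change of a convolutional layer's
#' activations over a sequence — small for slow (large-tau) layers whose
#' states drift, large for fast layers that track the input rhythm.
#'
#' @param params,arch trained network.
#' @param seq sequence to analyse.
#' @param conv convolutional-layer ordinal.
#' @return mean of `|v[t+1] - v[t]|` over units and steps.
#' @export
activation_change <- function(params, arch, seq, conv) {
  tr <- record_activations(params, arch, seq, conv = conv)[[1L]]
  mean(abs(tr[, -1, drop = FALSE] - tr[, -ncol(tr), drop = FALSE]))
}

#' Snapshot a layer's state across sequences
#'
#' `snapshot_matrix()` collects the activation vector of one
#' convolutional layer at a fixed time step for every sequence (rows =
#' sequences). `snapshot_pca()` then embeds these snapshots with centered
#' (unscaled) principal component analysis.
#'
#' @param params,arch trained network.
#' @param dataset list of `mstnn_video` (all at least `step` frames long).
#' @param step time step of the snapshot (1-based).
#' @param conv convolutional-layer ordinal.
#' @param n_components number of principal components to keep.
#' @return `snapshot_matrix()`: a sequences x units matrix.
#'   `snapshot_pca()`: an `mstnn_pca` with `scores` (sequences x
#'   components), `explained` (variance ratios, decreasing), `step` and
#'   `conv`.
#' @export
snapshot_matrix <- function(params, arch, dataset, step, conv) {
  stopifnot(length(dataset) >= 1)
  rows <- lapply(dataset, function(s) {
    T_ <- dim(s$frames)[3L]
    if (step > T_) stop("snapshot step ", step, " exceeds sequence length ", T_)
    out <- forward_sequence(params, arch, s, record = TRUE)
    as.vector(out$v[[conv]][, , , step])
  })
  do.call(rbind, rows)
}

#' @rdname snapshot_matrix
#' @export
snapshot_pca <- function(params, arch, dataset, step, conv,
                         n_components = 2L) {
  if (length(dataset) < 3L) stop("snapshot PCA needs at least 3 sequences")
  X <- snapshot_matrix(params, arch, dataset, step, conv)
  tot <- sum(apply(X, 2L, stats::var))
  if (tot < .Machine$double.eps) {
    warning("all snapshots are identical; zero-variance embedding")
    return(structure(list(scores = matrix(0, nrow(X), n_components),
                          explained = rep(0, n_components),
                          step = step, conv = conv),
                     class = "mstnn_pca"))
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(scores = p$x[, seq_len(min(n_components, ncol(p$x))),
                              drop = FALSE],
                 explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)],
                 step = step, conv = conv),
            class = "mstnn_pca")
}

#' Nested-cluster structure of a snapshot embedding
#'
#' Quantifies the "clusters of sub-clusters" organisation of an embedding
#' whose points carry an ordered pair of labels (first action, second
#' action): the coarse score is the mean silhouette coefficient grouping
#' by the second action; the fine score is the mean, over coarse groups,
#' of the silhouette coefficient of the first-action labels within that
#' group. A nested arrangement shows `coarse > fine > 0`.
#'
#' @param scores numeric matrix of embedding coordinates (points x dims),
#'   e.g. the `scores` of an [snapshot_pca()].
#' @param first,second label vectors (first and second action of each
#'   point).
#' @return list with `coarse`, `fine`, and logical `nested`.
#' @export
cluster_structure_summary <- function(scores, first, second) {
  first <- as.integer(factor(first))
  second <- as.integer(factor(second))
  if (length(unique(second)) < 2L || length(unique(first)) < 2L)
    stop("need at least 2 groups in both label sets")
  coarse <- mean_silhouette(scores, second)
  fine_vals <- vapply(unique(second), function(g) {
    idx <- second == g
    if (length(unique(first[idx])) < 2L) return(NA_real_)
    mean_silhouette(scores[idx, , drop = FALSE], first[idx])
  }, numeric(1))
  fine <- mean(fine_vals, na.rm = TRUE)
  list(coarse = coarse, fine = fine,
       nested = is.finite(coarse) && is.finite(fine) &&
         coarse > fine && fine > 0)
}

mean_silhouette <- function(scores, labels) {
  sil <- cluster::silhouette(labels, stats::dist(scores))
  mean(sil[, "sil_width"])
}

#' Linear readout of a state snapshot
#'
#' Trains a multinomial-logistic readout (via `nnet::multinom`) on
#' snapshot vectors and reports its accuracy on held-out snapshots. Used
#' to ask what information a layer's state still carries — e.g. whether
#' the slow layer's final state predicts the first action of a
#' concatenated sequence.
#'
#' @param train_x,train_y training snapshots (rows = sequences) and labels.
#' @param test_x,test_y held-out snapshots and labels.
#' @return held-out accuracy in [0, 1].
#' @export
snapshot_readout <- function(train_x, train_y, test_x, test_y) {
  df <- data.frame(y = factor(train_y), train_x)
  fit <- nnet::multinom(y ~ ., df, trace = FALSE,
                        MaxNWts = (ncol(train_x) + 2L) * nlevels(df$y) + 10L)
  pred <- predict(fit, newdata = data.frame(test_x))
  mean(as.character(pred) == as.character(test_y))
}

#' Top-layer time-constant ablation
#'
#' Retrains the network for each candidate time constant of the deepest
#' (slow) convolutional layer, leaving the lower layers' time constants
#' fixed, and records the per-epoch test accuracy — the experiment that
#' probes how much slow dynamics the contextual-recognition task needs.
#'
#' @param train_data,test_data concatenated-action sequences (black frames
#'   appended), split by subject.
#' @param arch the base `mstnn_arch`.
#' @param config a [training_config()].
#' @param tau_top time constants to try for the top conv layer (default
#'   100, 80, 60, 40, 20).
#' @param seeds training seeds to average over.
#' @return data frame (tau, seed, epoch, test_accuracy) with the
#'   per-(tau, seed) best-epoch accuracies as attribute `"summary"`.
#' @export
time_constant_ablation <- function(train_data, test_data, arch,
                                   config = training_config(),
                                   tau_top = c(100, 80, 60, 40, 20),
                                   seeds = 1L) {
  if (any(tau_top < 1)) stop("time constants must be >= 1")
  rows <- list()
  for (tau in tau_top) {
    arch_tau <- set_top_tau(arch, tau)
    for (seed in seeds) {
      cfg <- config
      cfg$seed <- seed
      fit <- train_mstnn(train_data, arch_tau, cfg, eval_data = test_data)
      rows[[length(rows) + 1L]] <- data.frame(
        tau = tau, seed = seed, epoch = fit$log$epoch,
        test_accuracy = fit$log$test_accuracy)
    }
  }
  tab <- do.call(rbind, rows)
  best <- stats::aggregate(test_accuracy ~ tau + seed, tab, max)
  attr(tab, "summary") <- stats::aggregate(test_accuracy ~ tau, best, mean)
  tab
}
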