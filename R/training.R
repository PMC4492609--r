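#' Training configuration
#'
#' Collects the hyper-parameters of the stochastic gradient training loop.
#' The defaults are the reference settings used throughout the package:
#' initial learning rate 0.1 adapted multiplicatively after every epoch
#' (x 1.05 if the monitored epoch error decreased, / 2 otherwise), weight
#' decay 0.0005 on weights (not biases), Gaussian initialization with
#' sd 0.05, 50 epochs, and a delay window of d = 15 black frames.
#'
#' @param epochs number of passes over the training set.
#' @param learning_rate initial learning rate.
#' @param lr_up multiplier applied when the monitored error decreases.
#' @param lr_down divisor applied otherwise.
#' @param weight_decay L2 shrinkage on kernel and output weights.
#' @param init_sd standard deviation of the Gaussian initializer.
#' @param delay number of appended black frames (= supervised steps).
#' @param seed integer seed fixing initialization and shuffling.
#' @param shuffle present sequences in a fresh random order each epoch.
#' @param monitor error monitored by the learning-rate schedule: mean
#'   squared error between the output distribution and the one-hot target
#'   on supervised steps (`"mse"`, default) or the mean KL loss (`"kl"`).
#' @param literal_window supervise d + 1 steps (`T - t <= d`) instead of
#'   the final d steps; see [sequence_loss()].
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 50L, learning_rate = 0.1, lr_up = 1.05,
                            lr_down = 2, weight_decay = 5e-4, init_sd = 0.05,
                            delay = 15L, seed = 1L, shuffle = TRUE,
                            monitor = c("mse", "kl"),
                            literal_window = FALSE) {
  monitor <- match.arg(monitor)
  stopifnot(epochs >= 0, learning_rate > 0, lr_up > 0, lr_down > 0,
            weight_decay >= 0, init_sd > 0, delay >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 lr_up = lr_up, lr_down = lr_down,
                 weight_decay = weight_decay, init_sd = init_sd,
                 delay = as.integer(delay), seed = seed, shuffle = shuffle,
                 monitor = monitor, literal_window = literal_window),
            class = "training_config")
}

#' Delay-response sequence loss
#'
#' The loss is the Kullback-Leibler divergence between the one-hot target
#' distribution and the predicted class distribution, accumulated only
#' over the supervised window — the final `d` steps of the sequence (the
#' appended black frames). With a one-hot target the per-step term reduces
#' to `-log(y[target, t])`; predicted probabilities are floored at 1e-12
#' inside the log. Steps before the window contribute exactly zero.
#'
#' Setting `literal_window = TRUE` supervises the `d + 1` steps satisfying
#' `T - t <= d` instead of the final `d` steps.
#'
#' @param y predicted class distributions, a classes x T matrix.
#' @param target target class index (1-based) or a one-hot vector.
#' @param d length of the supervised window; `1 <= d <= T`.
#' @param literal_window see above.
#' @return a `loss_ledger`: list with per-step errors `Et` (length T),
#'   logical `supervised` mask, total `E`, `T`, and `d`.
#' @export
sequence_loss <- function(y, target, d, literal_window = FALSE) {
  T_ <- ncol(y)
  C <- nrow(y)
  stopifnot(d >= 1, d <= T_)
  if (length(target) == 1L) {
    stopifnot(target >= 1, target <= C)
    cls <- as.integer(target)
  } else {
    stopifnot(length(target) == C, sum(target == 1) == 1L, all(target %in% c(0, 1)))
    cls <- which(target == 1)
  }
  t_ <- seq_len(T_)
  supervised <- if (literal_window) (T_ - t_) <= d else t_ > (T_ - d)
  Et <- numeric(T_)
  Et[supervised] <- -log(pmax(y[cls, supervised], 1e-12))
  structure(list(Et = Et, supervised = supervised, E = sum(Et),
                 T = T_, d = as.integer(d), class_index = cls),
            class = "loss_ledger")
}

#' Backpropagation through time
#'
#' Computes the exact gradient of the delay-response loss with respect to
#' every parameter, propagated backward through the leaky-integrator
#' recursion (the `1 - 1/tau` state carry), the scaled-tanh derivative,
#' the max-pooling argmax routing, and convolutional weight sharing
#' (kernel gradients sum over all spatial placements). The returned
#' gradients are normalized by the sequence length T.
#'
#' @param params an `mstnn_params`.
#' @param arch the matching `mstnn_arch`.
#' @param x an `mstnn_video` (already carrying its appended black frames)
#'   or a numeric array (rows, cols, T).
#' @param target target class (1-based); defaults to the video's label.
#' @param d supervised-window length.
#' @param literal_window see [sequence_loss()].
#' @return list with `grads` (shape-congruent with `params`), the
#'   `loss_ledger`, and the per-step output distributions `y`.
#' @export
bptt <- function(params, arch, x, target = NULL, d = 15L,
                 literal_window = FALSE) {
  frames <- if (inherits(x, "mstnn_video")) x$frames else x
  if (is.null(target)) {
    if (!inherits(x, "mstnn_video")) stop("target class required")
    target <- x$label
  }
  T_ <- dim(frames)[3L]
  stopifnot(d >= 1, d <= T_)
  plan <- arch_plan(arch)
  check_params(params, plan)
  stopifnot(target >= 1, target <= plan$classes)
  out <- .mstnn_bptt_cpp(frames, plan, unclass(params),
                         as.integer(target) - 1L, as.integer(d),
                         literal_window)
  t_ <- seq_len(T_)
  supervised <- if (literal_window) (T_ - t_) <= d else t_ > (T_ - d)
  ledger <- structure(list(Et = out$Et, supervised = supervised, E = out$E,
                           T = T_, d = as.integer(d),
                           class_index = as.integer(target)),
                      class = "loss_ledger")
  list(grads = out$grads, loss = ledger, y = out$y)
}

#' Adaptive learning-rate rule
#'
#' After each epoch the monitored error is compared with the previous
#' epoch's: a strict decrease multiplies the learning rate by `up`
#' (default 1.05); anything else — including an exact tie — divides it by
#' `down` (default 2).
#'
#' @param alpha current learning rate.
#' @param error_prev,error_this monitored errors of the previous and
#'   current epoch.
#' @param up,down adaptation factors.
#' @return the new learning rate.
#' @export
adapt_learning_rate <- function(alpha, error_prev, error_this,
                                up = 1.05, down = 2) {
  stopifnot(alpha > 0)
  if (is.finite(error_prev) && error_this < error_prev) alpha * up
  else alpha / down
}

#' Train a network by stochastic gradient descent
#'
#' Runs the full training loop: parameters are initialized from the
#' config seed (unless supplied), sequences are presented one at a time in
#' a freshly shuffled order each epoch, each presentation applies one
#' gradient step, and the learning rate is adapted after every epoch from
#' the monitored epoch error. Every sequence must already carry its `d`
#' appended black frames (see [append_black_frames()]).
#'
#' @param dataset list of `mstnn_video` objects sharing frame dimensions;
#'   labels must lie in `1..classes`.
#' @param arch an `mstnn_arch`.
#' @param config a [training_config()].
#' @param params optional starting `mstnn_params` (skips initialization).
#' @param eval_data optional held-out list of `mstnn_video`; when given,
#'   test accuracy is recorded after every epoch.
#' @param verbose print a one-line summary per epoch.
#' @return an `mstnn_fit`: list with the final `params`, `arch`, `config`,
#'   and a per-epoch `log` data frame (epoch, mean_error, mean_kl,
#'   learning_rate, train_accuracy, and test_accuracy if `eval_data` was
#'   given).
#' @export
train_mstnn <- function(dataset, arch, config = training_config(),
                        params = NULL, eval_data = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty training set")
  plan <- arch_plan(arch)
  labs <- vapply(dataset, function(s) s$label, numeric(1))
  if (any(labs < 1 | labs > plan$classes))
    stop("labels must lie in 1..", plan$classes)
  d <- config$delay
  if (is.null(params))
    params <- initialize_parameters(arch, config$init_sd, config$seed)

  n <- length(dataset)
  log_rows <- vector("list", config$epochs)
  alpha <- config$learning_rate
  prev_err <- NA_real_

  with_seed(derive_seed(config$seed, "shuffle"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- if (config$shuffle) sample.int(n) else seq_len(n)
      mon <- kl <- correct <- 0
      for (i in ord) {
        seq_i <- dataset[[i]]
        res <- bptt(params, arch, seq_i, d = d,
                    literal_window = config$literal_window)
        if (!is.finite(res$loss$E))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", sequence ", i)
        params <- apply_update(params, res$grads, alpha, config$weight_decay)
        sup <- res$loss$supervised
        ystar <- numeric(plan$classes); ystar[seq_i$label] <- 1
        mon <- mon + mean((res$y[, sup, drop = FALSE] - ystar)^2)
        kl <- kl + res$loss$E / sum(sup)
        pred <- vote_window(res$y, sup)
        correct <- correct + (pred == seq_i$label)
      }
      epoch_err <- if (config$monitor == "mse") mon / n else kl / n
      test_acc <- if (!is.null(eval_data))
        evaluate_accuracy(params, arch, eval_data, d = d) else NA_real_
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, mean_error = epoch_err, mean_kl = kl / n,
        learning_rate = alpha, train_accuracy = correct / n,
        test_accuracy = test_acc)
      if (verbose)
        message(sprintf("epoch %3d  err %.5f  lr %.4g  train acc %.3f%s",
                        epoch, epoch_err, alpha, correct / n,
                        if (is.na(test_acc)) "" else
                          sprintf("  test acc %.3f", test_acc)))
      alpha <- adapt_learning_rate(alpha, prev_err, epoch_err,
                                   config$lr_up, config$lr_down)
      prev_err <- epoch_err
    }
  })

  log <- if (config$epochs > 0) do.call(rbind, log_rows) else
    data.frame(epoch = integer(), mean_error = numeric(),
               mean_kl = numeric(), learning_rate = numeric(),
               train_accuracy = numeric(), test_accuracy = numeric())
  if (is.null(eval_data)) log$test_accuracy <- NULL
  structure(list(params = params, arch = arch, config = config, log = log),
            class = "mstnn_fit")
}

#' @export
print.mstnn_fit <- function(x, ...) {
  cat("mstnn fit: ", nrow(x$log), " epochs\n", sep = "")
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final mean error %.5f, train accuracy %.3f\n",
                last$mean_error, last$train_accuracy))
    if (!is.null(x$log$test_accuracy))
      cat(sprintf("  best test accuracy %.3f (epoch %d)\n",
                  max(x$log$test_accuracy),
                  x$log$epoch[which.max(x$log$test_accuracy)]))
  }
  invisible(x)
}
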