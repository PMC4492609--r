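# majority vote over the supervised window of a y-trace (classes x T);
# ties broken by the larger summed probability, then the lower class index
vote_window <- function(y, supervised) {
  votes <- apply(y[, supervised, drop = FALSE], 2L, which.max)
  tab <- tabulate(votes, nbins = nrow(y))
  top <- which(tab == max(tab))
  if (length(top) == 1L) return(top)
  sums <- rowSums(y[, supervised, drop = FALSE])[top]
  top[order(-sums, top)][1L]
}

#' Classify one sequence by delay-response voting
#'
#' Runs the network over the whole sequence from the reset state and
#' predicts by majority voting over the per-step argmax classes on the
#' final `d` steps only (the black-frame window); earlier steps are never
#' read. Vote ties go to the class with the larger summed probability over
#' the window, then to the lower class index.
#'
#' @param params an `mstnn_params`.
#' @param arch the matching `mstnn_arch`.
#' @param seq an `mstnn_video` already carrying its `d` black frames.
#' @param d length of the voting window.
#' @return an `mstnn_episode`: list with `predicted`, `truth`, per-step
#'   `votes` over the window, and the full output trace `y`.
#' @export
classify_sequence <- function(params, arch, seq, d = 15L) {
  frames <- if (inherits(seq, "mstnn_video")) seq$frames else seq
  T_ <- dim(frames)[3L]
  if (d > T_) stop("voting window d = ", d, " exceeds sequence length ", T_)
  out <- forward_sequence(params, arch, frames)
  supervised <- seq_len(T_) > (T_ - d)
  votes <- apply(out$y[, supervised, drop = FALSE], 2L, which.max)
  structure(list(predicted = vote_window(out$y, supervised),
                 truth = if (inherits(seq, "mstnn_video")) seq$label else NA,
                 votes = votes, supervised = supervised, y = out$y),
            class = "mstnn_episode")
}

#' @export
print.mstnn_episode <- function(x, ...) {
  cat(sprintf("mstnn episode: predicted %d (truth %s), votes over %d steps: %s\n",
              x$predicted, x$truth, length(x$votes),
              paste(x$votes, collapse = " ")))
  invisible(x)
}

#' Classification accuracy on a dataset
#'
#' @param params,arch network to evaluate.
#' @param dataset list of `mstnn_video` (with black frames appended).
#' @param d voting-window length.
#' @return fraction of sequences whose majority-vote prediction equals
#'   their label.
#' @export
evaluate_accuracy <- function(params, arch, dataset, d = 15L) {
  ok <- vapply(dataset, function(s)
    classify_sequence(params, arch, s, d = d)$predicted == s$label,
    logical(1))
  mean(ok)
}

#' Leave-one-subject-out evaluation protocol
#'
#' The full protocol: for every seed and every leave-one-subject-out fold,
#' train on the remaining subjects and record test accuracy after each
#' epoch. The aggregate is computed in the fixed order: mean over folds,
#' then mean over seeds, then the maximum over epochs, rounded to one
#' decimal (in percent).
#'
#' @param dataset list of `mstnn_video` with black frames appended and at
#'   least two distinct subjects.
#' @param arch an `mstnn_arch`.
#' @param config a [training_config()]; its seed is replaced fold-wise by
#'   each entry of `seeds`.
#' @param seeds integer vector of training seeds.
#' @param verbose print per-fold progress.
#' @return an `mstnn_protocol`: list with the per-(fold, seed, epoch)
#'   accuracy `grid`, the per-epoch seed-averaged curve, the `aggregate`
#'   accuracy in percent, and the final trained `models` (one per
#'   fold x seed, each with its fold's test indices).
#' @export
run_protocol <- function(dataset, arch, config = training_config(),
                         seeds = 1L, verbose = FALSE) {
  stopifnot(length(seeds) >= 1)
  folds <- loso_splits(dataset)
  grid <- list()
  models <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- seed
    for (f in seq_along(folds)) {
      fit <- train_mstnn(dataset[folds[[f]]$train], arch, cfg,
                         eval_data = dataset[folds[[f]]$test])
      grid[[length(grid) + 1L]] <- data.frame(
        fold = f, subject = folds[[f]]$subject, seed = seed,
        epoch = fit$log$epoch, accuracy = fit$log$test_accuracy)
      models[[length(models) + 1L]] <- list(params = fit$params, fold = f,
                                            seed = seed,
                                            test = folds[[f]]$test)
      if (verbose)
        message(sprintf("seed %d fold %d (%s): best test acc %.3f", seed, f,
                        folds[[f]]$subject, max(fit$log$test_accuracy)))
    }
  }
  grid <- do.call(rbind, grid)
  agg <- protocol_aggregate(grid)
  structure(list(grid = grid, curve = agg$curve, aggregate = agg$aggregate,
                 models = models, d = config$delay),
            class = "mstnn_protocol")
}

# fixed aggregation order of the evaluation protocol: mean over folds,
# then mean over seeds, then max over epochs, rounded to one decimal (%)
protocol_aggregate <- function(grid) {
  per_fold <- stats::aggregate(accuracy ~ seed + epoch, grid, mean)
  per_seed <- stats::aggregate(accuracy ~ epoch, per_fold, mean)
  list(curve = per_seed, aggregate = round(100 * max(per_seed$accuracy), 1))
}

#' @export
print.mstnn_protocol <- function(x, ...) {
  cat(sprintf("mstnn protocol: %d folds x %d seeds x %d epochs\n",
              length(unique(x$grid$fold)), length(unique(x$grid$seed)),
              max(x$grid$epoch)))
  cat(sprintf("  aggregate recognition rate: %.1f%%\n", x$aggregate))
  invisible(x)
}

#' Occlusion robustness sweep
#'
#' Evaluates already-trained models on test sequences occluded by moving
#' vertical stripes of increasing width. No retraining and no
#' max-over-epochs selection is involved: each model classifies its own
#' test set at every width, and accuracies are averaged over models.
#'
#' @param models list of model records, each a list with `params` and
#'   `test` (indices into `dataset`) — e.g. the `models` element of an
#'   [run_protocol()] result, or hand-built records.
#' @param dataset the full (unoccluded) dataset the test indices refer to,
#'   black frames already appended.
#' @param arch the `mstnn_arch` the models were trained under.
#' @param widths bar widths in pixels (default 0, 5, ..., 40; width 0
#'   reproduces the unoccluded accuracy).
#' @param gap,speed stripe geometry, see [occlusion_spec()].
#' @param d voting-window length.
#' @return an accuracy-versus-width table: data frame with columns
#'   `width`, `model`, `accuracy`, plus the model-averaged curve as
#'   attribute `"curve"`.
#' @export
occlusion_sweep <- function(models, dataset, arch,
                            widths = seq(0L, 40L, by = 5L), gap = 5L,
                            speed = 2L, d = 15L) {
  rows <- list()
  for (w in widths) {
    if (w %% speed != 0)
      warning("bar width ", w, " is not a multiple of the stripe step ",
              speed, "; running anyway")
    occ <- occlusion_spec(w, gap = gap, speed = speed)
    for (m in seq_along(models)) {
      test <- lapply(dataset[models[[m]]$test], apply_occlusion, occ = occ)
      rows[[length(rows) + 1L]] <- data.frame(
        width = w, model = m,
        accuracy = evaluate_accuracy(models[[m]]$params, arch, test, d = d))
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "curve") <- stats::aggregate(accuracy ~ width, tab, mean)
  tab
}
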