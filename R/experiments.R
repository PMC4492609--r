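# Packaged benchmark experiments on the synthetic silhouette generator.
# These fix the study conditions (dataset sizes, sequence lengths, epochs)
# once, so that the same experiment is reproducible from the tests, the
# command line, and the acceptance script.

#' Order-discrimination experiment
#'
#' Trains the full temporal-hierarchy network and its all-tau-equal-1
#' (memoryless) ablation on the synthetic order-discrimination pair: two
#' classes whose sequences contain identical frames in opposite temporal
#' order, so per-frame appearance carries no class information. The
#' hierarchy can solve the task because its slow layer carries the
#' temporal context into the black-frame voting window; the memoryless
#' ablation sees only black input there and cannot exceed chance.
#'
#' @param n_per_class sequences per class (default 20).
#' @param epochs training epochs (default 30).
#' @param seed base seed for data, initialization and shuffling.
#' @param taus time constants of the temporal-hierarchy model.
#' @return list with `mstnn_accuracy` and `tau1_accuracy` (each the best
#'   training accuracy over epochs, in [0, 1]) and the two epoch logs.
#' @export
run_order_experiment <- function(n_per_class = 20L, epochs = 30L, seed = 1L,
                                 taus = c(2, 5, 100)) {
  data <- synthetic_order_dataset(n_per_class = n_per_class,
                                  seed = derive_seed(seed, "orderdata"))
  data <- lapply(data, append_black_frames, d = 15L)
  cfg <- training_config(epochs = epochs, seed = derive_seed(seed, "ordertrain"))
  arch <- default_architecture(classes = 2L, taus = taus)
  # training accuracy is measured on the end-of-epoch model (eval_data =
  # the training set), not on the running within-epoch predictions
  fit <- train_mstnn(data, arch, cfg, eval_data = data)
  arch1 <- set_time_constants(arch, c(1, 1, 1))
  fit1 <- train_mstnn(data, arch1, cfg, eval_data = data)
  list(mstnn_accuracy = max(fit$log$test_accuracy),
       tau1_accuracy = max(fit1$log$test_accuracy),
       mstnn_log = fit$log, tau1_log = fit1$log)
}

#' Occlusion-robustness experiment
#'
#' Trains networks on clean synthetic prototypical actions (a six-way
#' fine-grained set: slow and fast bounce, slow and fast one-hand wave,
#' two-hand wave, and sway, performed by nine subjects; six subjects for
#' training, three held out), then sweeps
#' moving-stripe occlusion of increasing bar width over the held-out
#' sequences using the previously trained models — no retraining. Reports
#' the seed-averaged accuracy-versus-width curve and its Spearman trend.
#' The class set is deliberately fine-grained: the slow/fast pairs
#' (period 24 versus 8 frames) differ only in oscillation frequency,
#' information that wide moving bars subsample badly, so occlusion has
#' headroom to degrade recognition instead of saturating at ceiling.
#'
#' @param n_seeds number of training seeds to average over (default 3).
#' @param epochs training epochs per seed (default 20).
#' @param widths bar widths in pixels (default 0, 5, ..., 40).
#' @param seed base seed.
#' @return list with the per-model `table`, the seed-averaged `curve`
#'   (width, accuracy), and the Spearman `rho` / `p_value` of accuracy
#'   against width.
#' @export
run_occlusion_experiment <- function(n_seeds = 3L, epochs = 20L,
                                     widths = seq(0L, 40L, by = 5L),
                                     seed = 1L) {
  base <- synthetic_action_dataset(
    archetypes = c("bounce", "bounce", "wave_one", "wave_one",
                   "wave_two", "sway"),
    periods = c(24L, 8L, 24L, 8L, 24L, 24L),
    n_subjects = 9L, seed = derive_seed(seed, "occdata"))
  data <- lapply(base, append_black_frames, d = 15L)
  subjects <- vapply(data, function(s) s$subject, character(1))
  train_idx <- which(subjects %in% sprintf("s%02d", 1:6))
  test_idx <- which(subjects %in% sprintf("s%02d", 7:9))
  arch <- default_architecture(classes = 6L)
  models <- lapply(seq_len(n_seeds), function(k) {
    cfg <- training_config(epochs = epochs,
                           seed = derive_seed(seed, "occtrain", k))
    fit <- train_mstnn(data[train_idx], arch, cfg)
    list(params = fit$params, test = test_idx, seed = k)
  })
  tab <- occlusion_sweep(models, data, arch, widths = widths)
  curve <- attr(tab, "curve")
  trend <- suppressWarnings(
    stats::cor.test(curve$width, curve$accuracy, method = "spearman",
                    alternative = "less", exact = FALSE))
  list(table = tab, curve = curve,
       rho = unname(trend$estimate), p_value = trend$p.value)
}

#' Contextual-memory experiment on concatenated actions
#'
#' Builds all nine ordered concatenations of the three synthetic
#' archetypes for six subjects (42 + 42 + 15 frames each), trains on four
#' subjects and tests on two, once with the full temporal hierarchy (top
#' tau = 100) and once with the top time constant reduced to `tau_low`.
#' On the tau = 100 model it also measures (a) the mean per-step
#' activation change of the slow versus the fast conv layer on the test
#' sequences, and (b) a linear readout of the slow layer's final-step
#' state predicting the FIRST action on the held-out subjects (with the
#' middle layer's state at the end of the second action as contrast).
#'
#' @param epochs training epochs (default 30).
#' @param tau_low reduced top time constant (default 20).
#' @param seed base seed.
#' @param n_subjects,n_train_subjects synthetic subject counts.
#' @return list with `acc_tau_high` / `acc_tau_low` (best-epoch held-out
#'   accuracies), `fast_change` / `slow_change` (mean per-step activation
#'   change of conv layers 1 and 3), and `readout_slow` / `readout_mid`
#'   (first-action readout accuracies from the slow final-step and middle
#'   end-of-second-action snapshots).
#' @export
run_concatenation_experiment <- function(epochs = 30L, tau_low = 20,
                                         seed = 1L, n_subjects = 6L,
                                         n_train_subjects = 4L) {
  base <- synthetic_action_dataset(n_subjects = n_subjects,
                                   seed = derive_seed(seed, "concdata"))
  data <- concatenated_dataset(base) # 42 + 42 + 15 frames, 9 categories
  subjects <- vapply(data, function(s) s$subject, character(1))
  train_subj <- sprintf("s%02d", seq_len(n_train_subjects))
  train_idx <- which(subjects %in% train_subj)
  test_idx <- which(!subjects %in% train_subj)
  arch <- default_architecture(classes = 9L)
  cfg <- training_config(epochs = epochs,
                         seed = derive_seed(seed, "conctrain"))

  fit_hi <- train_mstnn(data[train_idx], arch, cfg,
                        eval_data = data[test_idx])
  fit_lo <- train_mstnn(data[train_idx], set_top_tau(arch, tau_low), cfg,
                        eval_data = data[test_idx])

  params <- fit_hi$params
  fast_change <- mean(vapply(data[test_idx], function(s)
    activation_change(params, arch, s, conv = 1L), numeric(1)))
  slow_change <- mean(vapply(data[test_idx], function(s)
    activation_change(params, arch, s, conv = 3L), numeric(1)))

  T_full <- dim(data[[1L]]$frames)[3L]       # 99 with the defaults
  t_second <- T_full - 15L                   # end of the second action
  first <- vapply(data, function(s) s$first_label, integer(1))
  slow_tr <- snapshot_matrix(params, arch, data[train_idx], T_full, conv = 3L)
  slow_te <- snapshot_matrix(params, arch, data[test_idx], T_full, conv = 3L)
  mid_tr <- snapshot_matrix(params, arch, data[train_idx], t_second, conv = 2L)
  mid_te <- snapshot_matrix(params, arch, data[test_idx], t_second, conv = 2L)
  # identical preprocessing for both layers: project onto the leading
  # principal components of the training snapshots before the readout
  reduce <- function(tr, te, k = 20L) {
    p <- stats::prcomp(tr, center = TRUE, scale. = FALSE, rank. = k)
    list(tr = p$x, te = predict(p, te))
  }
  rs <- reduce(slow_tr, slow_te)
  rm_ <- reduce(mid_tr, mid_te)
  readout_slow <- snapshot_readout(rs$tr, first[train_idx],
                                   rs$te, first[test_idx])
  readout_mid <- snapshot_readout(rm_$tr, first[train_idx],
                                  rm_$te, first[test_idx])

  list(acc_tau_high = max(fit_hi$log$test_accuracy),
       acc_tau_low = max(fit_lo$log$test_accuracy),
       fast_change = fast_change, slow_change = slow_change,
       readout_slow = readout_slow, readout_mid = readout_mid,
       log_tau_high = fit_hi$log, log_tau_low = fit_lo$log,
       data = list(train = train_idx, test = test_idx, first = first))
}
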