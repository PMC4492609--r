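test_that("the delay-response loss obeys its closed-form identities", {
  C <- 10L; T_ <- 99L; d <- 15L
  # uniform prediction: each supervised step contributes ln C
  y_unif <- matrix(1 / C, C, T_)
  led <- sequence_loss(y_unif, target = 3L, d = d)
  expect_equal(led$E, d * log(C), tolerance = 1e-12)
  expect_equal(sum(led$supervised), d)
  expect_true(all(led$Et[seq_len(T_ - d)] == 0))
  # prediction equal to the target at every supervised step: zero loss
  y_hit <- y_unif
  y_hit[, (T_ - d + 1):T_] <- 0
  y_hit[3, (T_ - d + 1):T_] <- 1
  expect_equal(sequence_loss(y_hit, 3L, d)$E, 0)
  expect_true(sequence_loss(matrix(runif(C * T_), C), 1L, d)$E >= 0)
  # one-hot vector targets are accepted
  tgt <- numeric(C); tgt[3] <- 1
  expect_equal(sequence_loss(y_unif, tgt, d)$E, led$E)
})

test_that("the loss reads only the supervised window", {
  set.seed(40)
  y <- matrix(rexp(5 * 30), 5, 30)
  y <- sweep(y, 2, colSums(y), "/")
  led <- sequence_loss(y, 4L, d = 6)
  y2 <- y
  y2[, !led$supervised] <- 1 / 5 # scramble everything outside the window
  expect_equal(sequence_loss(y2, 4L, d = 6)$E, led$E, tolerance = 1e-12)
})

test_that("the literal window variant supervises d + 1 steps", {
  y <- matrix(0.5, 2, 20)
  expect_equal(sum(sequence_loss(y, 1L, 5)$supervised), 5)
  expect_equal(sum(sequence_loss(y, 1L, 5, literal_window = TRUE)$supervised), 6)
})

test_that("collapsed output probabilities are floored, not -Inf", {
  y <- matrix(1e-300, 2, 4)
  y[2, ] <- 1 - 1e-300
  led <- sequence_loss(y, 1L, 2)
  expect_true(all(is.finite(led$Et)))
  expect_equal(led$E, -2 * log(1e-12), tolerance = 1e-6)
})

test_that("updates decay weights but never biases", {
  arch <- tiny_arch()
  p <- initialize_parameters(arch, seed = 2)
  zero <- list(kernels = lapply(p$kernels, function(k) array(0, dim(k))),
               kbias = lapply(p$kbias, function(b) 0 * b),
               W = 0 * p$W, wbias = 0 * p$wbias)
  alpha <- 0.3
  up <- apply_update(p, zero, alpha)
  for (i in seq_along(p$kernels)) {
    expect_equal(up$kernels[[i]], p$kernels[[i]] * (1 - alpha * 5e-4),
                 tolerance = 1e-14)
    expect_identical(up$kbias[[i]], p$kbias[[i]])
  }
  expect_equal(up$W, p$W * (1 - alpha * 5e-4), tolerance = 1e-14)
  expect_identical(up$wbias, p$wbias)
  # alpha = 0 leaves everything untouched
  expect_equal(apply_update(p, zero, 0), p)
  # scalar arithmetic: k = 1, grad = 0.2, alpha = 0.1
  p1 <- p; p1$kernels[[1]][1] <- 1
  g1 <- zero; g1$kernels[[1]][1] <- 0.2
  expect_equal(apply_update(p1, g1, 0.1)$kernels[[1]][1],
               1 - 0.1 * (0.2 + 5e-4 * 1), tolerance = 1e-14)
})

test_that("the learning rate adapts multiplicatively on the epoch error", {
  expect_equal(adapt_learning_rate(0.1, 1.0, 0.9), 0.105)
  expect_equal(adapt_learning_rate(0.1, 0.9, 1.0), 0.05)
  expect_equal(adapt_learning_rate(0.1, 1.0, 1.0), 0.05) # tie = no improvement
})

test_that("parameter initialization is seeded, Gaussian, and reproducible", {
  arch <- tiny_arch()
  p1 <- initialize_parameters(arch, seed = 11)
  p2 <- initialize_parameters(arch, seed = 11)
  p3 <- initialize_parameters(arch, seed = 12)
  expect_identical(p1, p2)
  expect_false(identical(p1$kernels[[1]], p3$kernels[[1]]))
  # moments of a large draw
  big <- mstnn_architecture(input_layer(300, 340), conv_layer(1, c(300, 334), 1),
                            output_layer(2))
  w <- as.vector(initialize_parameters(big, sigma = 0.05, seed = 1)$kernels[[1]])
  n <- length(w)
  expect_gt(n, 1e5)
  expect_lt(abs(mean(w)), 3 * 0.05 / sqrt(n))
  expect_lt(abs(sd(w) - 0.05) / 0.05, 0.02)
})

test_that("backpropagation through time matches central finite differences", {
  set.seed(20)
  for (i in 1:5) {
    arch <- rand_tiny_arch()
    plan <- mstnn:::arch_plan(arch)
    p <- initialize_parameters(arch, sigma = 0.2, seed = 100 + i)
    T_ <- sample(3:6, 1)
    frames <- rand_frames(plan$in_rows, plan$in_cols, T_)
    d <- sample(seq_len(T_ - 1), 1)
    target <- sample(plan$classes, 1)
    g <- bptt(p, arch, frames, target = target, d = d)
    ga <- bptt_gradient_flat(g$grads)
    gn <- numeric_gradient(p, arch, frames, target, d)
    rel <- max(abs(ga - gn)) / max(max(abs(gn)), 1e-8)
    expect_lt(rel, 1e-4)
  }
})

test_that("gradient normalization divides by the full sequence length", {
  # with memoryless units, frames prepended ahead of the supervised window
  # leave the raw gradient unchanged, so doubling T exactly halves the
  # normalized gradient
  arch <- mstnn_architecture(
    input_layer(7, 7), conv_layer(2, c(3, 3), tau = 1),
    output_layer(2))
  p <- initialize_parameters(arch, seed = 3)
  set.seed(33)
  frames <- rand_frames(7, 7, 4)
  doubled <- array(c(rand_frames(7, 7, 4), frames), c(7, 7, 8))
  g1 <- bptt_gradient_flat(bptt(p, arch, frames, target = 1, d = 2)$grads)
  g2 <- bptt_gradient_flat(bptt(p, arch, doubled, target = 1, d = 2)$grads)
  expect_equal(g2, g1 / 2, tolerance = 1e-12)
})

test_that("training solves a linearly separable static-frame toy", {
  arch <- mstnn_architecture(
    input_layer(6, 6), conv_layer(2, c(3, 3), tau = 2),
    pool_layer(2), output_layer(2))
  set.seed(5)
  mk <- function(label) {
    f <- matrix(0, 6, 6)
    if (label == 1) f[1:3, ] <- 1 else f[4:6, ] <- 1
    video_sequence(array(rep(f, 8), c(6, 6, 8)), label, paste0("s", label),
                   tag = "synthetic")
  }
  data <- lapply(rep(1:2, each = 4), mk)
  data <- lapply(data, append_black_frames, d = 3)
  cfg <- training_config(epochs = 40, delay = 3, seed = 7)
  fit <- train_mstnn(data, arch, cfg)
  expect_lt(fit$log$mean_error[40], 0.05)
  expect_equal(fit$log$train_accuracy[40], 1)
  expect_lt(min(fit$log$mean_kl), 0.2)
})

test_that("zero epochs return the initialization unchanged and logs are well-formed", {
  arch <- tiny_arch(classes = 2)
  data <- list(append_black_frames(
    video_sequence(rand_frames(9, 9, 4), 1, "a"), d = 2))
  cfg <- training_config(epochs = 0, delay = 2, seed = 1)
  fit <- train_mstnn(data, arch, cfg)
  expect_equal(fit$params, initialize_parameters(arch, cfg$init_sd, cfg$seed))
  expect_equal(nrow(fit$log), 0)
  # identical config and seed give identical epoch logs
  cfg2 <- training_config(epochs = 3, delay = 2, seed = 9)
  f1 <- train_mstnn(data, arch, cfg2)
  f2 <- train_mstnn(data, arch, cfg2)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
})
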