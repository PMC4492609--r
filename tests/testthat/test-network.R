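test_that("scaled tanh has the expected shape, scale and asymptote", {
  expect_equal(scaled_tanh(0), 0)
  expect_equal(scaled_tanh(1e6), 1.7159, tolerance = 1e-12)
  expect_equal(scaled_tanh(-1e6), -1.7159, tolerance = 1e-12)
  expect_equal(scaled_tanh(1.5), 1.7159 * tanh(1), tolerance = 1e-12)
  x <- seq(-5, 5, by = 0.1)
  expect_true(all(abs(scaled_tanh(x)) < 1.7159))
})

test_that("leaky integration follows the decay/drive balance", {
  set.seed(1)
  k <- array(rnorm(3 * 3 * 1 * 2, 0, 0.1), c(3, 3, 1, 2))
  b <- rnorm(2, 0, 0.1)
  x <- array(runif(6 * 6), c(6, 6, 1))
  u_prev <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  # tau = 1: the state is replaced by the drive (no memory)
  drive <- sweep(mstnn:::cross_correlate(x, k), 3, b, "+")
  st <- leaky_integrate_conv(u_prev, x, k, b, tau = 1)
  expect_equal(st$u, drive, tolerance = 1e-12)
  # tau = 2, zero drive: the state halves
  st2 <- leaky_integrate_conv(u_prev, x, 0 * k, 0 * b, tau = 2)
  expect_equal(st2$u, u_prev / 2, tolerance = 1e-12)
  expect_equal(st2$v, scaled_tanh(u_prev / 2), tolerance = 1e-12)
})

test_that("constant drive follows the closed form u_t = z + (1-1/tau)^t (u_0 - z)", {
  z <- 0.8
  for (tau in c(1, 2, 5, 100)) {
    k <- array(0, c(2, 2, 1, 1))
    x <- array(0, c(5, 5, 1))
    u <- array(0, c(4, 4, 1)) # u_0 = 0
    for (t in 1:30) {
      u <- leaky_integrate_conv(u, x, k, b = z, tau = tau)$u
      expect_equal(u[1, 1, 1], z + (1 - 1 / tau)^t * (0 - z), tolerance = 1e-10)
    }
    expect_equal(max(abs(u - z)), 0, tolerance = if (tau > 20) 1 else 1e-3)
  }
})

test_that("max pooling takes window maxima and records argmax positions", {
  m <- matrix(c(1, 3, 2, 4), 2, 2) # column-major: [[1,2],[3,4]]
  p <- max_pool(array(m, c(2, 2, 1)), 2)
  expect_equal(as.vector(p$values), 4)
  expect_equal(as.vector(p$argmax), which.max(m))
  const <- array(0.7, c(4, 4, 2))
  expect_true(all(max_pool(const, 2)$values == 0.7))
  # pooling commutes with any monotone increasing pointwise map
  set.seed(7)
  for (i in 1:10) {
    v <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
    expect_equal(max_pool(exp(v), 2)$values, exp(max_pool(v, 2)$values),
                 tolerance = 1e-12)
  }
  expect_error(max_pool(array(0, c(5, 5, 1)), 2), "does not divide")
})

test_that("the output head is a plain affine map checked against a double loop", {
  set.seed(2)
  v <- array(rnorm(12), c(2, 2, 3))
  W <- matrix(rnorm(4 * 12), 4, 12)
  b <- rnorm(4)
  s <- output_internal_states(v, W, b)
  naive <- numeric(4)
  vf <- as.vector(v)
  for (cc in 1:4) {
    acc <- b[cc]
    for (j in 1:12) acc <- acc + W[cc, j] * vf[j]
    naive[cc] <- acc
  }
  expect_equal(s, naive, tolerance = 1e-12)
  expect_equal(output_internal_states(v, 0 * W, 0 * b), numeric(4))
  expect_error(output_internal_states(v, W[, 1:5], b), "expect")
})

test_that("softmax is a proper, shift-invariant distribution", {
  expect_equal(softmax(rep(3, 10)), rep(0.1, 10))
  expect_equal(softmax(c(1, 0)), c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  s <- rnorm(5)
  expect_equal(softmax(s + 100), softmax(s), tolerance = 1e-12)
  expect_equal(sum(softmax(s * 50)), 1, tolerance = 1e-9)
})

test_that("reset state is all zeros and episodes are independent", {
  arch <- tiny_arch()
  st <- reset_state(arch)
  expect_true(all(vapply(st$u, function(u) all(u == 0), logical(1))))
  expect_equal(st$t, 0L)
  expect_identical(reset_state(arch), reset_state(arch))
  # forward after reset does not depend on a previous episode
  p <- initialize_parameters(arch, seed = 5)
  set.seed(9)
  f1 <- matrix(runif(81), 9, 9)
  out_a <- forward_step(reset_state(arch), p, f1, arch)
  prior <- forward_step(reset_state(arch), p, matrix(runif(81), 9, 9), arch)
  out_b <- forward_step(reset_state(arch), p, f1, arch)
  expect_equal(out_a$y, out_b$y, tolerance = 1e-14)
})

test_that("zero parameters give a uniform class distribution at every step", {
  arch <- tiny_arch(classes = 4)
  p <- initialize_parameters(arch, seed = 1)
  for (i in seq_along(p$kernels)) { p$kernels[[i]][] <- 0; p$kbias[[i]][] <- 0 }
  p$W[] <- 0; p$wbias[] <- 0
  out <- forward_sequence(p, arch, rand_frames(9, 9, 4))
  expect_true(all(abs(out$y - 0.25) < 1e-14))
})

test_that("the compiled and per-step reference engines agree to near machine precision", {
  set.seed(3)
  for (i in 1:5) {
    arch <- rand_tiny_arch()
    plan <- mstnn:::arch_plan(arch)
    p <- initialize_parameters(arch, seed = i)
    frames <- rand_frames(plan$in_rows, plan$in_cols, 5)
    a <- forward_sequence(p, arch, frames, engine = "cpp", record = TRUE)
    b <- forward_sequence(p, arch, frames, engine = "r", record = TRUE)
    expect_equal(a$y, b$y, tolerance = 1e-12)
    expect_equal(a$s, b$s, tolerance = 1e-12)
    for (j in seq_along(a$v)) expect_equal(a$v[[j]], b$v[[j]], tolerance = 1e-12)
  }
})

test_that("activations stay inside the scaled-tanh range and outputs normalize", {
  set.seed(4)
  arch <- tiny_arch()
  p <- initialize_parameters(arch, sigma = 0.5, seed = 8) # deliberately hot
  out <- forward_sequence(p, arch, rand_frames(9, 9, 12), record = TRUE)
  for (v in out$v) expect_true(all(abs(v) <= 1.7159))
  expect_equal(colSums(out$y), rep(1, 12), tolerance = 1e-9)
  expect_true(all(out$y > 0))
})
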