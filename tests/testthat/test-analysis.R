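test_that("activation traces have the right shape, bounds, and determinism", {
  arch <- default_architecture(classes = 3)
  p <- initialize_parameters(arch, seed = 6)
  v <- append_black_frames(
    generate_synthetic_action("bounce", length = 10, seed = 2), 5)
  tr <- record_activations(p, arch, v, conv = 1L)[[1]]
  expect_equal(dim(tr), c(6 * 40 * 40, 15)) # 9600 layer-1 units x T
  expect_true(all(abs(tr) <= 1.7159))
  expect_equal(attr(tr, "tau"), 2)
  # seeded subsampling
  tr40 <- record_activations(p, arch, v, conv = 1L, units = 40, seed = 3)[[1]]
  expect_equal(nrow(tr40), 40)
  tr40b <- record_activations(p, arch, v, conv = 1L, units = 40, seed = 3)[[1]]
  expect_identical(tr40, tr40b)
  expect_true(all(tr40 == tr[rownames(tr40), ]))
  expect_error(record_activations(p, arch, v, conv = 9L), "out of range")
})

test_that("snapshot PCA matches an independent eigendecomposition", {
  set.seed(17)
  arch <- tiny_arch(classes = 2)
  p <- initialize_parameters(arch, seed = 1)
  data <- lapply(1:8, function(i)
    video_sequence(rand_frames(9, 9, 6), 1, paste0("s", i)))
  emb <- snapshot_pca(p, arch, data, step = 6, conv = 2, n_components = 2)
  X <- snapshot_matrix(p, arch, data, step = 6, conv = 2)
  # oracle: eigendecomposition of the covariance of centered snapshots
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(Xc))
  scores <- Xc %*% eig$vectors[, 1:2]
  for (j in 1:2) {
    agree <- min(max(abs(emb$scores[, j] - scores[, j])),
                 max(abs(emb$scores[, j] + scores[, j]))) # sign-free
    expect_lt(agree, 1e-8)
  }
  expect_equal(emb$explained[1:2],
               (eig$values / sum(eig$values))[1:2], tolerance = 1e-8)
  expect_true(emb$explained[1] >= emb$explained[2])
})

test_that("degenerate snapshot geometries are handled", {
  arch <- tiny_arch(classes = 2)
  p <- initialize_parameters(arch, seed = 1)
  same <- video_sequence(array(0.5, c(9, 9, 4)), 1, "s")
  expect_warning(
    emb <- snapshot_pca(p, arch, list(same, same, same), step = 4, conv = 2),
    "identical")
  expect_true(all(emb$scores == 0))
  expect_error(snapshot_pca(p, arch, list(same, same), step = 4, conv = 2),
               "at least 3")
})

test_that("nested-cluster scores separate coarse from fine structure", {
  set.seed(8)
  # three coarse clusters far apart, each with three looser sub-clusters
  centers2 <- matrix(c(0, 0, 100, 0, 50, 100), 3, 2, byrow = TRUE)
  offs <- matrix(c(-2, 0, 2, 0, 0, 2), 3, 2, byrow = TRUE)
  pts <- do.call(rbind, lapply(1:3, function(g)
    do.call(rbind, lapply(1:3, function(s)
      sweep(matrix(rnorm(10, 0, 0.3), 5, 2), 2,
            centers2[g, ] + offs[s, ], "+")))))
  second <- rep(1:3, each = 15)
  first <- rep(rep(1:3, each = 5), 3)
  res <- cluster_structure_summary(pts, first, second)
  expect_true(res$nested)
  expect_gt(res$coarse, res$fine)
  expect_gt(res$fine, 0)
  # shuffled labels collapse the scores toward zero
  perm <- replicate(100, {
    r <- cluster_structure_summary(pts, sample(first), sample(second))
    c(r$coarse, r$fine)
  })
  expect_lt(abs(mean(perm[1, ])), 0.25)
  expect_lt(abs(mean(perm[2, ])), 0.25)
  expect_gt(res$coarse, max(perm[1, ])) # real structure beats every shuffle
  # no sub-structure inside coarse groups: fine score near zero
  flat <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(30, 0, 0.5), 15, 2), 2, centers2[g, ], "+")))
  res_flat <- cluster_structure_summary(flat, first, second)
  expect_lt(res_flat$fine, 0.2)
  expect_error(cluster_structure_summary(pts, rep(1, 45), second), "2 groups")
})

test_that("the linear snapshot readout learns separable labels", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
  y <- rep(1:2, each = 20)
  idx <- c(1:15, 21:35)
  acc <- snapshot_readout(x[idx, ], y[idx], x[-idx, ], y[-idx])
  expect_gt(acc, 0.9)
})

test_that("the ablation grid trains one model per tau and logs every epoch", {
  arch <- tiny_arch(classes = 2, taus = c(1, 2))
  set.seed(12)
  mk <- function(label, subject) {
    append_black_frames(
      video_sequence(rand_frames(9, 9, 4), label, subject), 2)
  }
  train <- list(mk(1, "a"), mk(2, "a"))
  test <- list(mk(1, "b"), mk(2, "b"))
  cfg <- training_config(epochs = 2, delay = 2, seed = 1)
  tab <- time_constant_ablation(train, test, arch, cfg, tau_top = c(8, 2),
                                seeds = 1)
  expect_equal(nrow(tab), 4) # 2 taus x 2 epochs
  expect_equal(sort(unique(tab$tau)), c(2, 8))
  expect_equal(nrow(attr(tab, "summary")), 2)
  expect_error(time_constant_ablation(train, test, arch, cfg, tau_top = 0.5),
               ">= 1")
  # the default grid spans 100 down to 20 in steps of 20
  expect_equal(eval(formals(time_constant_ablation)$tau_top),
               c(100, 80, 60, 40, 20))
})
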