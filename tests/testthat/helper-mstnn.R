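# Shared test helpers: tiny architectures, a finite-difference gradient
# oracle, and an independent naive static-CNN oracle (explicit loops, no
# shared code with the package internals beyond the public API).

tiny_arch <- function(classes = 3L, taus = c(2, 5)) {
  mstnn_architecture(
    input_layer(9, 9),
    conv_layer(2, c(4, 4), tau = taus[1]),
    pool_layer(2),
    conv_layer(3, c(2, 2), tau = taus[2]),
    output_layer(classes))
}

rand_frames <- function(rows, cols, T_) {
  array(runif(rows * cols * T_), c(rows, cols, T_))
}

# random small-but-valid architecture for gradient checking
rand_tiny_arch <- function(taus_pool = c(1, 2, 5, 100)) {
  depth <- sample(1:2, 1)
  rows <- sample(6:9, 1); cols <- sample(6:9, 1)
  t1 <- sample(taus_pool, 1)
  k1 <- sample(2:3, 1)
  layers <- list(input_layer(rows, cols),
                 conv_layer(sample(2:3, 1), c(k1, k1), tau = t1))
  r <- rows - k1 + 1; cc <- cols - k1 + 1
  if (r %% 2 == 0 && cc %% 2 == 0 && runif(1) < 0.5) {
    layers <- c(layers, list(pool_layer(2)))
    r <- r / 2; cc <- cc / 2
  }
  if (depth == 2 && r >= 3 && cc >= 3) {
    cand <- taus_pool[taus_pool >= t1]
    t2 <- cand[sample.int(length(cand), 1)]
    layers <- c(layers, list(conv_layer(2, c(2, 2), tau = t2)))
  }
  layers <- c(layers, list(output_layer(sample(2:3, 1))))
  mstnn_architecture(layers)
}

# loss used by the finite-difference oracle (matches bptt's normalization)
seq_loss_of <- function(params, arch, frames, target, d) {
  y <- forward_sequence(params, arch, frames)$y
  sequence_loss(y, target, d)$E / dim(frames)[3]
}

# central finite differences over every parameter; returns flat vector
numeric_gradient <- function(params, arch, frames, target, d, h = 1e-5) {
  getset <- param_accessors(params)
  unlist(lapply(getset, function(gs) {
    v0 <- gs$get(params)
    vapply(seq_along(v0), function(i) {
      v <- v0; v[i] <- v0[i] + h
      e1 <- seq_loss_of(gs$set(params, v), arch, frames, target, d)
      v[i] <- v0[i] - h
      e2 <- seq_loss_of(gs$set(params, v), arch, frames, target, d)
      (e1 - e2) / (2 * h)
    }, numeric(1))
  }))
}

bptt_gradient_flat <- function(grads) {
  c(unlist(lapply(grads$kernels, as.vector)), unlist(grads$kbias),
    as.vector(grads$W), grads$wbias)
}

param_accessors <- function(params) {
  acc <- list()
  for (i in seq_along(params$kernels)) {
    local({
      ii <- i
      acc[[length(acc) + 1L]] <<- list(
        get = function(p) as.vector(p$kernels[[ii]]),
        set = function(p, v) { p$kernels[[ii]][] <- v; p })
    })
  }
  for (i in seq_along(params$kbias)) {
    local({
      ii <- i
      acc[[length(acc) + 1L]] <<- list(
        get = function(p) p$kbias[[ii]],
        set = function(p, v) { p$kbias[[ii]] <- v; p })
    })
  }
  acc[[length(acc) + 1L]] <- list(get = function(p) as.vector(p$W),
                                  set = function(p, v) { p$W[] <- v; p })
  acc[[length(acc) + 1L]] <- list(get = function(p) p$wbias,
                                  set = function(p, v) { p$wbias <- v; p })
  acc
}

# ---- independent static per-frame CNN oracle (naive explicit loops) ----
# Forward: conv -> tanh -> (pool) -> conv -> ... -> affine -> softmax,
# one frame at a time, no temporal state. Backward: plain per-frame
# backprop. Used to check the tau = 1 degeneracy of the recurrent model.

oracle_conv <- function(x, k, b) {
  dk <- dim(k); dx <- dim(x)
  orows <- dx[1] - dk[1] + 1; ocols <- dx[2] - dk[2] + 1
  out <- array(0, c(orows, ocols, dk[4]))
  for (m in seq_len(dk[4])) for (r in seq_len(orows)) for (cl in seq_len(ocols)) {
    acc <- b[m]
    for (n in seq_len(dk[3])) for (dr in seq_len(dk[1])) for (dc in seq_len(dk[2]))
      acc <- acc + k[dr, dc, n, m] * x[r + dr - 1, cl + dc - 1, n]
    out[r, cl, m] <- acc
  }
  out
}

oracle_pool <- function(v, p) {
  d <- dim(v)
  pr <- d[1] / p; pc <- d[2] / p
  out <- array(0, c(pr, pc, d[3]))
  win <- array(0L, c(pr, pc, d[3], 2))
  for (m in seq_len(d[3])) for (i in seq_len(pr)) for (j in seq_len(pc)) {
    rs <- ((i - 1) * p + 1):(i * p); cs <- ((j - 1) * p + 1):(j * p)
    w <- v[rs, cs, m]
    bi <- which(w == max(w), arr.ind = TRUE)[1, ]
    out[i, j, m] <- max(w)
    win[i, j, m, ] <- c(rs[bi[1]], cs[bi[2]])
  }
  list(values = out, where = win)
}

oracle_static_forward <- function(frame, arch, params) {
  plan <- mstnn:::arch_plan(arch)
  x <- array(frame, c(dim(frame), 1L))
  acts <- list()
  for (i in seq_along(plan$blocks)) {
    b <- plan$blocks[[i]]
    u <- oracle_conv(x, params$kernels[[i]], params$kbias[[i]])
    v <- 1.7159 * tanh((2 / 3) * u)
    pooled <- if (b$pool > 1) oracle_pool(v, b$pool) else NULL
    acts[[i]] <- list(u = u, v = v, pooled = pooled)
    x <- if (b$pool > 1) pooled$values else v
  }
  s <- as.vector(params$W %*% as.vector(x) + params$wbias)
  e <- exp(s - max(s))
  list(acts = acts, s = s, y = e / sum(e), top = x)
}

# gradient of -log(y[target]) for ONE frame through the static network
oracle_static_grad <- function(frame, arch, params, target) {
  plan <- mstnn:::arch_plan(arch)
  fw <- oracle_static_forward(frame, arch, params)
  ds <- fw$y; ds[target] <- ds[target] - 1
  gW <- outer(ds, as.vector(fw$top))
  gwb <- ds
  dtop <- array(as.vector(t(params$W) %*% ds), dim(fw$top))
  gk <- list(); gb <- list()
  dout <- dtop
  for (i in rev(seq_along(plan$blocks))) {
    b <- plan$blocks[[i]]
    a <- fw$acts[[i]]
    dv <- if (b$pool > 1) {
      tmp <- array(0, dim(a$v))
      for (m in seq_len(dim(dout)[3])) for (ii in seq_len(dim(dout)[1]))
        for (jj in seq_len(dim(dout)[2])) {
          w <- a$pooled$where[ii, jj, m, ]
          tmp[w[1], w[2], m] <- tmp[w[1], w[2], m] + dout[ii, jj, m]
        }
      tmp
    } else dout
    du <- dv * (2 / 3) * (1.7159 - a$v^2 / 1.7159)
    xin <- if (i == 1) array(frame, c(dim(frame), 1L)) else {
      bb <- plan$blocks[[i - 1]]
      if (bb$pool > 1) fw$acts[[i - 1]]$pooled$values else fw$acts[[i - 1]]$v
    }
    dk <- array(0, dim(params$kernels[[i]]))
    dxin <- array(0, dim(xin))
    dimu <- dim(du)
    for (m in seq_len(dimu[3])) for (r in seq_len(dimu[1])) for (cl in seq_len(dimu[2])) {
      g <- du[r, cl, m]
      if (g == 0) next
      for (n in seq_len(dim(xin)[3])) for (dr in seq_len(dim(dk)[1]))
        for (dc in seq_len(dim(dk)[2])) {
          dk[dr, dc, n, m] <- dk[dr, dc, n, m] + g * xin[r + dr - 1, cl + dc - 1, n]
          dxin[r + dr - 1, cl + dc - 1, n] <- dxin[r + dr - 1, cl + dc - 1, n] +
            g * params$kernels[[i]][dr, dc, n, m]
        }
    }
    gk[[i]] <- dk
    gb[[i]] <- apply(du, 3, sum)
    dout <- dxin
  }
  list(kernels = gk, kbias = gb, W = gW, wbias = gwb)
}
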