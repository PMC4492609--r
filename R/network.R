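#' Scaled hyperbolic tangent activation
#'
#' The convolutional layers use `1.7159 * tanh(2/3 * u)`, a sigmoid scaled
#' so that its output at u = +-1 is close to +-1 and its effective gain
#' near the origin is about one. Activations are therefore bounded by
#' 1.7159 in absolute value.
#'
#' @param u numeric vector/array of internal states.
#' @return array of the same shape.
#' @export
scaled_tanh <- function(u) 1.7159 * tanh((2 / 3) * u)

# derivative of scaled_tanh expressed through its value v
scaled_tanh_prime_v <- function(v) (2 / 3) * (1.7159 - v * v / 1.7159)

#' One leaky-integrator convolution step
#'
#' Updates a convolutional layer's internal state for one frame:
#' `u = (1 - 1/tau) * u_prev + (1/tau) * (cross_correlate(v_below, k) + b)`,
#' and returns the activation `v = scaled_tanh(u)`. The convolution is
#' valid (no padding), stride 1, without kernel flipping. With `tau = 1`
#' the unit is memoryless; as `tau` grows the state becomes a long
#' exponential average of its drive.
#'
#' @param u_prev internal state array (rows, cols, maps) from the previous
#'   step.
#' @param v_below activations of the layer below at the current step
#'   (rows, cols, maps_in).
#' @param k kernel array with dim (kernel_rows, kernel_cols, maps_in, maps).
#' @param b bias vector, one per output map.
#' @param tau time constant, >= 1.
#' @return list with elements `u` and `v`, both (rows, cols, maps).
#' @export
leaky_integrate_conv <- function(u_prev, v_below, k, b, tau) {
  stopifnot(tau >= 1)
  drive <- cross_correlate(v_below, k)
  nout <- dim(k)[4L]
  drive <- sweep(drive, 3L, b, "+")
  if (!identical(dim(u_prev), dim(drive)))
    stop("internal state shape ", paste(dim(u_prev), collapse = "x"),
         " does not match the convolution output ",
         paste(dim(drive), collapse = "x"))
  u <- (1 - 1 / tau) * u_prev + (1 / tau) * drive
  list(u = u, v = scaled_tanh(u))
}

# valid stride-1 cross-correlation of a feature stack x (rows, cols, nin)
# with kernels k (kr, kc, nin, nout); returns (orows, ocols, nout)
cross_correlate <- function(x, k) {
  dx <- dim(x); dk <- dim(k)
  if (length(dx) == 2L) { dim(x) <- c(dx, 1L); dx <- dim(x) }
  if (dx[3L] != dk[3L])
    stop("input has ", dx[3L], " maps but the kernel expects ", dk[3L])
  orows <- dx[1L] - dk[1L] + 1L
  ocols <- dx[2L] - dk[2L] + 1L
  if (orows < 1L || ocols < 1L) stop("kernel larger than input maps")
  plen <- prod(dk[1:3])
  # im2col: one column per output position
  P <- matrix(0, plen, orows * ocols)
  p <- 1L
  for (n in seq_len(dk[3L])) for (dc in seq_len(dk[2L])) for (dr in seq_len(dk[1L])) {
    P[p, ] <- x[dr:(dr + orows - 1L), dc:(dc + ocols - 1L), n]
    p <- p + 1L
  }
  K <- matrix(k, plen, dk[4L])
  out <- crossprod(K, P)           # nout x npos
  array(t(out), c(orows, ocols, dk[4L]))
}

#' Non-overlapping max pooling
#'
#' Takes the maximum within each `pool_size` x `pool_size` window of every
#' feature map and records the argmax positions so that gradients can be
#' routed back to the winning units.
#'
#' @param v activation array (rows, cols, maps); rows and cols must be
#'   divisible by `pool_size`.
#' @param pool_size window edge length.
#' @return list with `values` (rows/p, cols/p, maps) and `argmax` (same
#'   shape, linear index of the winner within its input map).
#' @export
max_pool <- function(v, pool_size) {
  d <- dim(v)
  if (length(d) == 2L) { dim(v) <- c(d, 1L); d <- dim(v) }
  if (d[1L] %% pool_size != 0L || d[2L] %% pool_size != 0L)
    stop("pool size ", pool_size, " does not divide the map dimensions ",
         d[1L], "x", d[2L])
  pr <- d[1L] %/% pool_size; pc <- d[2L] %/% pool_size
  vals <- array(0, c(pr, pc, d[3L]))
  amax <- array(0L, c(pr, pc, d[3L]))
  for (m in seq_len(d[3L])) {
    S <- v[, , m]
    for (j in seq_len(pc)) for (i in seq_len(pr)) {
      rs <- ((i - 1L) * pool_size + 1L):(i * pool_size)
      cs <- ((j - 1L) * pool_size + 1L):(j * pool_size)
      w <- S[rs, cs]
      best <- which.max(w)
      vals[i, j, m] <- w[best]
      br <- (best - 1L) %% pool_size + 1L
      bc <- (best - 1L) %/% pool_size + 1L
      amax[i, j, m] <- rs[br] + d[1L] * (cs[bc] - 1L) # 1-based within-map index
    }
  }
  list(values = vals, argmax = amax)
}

#' Output-head internal states
#'
#' The output layer is static (no temporal integration): at every step it
#' applies an affine map to the flattened activations of the top
#' convolutional block, `s = W v + b`.
#'
#' @param v_top activation array (or vector) of the top convolutional
#'   block, flattened column-major (rows, then cols, then maps).
#' @param W weight matrix, classes x length(v_top).
#' @param b bias vector, one per class.
#' @return numeric vector of class scores `s`.
#' @export
output_internal_states <- function(v_top, W, b) {
  v <- as.vector(v_top)
  if (ncol(W) != length(v))
    stop("output weights expect ", ncol(W), " inputs, got ", length(v))
  as.vector(W %*% v + b)
}

#' Softmax class distribution
#'
#' Numerically stabilized by subtracting the maximum score, which leaves
#' the distribution unchanged (softmax is invariant to additive shifts).
#'
#' @param s numeric vector of class scores.
#' @return probability vector summing to one.
#' @export
softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Reset the network state
#'
#' Returns the state at time zero: all internal states are exactly zero
#' (and hence all activations are zero), so every episode starts from the
#' same point regardless of what was presented before.
#'
#' @param arch an `mstnn_arch`.
#' @return an `mstnn_state`: list with `u` and `v` (one array per
#'   convolutional block) and step counter `t = 0`.
#' @export
reset_state <- function(arch) {
  plan <- arch_plan(arch)
  u <- lapply(plan$blocks, function(b) array(0, c(b$outrows, b$outcols, b$nout)))
  structure(list(u = u, v = u, t = 0L), class = "mstnn_state")
}

#' One forward step of the full network (reference engine)
#'
#' Performs a single bottom-up sweep for one frame: each convolutional
#' block reads the same-step activations of the block below and its own
#' internal state from the previous step; pooling and the static output
#' head follow. This is the readable per-step reference implementation;
#' [forward_sequence()] evaluates whole sequences through the compiled
#' engine and agrees with iterated calls of this function.
#'
#' @param state an `mstnn_state` (see [reset_state()]).
#' @param params an `mstnn_params` (see [initialize_parameters()]).
#' @param frame numeric matrix (rows x cols) matching the input layer.
#' @param arch the `mstnn_arch`.
#' @return list with the updated `state`, class scores `s`, and the class
#'   distribution `y`.
#' @export
forward_step <- function(state, params, frame, arch) {
  plan <- arch_plan(arch)
  if (!all(dim(frame) == c(plan$in_rows, plan$in_cols)))
    stop("frame is ", paste(dim(frame), collapse = "x"), " but the input ",
         "layer is ", plan$in_rows, "x", plan$in_cols)
  x <- array(frame, c(plan$in_rows, plan$in_cols, 1L))
  for (i in seq_along(plan$blocks)) {
    b <- plan$blocks[[i]]
    st <- leaky_integrate_conv(state$u[[i]], x, params$kernels[[i]],
                               params$kbias[[i]], b$tau)
    state$u[[i]] <- st$u
    state$v[[i]] <- st$v
    x <- if (b$pool > 1L) max_pool(st$v, b$pool)$values else st$v
  }
  s <- output_internal_states(x, params$W, params$wbias)
  state$t <- state$t + 1L
  list(state = state, s = s, y = softmax(s))
}

#' Run the network over a whole sequence
#'
#' Evaluates the recurrent dynamics from the reset (all-zero) state over
#' every frame and returns the per-step class scores and distributions.
#' `engine = "cpp"` (default) uses the compiled layer-wise implementation;
#' `engine = "r"` iterates [forward_step()] and is provided as a slow
#' cross-checkable reference.
#'
#' @param params an `mstnn_params`.
#' @param arch the matching `mstnn_arch`.
#' @param x an `mstnn_video` or a numeric array (rows, cols, T).
#' @param engine `"cpp"` or `"r"`.
#' @param record if `TRUE`, also return the activations `v` of every
#'   convolutional layer as arrays (rows, cols, maps, T).
#' @return list with `y` (classes x T), `s` (classes x T), and optionally
#'   `v` (list of arrays, one per convolutional layer).
#' @export
forward_sequence <- function(params, arch, x, engine = c("cpp", "r"),
                             record = FALSE) {
  engine <- match.arg(engine)
  frames <- if (inherits(x, "mstnn_video")) x$frames else x
  stopifnot(length(dim(frames)) == 3L)
  plan <- arch_plan(arch)
  check_params(params, plan)
  if (engine == "cpp") {
    out <- .mstnn_forward_cpp(frames, plan, unclass(params), record)
    return(out)
  }
  T_ <- dim(frames)[3L]
  C <- plan$classes
  y <- s <- matrix(0, C, T_)
  v <- if (record) lapply(plan$blocks, function(b)
    array(0, c(b$outrows, b$outcols, b$nout, T_)))
  state <- reset_state(arch)
  for (t in seq_len(T_)) {
    st <- forward_step(state, params, frames[, , t], arch)
    state <- st$state
    s[, t] <- st$s
    y[, t] <- st$y
    if (record) for (i in seq_along(v)) v[[i]][, , , t] <- state$v[[i]]
  }
  out <- list(s = s, y = y)
  if (record) out$v <- v
  out
}
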