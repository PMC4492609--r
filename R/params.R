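#' Initialize network parameters
#'
#' Draws every kernel weight, bias, and output-head weight i.i.d. from a
#' zero-mean Gaussian with standard deviation `sigma` (default 0.05),
#' using a seeded generator so the draw is exactly reproducible.
#'
#' @param arch an `mstnn_arch`.
#' @param sigma standard deviation of the Gaussian initializer.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @return an `mstnn_params` object: per-block kernel arrays
#'   (kernel_rows, kernel_cols, maps_in, maps_out) and bias vectors, plus
#'   the output weight matrix `W` (classes x top-block size) and bias
#'   `wbias`.
#' @export
initialize_parameters <- function(arch, sigma = 0.05, seed = NULL) {
  stopifnot(sigma > 0)
  plan <- arch_plan(arch)
  with_seed(seed, {
    kernels <- lapply(plan$blocks, function(b)
      array(rnorm(b$kr * b$kc * b$nin * b$nout, 0, sigma),
            c(b$kr, b$kc, b$nin, b$nout)))
    kbias <- lapply(plan$blocks, function(b) rnorm(b$nout, 0, sigma))
    W <- matrix(rnorm(plan$classes * plan$top_size, 0, sigma),
                plan$classes, plan$top_size)
    wbias <- rnorm(plan$classes, 0, sigma)
    structure(list(kernels = kernels, kbias = kbias, W = W, wbias = wbias,
                   arch_hash = content_hash(unclass(arch))),
              class = "mstnn_params")
  })
}

check_params <- function(params, plan) {
  for (i in seq_along(plan$blocks)) {
    b <- plan$blocks[[i]]
    dk <- dim(params$kernels[[i]])
    if (!identical(as.integer(dk),
                   as.integer(c(b$kr, b$kc, b$nin, b$nout))))
      stop("kernel ", i, " has shape ", paste(dk, collapse = "x"),
           " but the architecture requires ",
           paste(c(b$kr, b$kc, b$nin, b$nout), collapse = "x"))
    if (length(params$kbias[[i]]) != b$nout)
      stop("bias ", i, " has length ", length(params$kbias[[i]]),
           ", expected ", b$nout)
  }
  if (!identical(dim(params$W), c(plan$classes, as.integer(plan$top_size))))
    stop("output weights are ", paste(dim(params$W), collapse = "x"),
         ", expected ", plan$classes, "x", plan$top_size)
  if (!all(vapply(params$kernels, function(k) all(is.finite(k)), logical(1))) ||
      !all(is.finite(params$W)))
    stop("parameters contain non-finite entries")
  invisible(TRUE)
}

#' Gradient-descent parameter update with weight decay
#'
#' Applies one stochastic gradient step. Weight decay (L2 shrinkage) acts
#' on kernel weights and output weights but never on biases:
#' `k <- k - alpha * (grad_k + decay * k)`, `b <- b - alpha * grad_b`.
#'
#' @param params an `mstnn_params`.
#' @param grads a gradient set of the same shape family (from [bptt()]).
#' @param alpha learning rate.
#' @param decay weight-decay coefficient (default 0.0005).
#' @return the updated `mstnn_params`.
#' @export
apply_update <- function(params, grads, alpha, decay = 5e-4) {
  for (i in seq_along(params$kernels)) {
    params$kernels[[i]] <- params$kernels[[i]] -
      alpha * (grads$kernels[[i]] + decay * params$kernels[[i]])
    params$kbias[[i]] <- params$kbias[[i]] - alpha * grads$kbias[[i]]
  }
  params$W <- params$W - alpha * (grads$W + decay * params$W)
  params$wbias <- params$wbias - alpha * grads$wbias
  if (!all(is.finite(params$W)) ||
      !all(vapply(params$kernels, function(k) all(is.finite(k)), logical(1))))
    stop("non-finite parameter after update (diverged); reduce the ",
         "learning rate")
  params
}

#' @export
print.mstnn_params <- function(x, ...) {
  nk <- sum(vapply(x$kernels, length, numeric(1)))
  nb <- sum(vapply(x$kbias, length, numeric(1)))
  cat("mstnn parameters: ", length(x$kernels), " conv blocks, ",
      nk + nb + length(x$W) + length(x$wbias), " learnable values\n", sep = "")
  invisible(x)
}

#' Save and load parameter checkpoints
#'
#' A checkpoint stores the parameters together with a hash of the
#' architecture they were shaped by; loading against a different
#' architecture is refused. Checkpoints are run-time artifacts (RDS).
#'
#' @param params an `mstnn_params`.
#' @param path file path.
#' @param arch if given to `load_checkpoint()`, the architecture the
#'   parameters must match.
#' @export
save_checkpoint <- function(params, path) {
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, arch = NULL) {
  params <- readRDS(path)
  if (!inherits(params, "mstnn_params")) stop("not an mstnn checkpoint: ", path)
  if (!is.null(arch) &&
      !identical(params$arch_hash, content_hash(unclass(arch))))
    stop("checkpoint ", path, " was trained under a different architecture")
  params
}
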