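#' Declare network layers
#'
#' Constructors for the layer records that make up an [mstnn_architecture()].
#' A network is an ordered stack: one input layer, then convolutional
#' layers (each optionally followed by a max-pooling layer), and a final
#' fully-connected softmax output layer.
#'
#' Convolution is valid (no padding), stride-1 cross-correlation, so a
#' convolutional layer's map size is `prev_rows - kernel_rows + 1` by
#' `prev_cols - kernel_cols + 1`. The spatial map dimensions are derived
#' automatically; pass `rows`/`cols` only to assert an expected size.
#'
#' @param rows,cols spatial dimensions of the input frames (rows x columns).
#' @param maps number of feature maps.
#' @param kernel integer vector `c(kernel_rows, kernel_cols)`.
#' @param tau time constant of the layer's leaky-integrator units; must be
#'   >= 1. `tau = 1` gives memoryless (static) units; larger values give
#'   slower dynamics (the internal state decays by a factor `1 - 1/tau`
#'   per frame).
#' @param size max-pooling window; the window is `size` x `size`,
#'   non-overlapping, and must tile the previous layer's maps exactly.
#' @param classes number of output classes.
#' @return a layer record (plain list with class `"mstnn_layer"`).
#' @seealso [mstnn_architecture()], [default_architecture()]
#' @export
input_layer <- function(rows, cols, maps = 1L) {
  new_layer("input", maps = maps, rows = rows, cols = cols)
}

#' @rdname input_layer
#' @export
conv_layer <- function(maps, kernel, tau, rows = NULL, cols = NULL) {
  stopifnot(length(kernel) == 2L)
  new_layer("convolutional", maps = maps, rows = rows, cols = cols,
            krows = kernel[1L], kcols = kernel[2L], tau = tau)
}

#' @rdname input_layer
#' @export
pool_layer <- function(size = 2L) {
  new_layer("max_pooling", pool = size)
}

#' @rdname input_layer
#' @export
output_layer <- function(classes) {
  new_layer("fully_connected", classes = classes)
}

new_layer <- function(role, maps = NULL, rows = NULL, cols = NULL,
                      krows = NULL, kcols = NULL, tau = NULL, pool = NULL,
                      classes = NULL) {
  structure(list(role = role, maps = maps, rows = rows, cols = cols,
                 krows = krows, kcols = kcols, tau = tau, pool = pool,
                 classes = classes),
            class = "mstnn_layer")
}

#' Assemble and validate a network architecture
#'
#' Builds an `mstnn_arch` object from an ordered list of layer records and
#' checks every structural invariant: the stack starts with an input layer
#' and ends with a fully-connected layer; each convolutional layer's map
#' size follows the valid-convolution arithmetic; every pooling layer
#' directly follows a convolutional (or pooling) layer whose maps its
#' window tiles exactly; time constants are >= 1 and non-decreasing with
#' depth.
#'
#' @param ... layer records (see [input_layer()]), or a single list of them.
#' @return an object of class `mstnn_arch`: the layer list with all derived
#'   map dimensions filled in.
#' @examples
#' arch <- mstnn_architecture(
#'   input_layer(12, 12),
#'   conv_layer(2, kernel = c(3, 3), tau = 2),
#'   pool_layer(2),
#'   output_layer(3)
#' )
#' arch
#' @export
mstnn_architecture <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "mstnn_layer"))
    layers <- layers[[1L]]
  validate_architecture(structure(list(layers = layers), class = "mstnn_arch"))
}

#' The reference seven-layer silhouette architecture
#'
#' The default stack used throughout the package for 48 x 54 silhouette
#' videos: input 1 x 48 x 54, conv 6 maps (kernel 9 x 15, tau = 2) ->
#' 40 x 40, pool 2 -> 20 x 20, conv 50 maps (kernel 7 x 7, tau = 5) ->
#' 14 x 14, pool 2 -> 7 x 7, conv 100 maps (kernel 7 x 7, tau = 100) ->
#' 1 x 1, then a fully-connected softmax head. Time constants increase
#' along the hierarchy so that higher layers integrate over progressively
#' longer windows of the input.
#'
#' @param classes number of output classes.
#' @param taus time constants for the three convolutional layers.
#' @return an `mstnn_arch` object.
#' @export
default_architecture <- function(classes = 10L, taus = c(2, 5, 100)) {
  stopifnot(length(taus) == 3L)
  mstnn_architecture(
    input_layer(48, 54),
    conv_layer(6, kernel = c(9, 15), tau = taus[1L]),
    pool_layer(2),
    conv_layer(50, kernel = c(7, 7), tau = taus[2L]),
    pool_layer(2),
    conv_layer(100, kernel = c(7, 7), tau = taus[3L]),
    output_layer(classes)
  )
}

#' Validate an architecture and fill in derived dimensions
#'
#' @param arch an `mstnn_arch` object (possibly with unspecified
#'   convolutional map dimensions).
#' @return the validated architecture, with `rows`/`cols` of every layer
#'   resolved.
#' @export
validate_architecture <- function(arch) {
  layers <- arch$layers
  n <- length(layers)
  if (n < 2L) stop("architecture needs at least an input and an output layer")
  if (layers[[1L]]$role != "input")
    stop("layer 1 must be an input layer, not '", layers[[1L]]$role, "'")
  if (layers[[n]]$role != "fully_connected")
    stop("the last layer must be fully_connected, not '", layers[[n]]$role, "'")

  prev <- NULL
  last_tau <- -Inf
  for (i in seq_len(n)) {
    ly <- layers[[i]]
    switch(ly$role,
      input = {
        if (i != 1L) stop("layer ", i, ": input layer only allowed first")
        check_pos(ly$rows, ly$cols, ly$maps, layer = i)
      },
      convolutional = {
        if (is.null(prev) || is.null(prev$rows))
          stop("layer ", i, ": convolutional layer needs a spatial layer below")
        check_pos(ly$maps, ly$krows, ly$kcols, layer = i)
        if (is.null(ly$tau) || !is.finite(ly$tau) || ly$tau < 1)
          stop("layer ", i, ": time constant tau must be >= 1 (got ",
               ly$tau %||% "NULL", ")")
        if (ly$tau < last_tau)
          stop("layer ", i, ": time constant (", ly$tau, ") decreases with ",
               "depth; the hierarchy requires non-decreasing tau")
        last_tau <- ly$tau
        er <- prev$rows - ly$krows + 1L
        ec <- prev$cols - ly$kcols + 1L
        if (er < 1L || ec < 1L)
          stop("layer ", i, ": kernel ", ly$krows, "x", ly$kcols,
               " larger than input maps ", prev$rows, "x", prev$cols)
        if (!is.null(ly$rows) && (ly$rows != er || ly$cols != ec))
          stop("layer ", i, ": declared map size ", ly$rows, "x", ly$cols,
               " but valid convolution of ", prev$rows, "x", prev$cols,
               " with a ", ly$krows, "x", ly$kcols, " kernel gives ",
               er, "x", ec)
        layers[[i]]$rows <- as.integer(er)
        layers[[i]]$cols <- as.integer(ec)
      },
      max_pooling = {
        if (is.null(prev) || prev$role != "convolutional")
          stop("layer ", i, ": max-pooling must directly follow a ",
               "convolutional layer")
        check_pos(ly$pool, layer = i)
        if (prev$rows %% ly$pool != 0L || prev$cols %% ly$pool != 0L)
          stop("layer ", i, ": pool size ", ly$pool, " does not divide the ",
               "previous maps (", prev$rows, "x", prev$cols, ") exactly")
        layers[[i]]$maps <- prev$maps
        layers[[i]]$rows <- as.integer(prev$rows / ly$pool)
        layers[[i]]$cols <- as.integer(prev$cols / ly$pool)
      },
      fully_connected = {
        if (i != n) stop("layer ", i, ": fully_connected layer only allowed last")
        check_pos(ly$classes, layer = i)
        if (is.null(prev$rows))
          stop("layer ", i, ": output layer needs a spatial layer below")
      },
      stop("layer ", i, ": unknown role '", ly$role, "'")
    )
    prev <- layers[[i]]
  }
  arch$layers <- layers
  arch$classes <- as.integer(layers[[n]]$classes)
  arch
}

check_pos <- function(..., layer) {
  vals <- c(...)
  if (length(vals) == 0L || any(is.null(vals)) || any(!is.finite(vals)) ||
      any(vals < 1) || any(vals != round(vals)))
    stop("layer ", layer, ": expected positive integer dimensions, got ",
         paste(vals, collapse = ", "))
  invisible(TRUE)
}

# Compile an architecture into the conv-block plan consumed by the C++
# kernels: one record per convolutional layer, with its (post-pool) output
# geometry folded in.
arch_plan <- function(arch) {
  layers <- arch$layers
  blocks <- list()
  prev <- layers[[1L]]
  i <- 2L
  n <- length(layers)
  while (i < n) {
    ly <- layers[[i]]
    if (ly$role != "convolutional")
      stop("unsupported layer order at layer ", i)
    pool <- 1L
    prows <- ly$rows; pcols <- ly$cols
    if (i + 1L < n && layers[[i + 1L]]$role == "max_pooling") {
      pool <- layers[[i + 1L]]$pool
      prows <- layers[[i + 1L]]$rows
      pcols <- layers[[i + 1L]]$cols
      i <- i + 1L
    }
    blocks[[length(blocks) + 1L]] <- list(
      nin = prev$maps, nout = ly$maps,
      inrows = prev$rows, incols = prev$cols,
      outrows = ly$rows, outcols = ly$cols,
      kr = ly$krows, kc = ly$kcols, tau = ly$tau,
      pool = pool, prows = as.integer(prows), pcols = as.integer(pcols))
    prev <- list(maps = ly$maps, rows = prows, cols = pcols)
    i <- i + 1L
  }
  list(blocks = blocks, classes = arch$classes,
       in_rows = layers[[1L]]$rows, in_cols = layers[[1L]]$cols,
       top_size = prev$maps * prev$rows * prev$cols)
}

#' Indices and sizes of the convolutional layers
#'
#' @param arch an `mstnn_arch`.
#' @return `conv_layers()`: integer positions of the convolutional layers in
#'   the stack. `layer_units()`: the number of units (maps x rows x cols) of
#'   layer `i` of the stack.
#' @export
conv_layers <- function(arch) {
  which(vapply(arch$layers, function(l) l$role == "convolutional", logical(1)))
}

#' @rdname conv_layers
#' @param i layer position in the stack.
#' @export
layer_units <- function(arch, i) {
  ly <- arch$layers[[i]]
  if (is.null(ly$rows)) stop("layer ", i, " has no spatial units")
  as.integer(ly$maps * ly$rows * ly$cols)
}

#' Replace the time constants of the convolutional layers
#'
#' Convenience for ablation experiments: `set_time_constants()` replaces
#' all conv-layer taus; `set_top_tau()` changes only the deepest
#' convolutional layer (the slow layer), leaving the lower layers fixed.
#'
#' @param arch an `mstnn_arch`.
#' @param taus numeric vector, one per convolutional layer.
#' @param tau a single time constant for the top convolutional layer.
#' @return the modified, re-validated architecture.
#' @export
set_time_constants <- function(arch, taus) {
  idx <- conv_layers(arch)
  stopifnot(length(taus) == length(idx))
  for (j in seq_along(idx)) arch$layers[[idx[j]]]$tau <- taus[j]
  validate_architecture(arch)
}

#' @rdname set_time_constants
#' @export
set_top_tau <- function(arch, tau) {
  idx <- conv_layers(arch)
  arch$layers[[idx[length(idx)]]]$tau <- tau
  validate_architecture(arch)
}

#' @export
print.mstnn_arch <- function(x, ...) {
  cat("mstnn architecture (", length(x$layers), " layers, ",
      x$classes, " classes)\n", sep = "")
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    desc <- switch(ly$role,
      input = sprintf("input            %d x %d x %d", ly$maps, ly$rows, ly$cols),
      convolutional = sprintf(
        "convolutional    %d x %d x %d   kernel %dx%d  tau %g",
        ly$maps, ly$rows, ly$cols, ly$krows, ly$kcols, ly$tau),
      max_pooling = sprintf("max-pooling      %d x %d x %d   window %dx%d",
                            ly$maps, ly$rows, ly$cols, ly$pool, ly$pool),
      fully_connected = sprintf("fully-connected  %d classes (softmax)",
                                ly$classes))
    cat(sprintf("  [%d] %s\n", i - 1L, desc))
  }
  invisible(x)
}

#' Read and write architecture descriptions
#'
#' Architectures are serialized as a YAML or JSON document (chosen by file
#' extension) listing one record per layer: role, maps, rows, cols,
#' kernel, pool, tau, classes.
#'
#' @param arch an `mstnn_arch`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_architecture()` returns a validated `mstnn_arch`.
#' @export
write_architecture <- function(arch, path) {
  recs <- lapply(arch$layers, function(l) Filter(Negate(is.null), unclass(l)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  layers <- lapply(recs, function(r) {
    new_layer(r$role, maps = r$maps, rows = r$rows, cols = r$cols,
              krows = r$krows, kcols = r$kcols, tau = r$tau, pool = r$pool,
              classes = r$classes)
  })
  mstnn_architecture(layers)
}
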