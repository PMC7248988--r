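# Deconvolution-based introspection: project a chosen kernel's activation
# from any layer back to the input domain by reversing the pooling and
# convolution of each block (average pooling reversed by its adjoint —
# uniform redistribution — since there are no max-pool switches; biases
# omitted on the reverse pass).

# adjoint of 2-wide average pooling: each pooled value is split equally
# across its pool window; a trailing column dropped by pooling gets zero
unpool_uniform <- function(p, out_len, kernel = 2L) {
  stopifnot(is.matrix(p))
  u <- matrix(0, nrow(p), out_len)
  used <- kernel * ncol(p)
  for (kk in seq_len(kernel))
    u[, seq(kk, used, by = kernel)] <- p / kernel
  u
}

# transposed ("flipped-kernel") convolution with a layer's own weights:
# the adjoint of the valid temporal convolution, mapping a filters x Lout
# map back to channels x Lin
conv_transpose <- function(map, w) {
  stopifnot(is.matrix(map), is.array(w), length(dim(w)) == 3L)
  n_filt <- dim(w)[1]; n_ch <- dim(w)[2]; k <- dim(w)[3]
  stopifnot(nrow(map) == n_filt)
  wm <- matrix(w, n_filt, n_ch * k)
  col2im(crossprod(wm, map), n_ch, k, ncol(map) + k - 1L)
}

#' Kernel with the largest activation at a layer
#'
#' Returns the index of the filter whose activation map (the layer's
#' post-pooling output for this input) has the largest L2 norm; ties
#' resolve to the lowest index.
#'
#' @param model A fitted [mf_cnn()].
#' @param segment A `channels x samples` input matrix (or a
#'   `fused_segments` object with one segment).
#' @param layer Layer index, 1 to the model depth.
#' @return Integer kernel index.
#' @export
top_kernel <- function(model, segment, layer) {
  stopifnot(inherits(model, "mf_cnn"))
  if (!is_count(layer) || layer > model$spec$n_layers)
    stop("layer must be in 1..", model$spec$n_layers, call. = FALSE)
  x <- as_input_matrix(segment)
  fwd <- cnn_forward_matrix(model$spec, model$weights, x, keep_cache = TRUE)
  norms <- sqrt(rowSums(fwd$cache[[layer]]$p^2))
  which.max(norms)
}

as_input_matrix <- function(segment) {
  if (inherits(segment, "fused_segments")) {
    stopifnot(dim(segment$segments)[3] >= 1L)
    segment$segments[, , 1L]
  } else {
    stopifnot(is.matrix(segment))
    segment
  }
}

#' Project one kernel's activation back to the input domain
#'
#' Runs the forward pass, zeroes every activation map at `layer` except
#' `kernel`, then reverses each block down to the input: average pooling
#' is reversed by uniform redistribution (its adjoint), ReLU is applied,
#' and the transposed convolution with the layer's own weights maps the
#' result one block down.  Biases are omitted on the reverse pass.  The
#' projection lives in input coordinates (channels x input columns) and
#' shows what the selected kernel responds to.
#'
#' @inheritParams top_kernel
#' @param kernel Filter index within `layer`; defaults to
#'   [top_kernel()].
#' @return An `mf_projection`: `values` (channels x input columns),
#'   `source_layer`, `source_kernel`, `activation_norm` and the channel
#'   order when available.
#' @export
project_activation <- function(model, segment, layer, kernel = NULL) {
  stopifnot(inherits(model, "mf_cnn"))
  spec <- model$spec
  if (!is_count(layer) || layer > spec$n_layers)
    stop("layer must be in 1..", spec$n_layers, call. = FALSE)
  x <- as_input_matrix(segment)
  if (is.null(kernel)) kernel <- top_kernel(model, x, layer)
  if (!is_count(kernel) || kernel > spec$conv_filters[layer])
    stop("kernel must be in 1..", spec$conv_filters[layer], call. = FALSE)
  fwd <- cnn_forward_matrix(spec, model$weights, x, keep_cache = TRUE)
  a <- fwd$cache[[layer]]$p
  keep <- a[kernel, , drop = FALSE]
  a[] <- 0
  a[kernel, ] <- keep
  activation_norm <- sqrt(sum(keep^2))
  for (l in layer:1) {
    u <- unpool_uniform(a, spec$conv_len[l])
    r <- relu(u)
    a <- conv_transpose(r, layer_kernel_array(spec, model$weights, l))
  }
  ch <- if (inherits(segment, "fused_segments")) segment$channel_order
        else rownames(x)
  structure(list(
    values = a,
    source_layer = as.integer(layer),
    source_kernel = as.integer(kernel),
    activation_norm = activation_norm,
    channel_order = ch
  ), class = "mf_projection")
}

#' Per-channel attribution norms of a projection
#'
#' The L2 norm of each channel row of the projection: the measurement
#' primitive for judging which input channel a kernel relies on.
#'
#' @param projection An `mf_projection`.
#' @return Named numeric vector of per-channel L2 norms.
#' @export
channel_norms <- function(projection) {
  stopifnot(inherits(projection, "mf_projection"))
  v <- sqrt(rowSums(projection$values^2))
  names(v) <- projection$channel_order %||% paste0("ch", seq_along(v))
  v
}

#' @export
print.mf_projection <- function(x, ...) {
  cat(sprintf("<mf_projection> layer %d, kernel %d -> %d x %d input grid (activation L2 %.3g)\n",
              x$source_layer, x$source_kernel, nrow(x$values),
              ncol(x$values), x$activation_norm))
  invisible(x)
}

#' Plot a projection as one panel per channel
#'
#' @param x An `mf_projection`.
#' @param rate Sampling rate used for the time axis (default 128).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mf_projection <- function(x, rate = 128, ...) {
  n_ch <- nrow(x$values)
  old <- graphics::par(mfrow = c(n_ch, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old), add = TRUE)
  t <- (seq_len(ncol(x$values)) - 1) / rate
  nms <- x$channel_order %||% paste0("ch", seq_len(n_ch))
  for (i in seq_len(n_ch))
    graphics::plot(t, x$values[i, ], type = "l", xlab = "", ylab = nms[i],
                   ...)
  invisible(x)
}
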