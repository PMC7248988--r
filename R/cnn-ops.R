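# Network building blocks: temporal valid convolution (im2col + matrix
# multiply), ReLU, average pooling, overflow-safe softmax, and the full
# forward pass.  The convolution treats the channel/filter axis as depth:
# each output filter sums over every input row, which reproduces the 2D
# convolution when the kernel spans the full channel axis.

#' Convolutional network architecture specification
#'
#' Five (conv -> ReLU -> average-pool) blocks followed by a fully
#' connected layer and softmax.  The default architecture uses 256, 128,
#' 64, 32 and 32 filters with kernel sizes 3, 5, 7, 9 and 9; pooling is
#' average with kernel size 2.  Convolutions are "valid" (no padding,
#' stride 1) along time.
#'
#' @param n_channels Number of input channel rows.
#' @param input_cols Temporal length of the input (768 = 6 s at 128 Hz).
#' @param conv_filters Integer vector of filter counts per layer.
#' @param conv_kernels Integer vector of temporal kernel sizes, same
#'   length as `conv_filters`.
#' @param n_classes Number of output classes (2: low/high MF).
#' @return A `model_spec` with the derived per-layer temporal extents.
#' @export
model_spec <- function(n_channels, input_cols = 768,
                       conv_filters = c(256, 128, 64, 32, 32),
                       conv_kernels = c(3, 5, 7, 9, 9),
                       n_classes = 2) {
  stopifnot(is_count(n_channels), is_count(input_cols), is_count(n_classes),
            n_classes >= 2)
  if (length(conv_filters) != length(conv_kernels) || !length(conv_filters))
    stop("conv_filters and conv_kernels must have equal, positive length",
         call. = FALSE)
  stopifnot(all(conv_filters >= 1), all(conv_kernels >= 1))
  n_layers <- length(conv_filters)
  conv_len <- integer(n_layers)   # temporal extent after each conv
  pool_len <- integer(n_layers)   # ... and after each pool
  len <- input_cols
  for (l in seq_len(n_layers)) {
    if (conv_kernels[l] > len)
      stop("layer ", l, " kernel (", conv_kernels[l],
           ") longer than its input (", len, ")", call. = FALSE)
    conv_len[l] <- len - conv_kernels[l] + 1L
    if (conv_len[l] < 2)
      stop("layer ", l, " pooling input too short", call. = FALSE)
    pool_len[l] <- conv_len[l] %/% 2L
    len <- pool_len[l]
  }
  structure(list(
    n_channels = as.integer(n_channels),
    input_cols = as.integer(input_cols),
    conv_filters = as.integer(conv_filters),
    conv_kernels = as.integer(conv_kernels),
    n_classes = as.integer(n_classes),
    n_layers = n_layers,
    conv_len = conv_len, pool_len = pool_len,
    n_flat = as.integer(conv_filters[n_layers] * pool_len[n_layers])
  ), class = "model_spec")
}

#' Reduced demo architecture
#'
#' Same depth, kernel sizes and pooling as the full architecture but with
#' 16, 16, 8, 8, 8 filters, sized to train in seconds on a single CPU;
#' the temporal extent chain is identical to the full model.
#'
#' @inheritParams model_spec
#' @return A [model_spec()].
#' @export
demo_model_spec <- function(n_channels = 6, input_cols = 768, n_classes = 2) {
  model_spec(n_channels, input_cols,
             conv_filters = c(16, 16, 8, 8, 8),
             conv_kernels = c(3, 5, 7, 9, 9),
             n_classes = n_classes)
}

# im2col: stack the K lagged slices of x (C x L) into a (C*K) x Lout
# matrix so a valid temporal convolution becomes one matrix product
im2col <- function(x, k) {
  n_ch <- nrow(x)
  l_out <- ncol(x) - k + 1L
  xc <- matrix(0, n_ch * k, l_out)
  for (kk in seq_len(k))
    xc[((kk - 1L) * n_ch + 1L):(kk * n_ch), ] <-
      x[, kk:(kk + l_out - 1L), drop = FALSE]
  xc
}

# adjoint of im2col: scatter-add the (C*K) x Lout gradient back onto C x L
col2im <- function(dxc, n_ch, k, l_in) {
  l_out <- ncol(dxc)
  dx <- matrix(0, n_ch, l_in)
  for (kk in seq_len(k)) {
    cols <- kk:(kk + l_out - 1L)
    dx[, cols] <- dx[, cols] + dxc[((kk - 1L) * n_ch + 1L):(kk * n_ch), ]
  }
  dx
}

#' Temporal valid convolution over a channel stack
#'
#' Computes `out[f, j] = b[f] + sum_{c,k} w[f, c, k] * x[c, j + k - 1]`,
#' i.e. the discrete convolution summed over the full channel depth with
#' no padding, so the output temporal length is
#' `ncol(x) - dim(w)[3] + 1`.
#'
#' @param x Numeric matrix, channels x time.
#' @param w Kernel bank: numeric array `(filters, channels, kernel_size)`.
#' @param b Bias vector, one per filter (default zeros).
#' @return Numeric matrix, filters x output time.
#' @export
conv_forward <- function(x, w, b = numeric(dim(w)[1])) {
  stopifnot(is.matrix(x), is.array(w), length(dim(w)) == 3L)
  n_filt <- dim(w)[1]; n_ch <- dim(w)[2]; k <- dim(w)[3]
  if (n_ch != nrow(x))
    stop("kernel depth (", n_ch, ") does not match input channels (",
         nrow(x), ")", call. = FALSE)
  if (k > ncol(x))
    stop("kernel (", k, ") longer than input (", ncol(x), ")",
         call. = FALSE)
  stopifnot(length(b) == n_filt)
  wm <- matrix(w, n_filt, n_ch * k)
  wm %*% im2col(x, k) + b
}

#' Rectified linear activation, elementwise
#' @param x Numeric vector/matrix/array.
#' @return `pmax(x, 0)` with the shape of `x`.
#' @export
relu <- function(x) {
  out <- pmax(x, 0)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Average pooling along time
#'
#' Averages non-overlapping windows of `kernel` columns (stride =
#' `kernel`); trailing columns that do not fill a window are dropped.
#'
#' @param x Numeric matrix, filters x time, with at least `kernel`
#'   columns.
#' @param kernel Pool width (default 2).
#' @return Matrix of `floor(ncol(x) / kernel)` columns.
#' @export
avg_pool <- function(x, kernel = 2L) {
  stopifnot(is.matrix(x), is_count(kernel))
  if (ncol(x) < kernel)
    stop("pooling input shorter than kernel", call. = FALSE)
  l_out <- ncol(x) %/% kernel
  out <- matrix(0, nrow(x), l_out)
  for (kk in seq_len(kernel))
    out <- out + x[, seq(kk, by = kernel, length.out = l_out), drop = FALSE]
  out / kernel
}

#' Overflow-safe softmax
#'
#' @param logits Finite numeric vector of length K.
#' @return Probability vector: positive, sums to 1, invariant to adding
#'   any constant to all logits.
#' @export
softmax <- function(logits) {
  if (!is.numeric(logits) || !all(is.finite(logits)))
    stop("softmax requires finite numeric logits", call. = FALSE)
  z <- exp(logits - max(logits))
  z / sum(z)
}

# He-style fan-in scaled initialization, fully determined by the RNG state
init_weights <- function(spec) {
  conv <- vector("list", spec$n_layers)
  in_ch <- spec$n_channels
  for (l in seq_len(spec$n_layers)) {
    n_filt <- spec$conv_filters[l]; k <- spec$conv_kernels[l]
    fan_in <- in_ch * k
    conv[[l]] <- list(
      w = matrix(stats::rnorm(n_filt * fan_in, 0, sqrt(2 / fan_in)),
                 n_filt, fan_in),
      b = numeric(n_filt))
    in_ch <- n_filt
  }
  fc <- list(
    w = matrix(stats::rnorm(spec$n_classes * spec$n_flat, 0,
                            sqrt(1 / spec$n_flat)),
               spec$n_classes, spec$n_flat),
    b = numeric(spec$n_classes))
  list(conv = conv, fc = fc)
}

# full forward pass on one segment matrix; weights use the flattened
# (filters x channels*kernel) layout.  With keep_cache the per-layer
# inputs and pre/post-activation maps are returned for backprop and
# introspection.
cnn_forward_matrix <- function(spec, weights, x, keep_cache = FALSE) {
  if (!is.matrix(x) || nrow(x) != spec$n_channels ||
      ncol(x) != spec$input_cols)
    stop("input shape mismatch: expected ", spec$n_channels, " x ",
         spec$input_cols, ", got ", nrow(x), " x ", ncol(x), call. = FALSE)
  cache <- if (keep_cache) vector("list", spec$n_layers)
  a <- x
  in_ch <- spec$n_channels
  for (l in seq_len(spec$n_layers)) {
    k <- spec$conv_kernels[l]
    xc <- im2col(a, k)
    z <- weights$conv[[l]]$w %*% xc + weights$conv[[l]]$b
    r <- relu(z)
    p <- avg_pool(r, 2L)
    if (keep_cache) cache[[l]] <- list(xc = xc, z = z, p = p, in_len = ncol(a),
                                       in_ch = in_ch)
    a <- p
    in_ch <- spec$conv_filters[l]
  }
  v <- as.vector(a)
  logits <- drop(weights$fc$w %*% v + weights$fc$b)
  probs <- softmax(logits)
  if (keep_cache) list(probs = probs, logits = logits, v = v, cache = cache)
  else probs
}

# gradient of the cross-entropy loss for one sample; returns grads shaped
# like the weights plus the loss value
cnn_backward_matrix <- function(spec, weights, fwd, y_idx) {
  probs <- fwd$probs
  loss <- -log(max(probs[y_idx], 1e-12))
  dlogits <- probs
  dlogits[y_idx] <- dlogits[y_idx] - 1
  g <- list(conv = vector("list", spec$n_layers),
            fc = list(w = tcrossprod(dlogits, fwd$v), b = dlogits))
  dv <- drop(crossprod(weights$fc$w, dlogits))
  n_l <- spec$n_layers
  dp <- matrix(dv, spec$conv_filters[n_l], spec$pool_len[n_l])
  for (l in n_l:1) {
    cc <- fwd$cache[[l]]
    l_conv <- spec$conv_len[l]
    # average-pool backward: each input column in a window gets half the
    # gradient; a dropped trailing column gets none
    dr <- matrix(0, nrow(dp), l_conv)
    l_used <- 2L * ncol(dp)
    dr[, seq(1L, l_used, by = 2L)] <- dp / 2
    dr[, seq(2L, l_used, by = 2L)] <- dp / 2
    dz <- dr * (cc$z > 0)
    g$conv[[l]] <- list(w = tcrossprod(dz, cc$xc), b = rowSums(dz))
    if (l > 1L) {
      dxc <- crossprod(weights$conv[[l]]$w, dz)
      dx <- col2im(dxc, cc$in_ch, spec$conv_kernels[l], cc$in_len)
      dp <- dx
    }
  }
  list(grads = g, loss = loss)
}

# kernel bank of layer l as the (filters, channels, kernel) array
layer_kernel_array <- function(spec, weights, l) {
  in_ch <- if (l == 1L) spec$n_channels else spec$conv_filters[l - 1L]
  array(weights$conv[[l]]$w,
        dim = c(spec$conv_filters[l], in_ch, spec$conv_kernels[l]))
}
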