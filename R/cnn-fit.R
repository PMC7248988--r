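# Model fitting: Adam-optimized cross-entropy training with validation-
# driven learning-rate decay, early stopping and best-checkpoint restore,
# plus Monte-Carlo cross-validation over repeated stratified 60/20/20
# splits.

#' Training protocol configuration
#'
#' Encodes the cross-validated training protocol: repeated seeded
#' stratified 60/20/20 train/validation/test splits; at least
#' `min_epochs` epochs per fold; when the validation accuracy fails to
#' improve for `lr_patience` consecutive epochs the learning rate is
#' reduced by 20% (multiplied by `1 - lr_decay_factor`), and after
#' `stop_patience` epochs without improvement training terminates; the
#' weights with the best validation accuracy are restored before the test
#' set is touched.
#'
#' @param folds Number of Monte-Carlo cross-validation folds (default 20).
#' @param split Named fractions `c(train, val, test)` summing to 1
#'   (default 0.6/0.2/0.2).
#' @param min_epochs Minimum epochs per fold (default 15).
#' @param max_epochs Hard epoch cap (default 60).
#' @param lr_init Initial learning rate (default 1e-3).
#' @param lr_decay_factor Fractional reduction applied at each decay event
#'   (default 0.2, i.e. multiply by 0.8).
#' @param lr_patience Epochs without improvement per decay event
#'   (default 5).
#' @param stop_patience Epochs without improvement before termination
#'   (default 15).
#' @param batch_size Minibatch size (default 32); capped at the training
#'   set size, so large values give full-batch gradient descent.
#' @param weight_decay L2 penalty coefficient added to the weight (not
#'   bias) gradients (default 0.1).  On the small training sets this
#'   package targets, the unregularized network memorizes the training
#'   windows long before it finds features that generalize; the decay
#'   steadily shrinks the memorizing components so the class-relevant
#'   signal structure wins out.
#' @param seed Integer seed controlling splits, initialization and
#'   shuffling.
#' @param split_mode `"random"` (segment-level random splits, as implied
#'   by the protocol) or `"block"` (contiguous per-class blocks, which
#'   controls train/test leakage through the 2 s window overlap).
#' @return A `train_config`.
#' @export
train_config <- function(folds = 20, split = c(train = 0.6, val = 0.2,
                                               test = 0.2),
                         min_epochs = 15, max_epochs = 60,
                         lr_init = 1e-3, lr_decay_factor = 0.2,
                         lr_patience = 5, stop_patience = 15,
                         batch_size = 32, weight_decay = 0.1, seed = 1L,
                         split_mode = c("random", "block")) {
  split_mode <- match.arg(split_mode)
  stopifnot(is_count(folds), is_count(min_epochs), is_count(max_epochs),
            is_count(lr_patience), is_count(stop_patience),
            is_count(batch_size), length(split) == 3L,
            abs(sum(split) - 1) < 1e-9, all(split > 0),
            lr_init > 0, lr_decay_factor > 0, lr_decay_factor < 1,
            is_scalar_num(weight_decay), weight_decay >= 0)
  names(split) <- c("train", "val", "test")
  structure(list(folds = as.integer(folds), split = split,
                 min_epochs = as.integer(min_epochs),
                 max_epochs = as.integer(max_epochs),
                 lr_init = lr_init, lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 seed = as.integer(seed), split_mode = split_mode),
            class = "train_config")
}

#' Demo-scale training configuration
#'
#' The 60/20/20 cross-validation protocol with optimizer settings sized
#' for demo training sets of a few dozen windows: full-batch gradient
#' steps (batch size capped at the training-set size), constant learning
#' rate 3e-3, weight decay 0.03 and a fixed 250-epoch budget
#' (`min_epochs = max_epochs`, so the dynamic decay and early stopping
#' never cut the run short).  In this small-sample regime the network
#' memorizes the training windows within a few epochs and only
#' generalizes tens of epochs later, as the decay term prunes the
#' memorizing components; the fixed budget reliably carries every fold
#' through that late-generalization plateau.
#'
#' @param folds Number of folds (default 5 at demo scale).
#' @param seed Integer seed.
#' @param ... Further overrides passed to [train_config()].
#' @return A [train_config()].
#' @export
demo_train_config <- function(folds = 5, seed = 1L, ...) {
  train_config(folds = folds, seed = seed, batch_size = 512,
               lr_init = 3e-3, weight_decay = 0.03,
               min_epochs = 250, max_epochs = 250, ...)
}

# coerce x/y into (3D array, integer class index, class level names)
as_training_xy <- function(x, y = NULL, classes = NULL) {
  if (inherits(x, "fused_segments")) {
    if (is.null(y)) y <- x$labels
    x <- x$segments
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (is.null(y)) stop("labels are required for training", call. = FALSE)
  if (is.factor(y)) {
    if (is.null(classes)) classes <- levels(droplevels(y))
    y_idx <- match(as.character(y), classes)
  } else {
    if (is.null(classes)) classes <- as.character(sort(unique(y)))
    y_idx <- match(as.character(y), classes)
  }
  if (anyNA(y_idx)) stop("labels outside the class set", call. = FALSE)
  if (length(y_idx) != dim(x)[3])
    stop("one label per segment required", call. = FALSE)
  list(x = x, y = y_idx, classes = classes)
}

adam_init <- function(weights) {
  rapply(weights, function(w) list(m = w * 0, v = w * 0),
         how = "list", classes = "ANY")
}

# one Adam update over a list of weight tensors (recursively mirrors the
# weights structure)
adam_step <- function(weights, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(w, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(w = w - lr * mh / (sqrt(vh) + eps), s = s)
  }
  for (l in seq_along(weights$conv)) {
    for (nm in c("w", "b")) {
      r <- upd(weights$conv[[l]][[nm]], grads$conv[[l]][[nm]],
               state$conv[[l]][[nm]])
      weights$conv[[l]][[nm]] <- r$w
      state$conv[[l]][[nm]] <- r$s
    }
  }
  for (nm in c("w", "b")) {
    r <- upd(weights$fc[[nm]], grads$fc[[nm]], state$fc[[nm]])
    weights$fc[[nm]] <- r$w
    state$fc[[nm]] <- r$s
  }
  list(weights = weights, state = state)
}

scale_grads <- function(g, f) {
  for (l in seq_along(g$conv)) {
    g$conv[[l]]$w <- g$conv[[l]]$w * f
    g$conv[[l]]$b <- g$conv[[l]]$b * f
  }
  g$fc$w <- g$fc$w * f
  g$fc$b <- g$fc$b * f
  g
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (l in seq_along(a$conv)) {
    a$conv[[l]]$w <- a$conv[[l]]$w + b$conv[[l]]$w
    a$conv[[l]]$b <- a$conv[[l]]$b + b$conv[[l]]$b
  }
  a$fc$w <- a$fc$w + b$fc$w
  a$fc$b <- a$fc$b + b$fc$b
  a
}

model_accuracy <- function(spec, weights, x, y_idx) {
  if (!length(y_idx)) return(NA_real_)
  pred <- vapply(seq_len(dim(x)[3]), function(i)
    which.max(cnn_forward_matrix(spec, weights, x[, , i])), 0L)
  mean(pred == y_idx)
}

#' Fit the convolutional mental-fatigue classifier
#'
#' Trains the network on labeled fused segments by minibatch Adam on the
#' cross-entropy loss.  Validation accuracy drives the dynamic learning
#' rate (multiply by `1 - lr_decay_factor` after `lr_patience` epochs
#' without improvement), early stopping (`stop_patience` epochs without
#' improvement, after at least `min_epochs`), and checkpointing: the
#' returned weights are those with the best validation accuracy.
#'
#' @param x Training inputs: a labeled `fused_segments` object or a
#'   `channels x samples x n` array.
#' @param y Class labels (factor or vector), one per segment; taken from
#'   `x$labels` when `x` is a labeled `fused_segments`.
#' @param spec A [model_spec()]; defaults to [demo_model_spec()] sized to
#'   the input.
#' @param control A [train_config()].
#' @param validation Optional list `list(x =, y =)` in the same form; when
#'   absent, training accuracy drives the schedule.
#' @return An object of class `mf_cnn` with elements `spec`, `weights`
#'   (best checkpoint), `classes`, `history` (per-epoch loss, validation
#'   accuracy and learning rate), `best_epoch` and `control`.
#' @seealso [predict.mf_cnn()], [train_cv()]
#' @export
mf_cnn <- function(x, y = NULL, spec = NULL, control = train_config(),
                   validation = NULL) {
  tr <- as_training_xy(x, y)
  if (length(unique(tr$y)) < 2L)
    stop("training data must contain at least 2 classes", call. = FALSE)
  if (is.null(spec))
    spec <- demo_model_spec(n_channels = dim(tr$x)[1],
                            input_cols = dim(tr$x)[2],
                            n_classes = length(tr$classes))
  stopifnot(inherits(spec, "model_spec"), inherits(control, "train_config"))
  val <- if (!is.null(validation)) {
    as_training_xy(validation$x, validation$y, classes = tr$classes)
  }
  n <- dim(tr$x)[3]

  with_seed(control$seed, {
    weights <- init_weights(spec)
    state <- adam_init(weights)
    lr <- control$lr_init
    best <- list(acc = -Inf, weights = weights, epoch = 0L)
    no_improve <- 0L
    t_step <- 0L
    history <- list()
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = control$batch_size)) {
        idx <- ord[start:min(start + control$batch_size - 1L, n)]
        g <- NULL
        for (i in idx) {
          fwd <- cnn_forward_matrix(spec, weights, tr$x[, , i],
                                    keep_cache = TRUE)
          bk <- cnn_backward_matrix(spec, weights, fwd, tr$y[i])
          g <- add_grads(g, bk$grads)
          ep_loss <- ep_loss + bk$loss
        }
        g <- scale_grads(g, 1 / length(idx))
        if (control$weight_decay > 0) {
          for (l in seq_along(g$conv))
            g$conv[[l]]$w <- g$conv[[l]]$w +
              control$weight_decay * weights$conv[[l]]$w
          g$fc$w <- g$fc$w + control$weight_decay * weights$fc$w
        }
        t_step <- t_step + 1L
        upd <- adam_step(weights, g, state, lr, t_step)
        weights <- upd$weights
        state <- upd$state
      }
      acc <- if (!is.null(val)) model_accuracy(spec, weights, val$x, val$y)
             else model_accuracy(spec, weights, tr$x, tr$y)
      history[[epoch]] <- c(epoch = epoch, loss = ep_loss / n,
                            val_acc = acc, lr = lr)
      # checkpoint the best-validation weights; among epochs tied at the
      # best accuracy prefer the latest (most-trained) weights, but only a
      # strict improvement resets the patience counters
      if (acc > best$acc + 1e-12) {
        best <- list(acc = acc, weights = weights, epoch = epoch)
        no_improve <- 0L
      } else {
        if (acc >= best$acc - 1e-12)
          best <- list(acc = best$acc, weights = weights, epoch = epoch)
        no_improve <- no_improve + 1L
        # the dynamic learning rate engages once the mandatory-epoch
        # phase is over; before that the rate stays at lr_init so an
        # early lucky validation score cannot starve the optimizer
        if (no_improve %% control$lr_patience == 0L &&
            epoch >= control$min_epochs)
          lr <- lr * (1 - control$lr_decay_factor)
      }
      if (epoch >= control$min_epochs && no_improve >= control$stop_patience)
        break
    }
    structure(list(
      spec = spec, weights = best$weights, classes = tr$classes,
      history = as.data.frame(do.call(rbind, history)),
      best_epoch = best$epoch, best_val_acc = best$acc,
      control = control, n_train = n
    ), class = "mf_cnn")
  })
}

#' Predict MF classes or probabilities for fused segments
#'
#' @param object A fitted [mf_cnn()].
#' @param newdata A `fused_segments` object, a `channels x samples x n`
#'   array, or a single `channels x samples` matrix.
#' @param type `"class"` for predicted labels, `"prob"` for the softmax
#'   probability matrix.
#' @param ... Unused.
#' @return Factor of predicted classes, or an `n x n_classes` probability
#'   matrix.  Argmax ties resolve to the lower class index.
#' @export
predict.mf_cnn <- function(object, newdata,
                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "fused_segments")) newdata$segments else newdata
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  probs <- t(vapply(seq_len(dim(x)[3]), function(i)
    cnn_forward_matrix(object$spec, object$weights, x[, , i]),
    numeric(object$spec$n_classes)))
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.mf_cnn <- function(x, ...) {
  cat(sprintf("<mf_cnn> %d-layer CNN (%s filters), %d channels x %d cols -> %d classes\n",
              x$spec$n_layers, paste(x$spec$conv_filters, collapse = "/"),
              x$spec$n_channels, x$spec$input_cols, x$spec$n_classes))
  cat(sprintf("  trained %d epochs on %d segments; best val acc %.3f (epoch %d)\n",
              nrow(x$history), x$n_train, x$best_val_acc, x$best_epoch))
  invisible(x)
}

#' @export
summary.mf_cnn <- function(object, ...) {
  n_par <- sum(vapply(object$weights$conv,
                      function(l) length(l$w) + length(l$b), 0)) +
    length(object$weights$fc$w) + length(object$weights$fc$b)
  cat(sprintf("Convolutional MF classifier: %d parameters\n", n_par))
  print(object)
  cat("  learning-rate trajectory:",
      paste(sprintf("%.2g", unique(object$history$lr)), collapse = " -> "),
      "\n")
  invisible(object)
}

#' @export
coef.mf_cnn <- function(object, ...) object$weights

#' @export
plot.mf_cnn <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$val_acc, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation accuracy",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}

# stratified random 60/20/20 split; every partition must receive at least
# one segment of every class
stratified_split <- function(y_idx, split) {
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in unique(y_idx)) {
    idx <- sample(which(y_idx == cl))
    n <- length(idx)
    n_tr <- floor(split[["train"]] * n)
    n_va <- floor(split[["val"]] * n)
    n_te <- n - n_tr - n_va
    if (n_tr < 1 || n_va < 1 || n_te < 1)
      stop("split too small: class with ", n,
           " segments cannot fill train/val/test", call. = FALSE)
    parts$train <- c(parts$train, idx[seq_len(n_tr)])
    parts$val <- c(parts$val, idx[n_tr + seq_len(n_va)])
    parts$test <- c(parts$test, idx[n_tr + n_va + seq_len(n_te)])
  }
  parts
}

# contiguous per-class split with a fold-dependent circular offset:
# controls leakage through the 2 s segment overlap
block_split <- function(y_idx, split, fold) {
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in unique(y_idx)) {
    idx <- which(y_idx == cl)           # already time-ordered
    n <- length(idx)
    off <- ((fold - 1L) * max(1L, n %/% 5L)) %% n
    idx <- idx[((seq_len(n) - 1L + off) %% n) + 1L]
    n_tr <- floor(split[["train"]] * n)
    n_va <- floor(split[["val"]] * n)
    n_te <- n - n_tr - n_va
    if (n_tr < 1 || n_va < 1 || n_te < 1)
      stop("split too small: class with ", n,
           " segments cannot fill train/val/test", call. = FALSE)
    parts$train <- c(parts$train, idx[seq_len(n_tr)])
    parts$val <- c(parts$val, idx[n_tr + seq_len(n_va)])
    parts$test <- c(parts$test, idx[n_tr + n_va + seq_len(n_te)])
  }
  parts
}

#' Monte-Carlo cross-validated training
#'
#' Runs `control$folds` independent seeded stratified 60/20/20
#' train/validation/test splits of the labeled segments.  In each fold a
#' per-channel normalizer is fitted on that fold's training subset only,
#' applied to all three partitions, the network is trained with
#' [mf_cnn()] and the restored best-validation weights are scored on the
#' held-out test segments.  Reported as mean and standard deviation of
#' the per-fold test accuracies.
#'
#' @param segments A labeled `fused_segments` object (see
#'   [assign_labels()]); only `low`/`high` segments are used.
#' @param spec A [model_spec()]; defaults to [demo_model_spec()] sized to
#'   the input.
#' @param control A [train_config()].
#' @param normalize Fit/apply the per-channel normalizer inside each fold
#'   (default TRUE; set FALSE if `segments` are already normalized).
#' @return An `mf_cv` object: per-fold results, `mean_acc`, `sd_acc`, and
#'   `best_model`/`best_normalizer` from the fold with the highest
#'   validation accuracy.
#' @export
train_cv <- function(segments, spec = NULL, control = train_config(),
                     normalize = TRUE) {
  stopifnot(inherits(segments, "fused_segments"),
            inherits(control, "train_config"))
  if (is.null(segments$labels)) stop("segments are unlabeled", call. = FALSE)
  lab <- labeled_subset(segments)
  tr <- as_training_xy(lab)
  if (length(unique(tr$y)) < 2L)
    stop("need at least 2 labeled classes", call. = FALSE)
  if (is.null(spec))
    spec <- demo_model_spec(n_channels = dim(tr$x)[1],
                            input_cols = dim(tr$x)[2],
                            n_classes = length(tr$classes))
  folds <- vector("list", control$folds)
  best <- list(val = -Inf, model = NULL, normalizer = NULL)
  for (f in seq_len(control$folds)) {
    fold_seed <- control$seed + 7919L * f
    parts <- with_seed(fold_seed, {
      if (control$split_mode == "random") stratified_split(tr$y, control$split)
      else block_split(tr$y, control$split, f)
    })
    seg_tr <- subset_segments(lab, parts$train)
    seg_va <- subset_segments(lab, parts$val)
    seg_te <- subset_segments(lab, parts$test)
    norm <- NULL
    if (normalize) {
      norm <- fit_normalizer(seg_tr)
      seg_tr <- apply_normalizer(seg_tr, norm)
      seg_va <- apply_normalizer(seg_va, norm)
      seg_te <- apply_normalizer(seg_te, norm)
    }
    fold_control <- control
    fold_control$seed <- fold_seed
    fit <- mf_cnn(seg_tr, spec = spec, control = fold_control,
                  validation = list(x = seg_va, y = seg_va$labels))
    te <- as_training_xy(seg_te, classes = fit$classes)
    test_acc <- model_accuracy(spec, fit$weights, te$x, te$y)
    folds[[f]] <- data.frame(fold = f, seed = fold_seed,
                             best_epoch = fit$best_epoch,
                             n_epochs = nrow(fit$history),
                             val_acc = fit$best_val_acc,
                             test_acc = test_acc)
    if (fit$best_val_acc > best$val) {
      best <- list(val = fit$best_val_acc, model = fit, normalizer = norm)
    }
    mf_log("debug", sprintf("fold %d: test acc %.3f", f, test_acc))
  }
  folds <- do.call(rbind, folds)
  structure(list(
    folds = folds,
    mean_acc = mean(folds$test_acc),
    sd_acc = stats::sd(folds$test_acc),
    spec = spec, control = control, classes = tr$classes,
    best_model = best$model, best_normalizer = best$normalizer
  ), class = "mf_cv")
}

#' @export
print.mf_cv <- function(x, digits = 2, ...) {
  cat(sprintf("<mf_cv> %d folds (%s splits)\n", nrow(x$folds),
              x$control$split_mode))
  cat(sprintf("  Test acc (avg +/- std): %.*f +/- %.*f\n",
              digits, x$mean_acc, digits,
              if (is.na(x$sd_acc)) 0 else x$sd_acc))
  invisible(x)
}

#' Format a cross-validation report as a text table
#'
#' One row per fold plus the aggregate "avg +/- std" line.
#'
#' @param report An `mf_cv` object.
#' @param digits Decimal places for accuracies.
#' @return Character vector of table lines.
#' @export
format_cv_report <- function(report, digits = 2) {
  stopifnot(inherits(report, "mf_cv"))
  c("fold\ttest_acc",
    sprintf("%d\t%.*f", report$folds$fold, digits, report$folds$test_acc),
    sprintf("avg +/- std\t%.*f +/- %.*f", digits, report$mean_acc,
            digits, if (is.na(report$sd_acc)) 0 else report$sd_acc))
}
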