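# Fitting and cross-validation mechanics on a tiny two-layer model so
# the tests run in seconds; the full demo-scale training lives with the
# end-to-end acceptance checks.

tiny_spec <- function(n_ch = 2) {
  model_spec(n_channels = n_ch, input_cols = 64,
             conv_filters = c(4, 4), conv_kernels = c(3, 5))
}

# amplitude-separable segments: class low has unit noise, class high
# noise with sd `gap`
tiny_labeled_segments <- function(n_per_class = 20, gap = 3, seed = 1) {
  segs <- make_dummy_segments(2 * n_per_class, n_ch = 2, spw = 64,
                              seed = seed)
  hi <- (n_per_class + 1):(2 * n_per_class)
  segs$segments[, , hi] <- segs$segments[, , hi] * gap
  segs$labels <- factor(rep(c("low", "high"), each = n_per_class),
                        levels = c("low", "unknown", "high"))
  segs$window <- window_spec(length_s = 0.5, overlap_s = 0, rate = 128)
  segs
}

test_that("the fitted model separates amplitude-coded classes", {
  segs <- tiny_labeled_segments()
  lab <- mfsense:::labeled_subset(segs)
  norm <- fit_normalizer(lab)
  labn <- apply_normalizer(lab, norm)
  fit <- mf_cnn(labn, spec = tiny_spec(),
                control = train_config(batch_size = 64, lr_init = 1e-2,
                                       min_epochs = 20, max_epochs = 40,
                                       seed = 4))
  expect_s3_class(fit, "mf_cnn")
  expect_gte(fit$best_val_acc, 0.9)   # training-set accuracy here
  pred <- predict(fit, labn)
  expect_gte(mean(pred == labn$labels), 0.9)
})

test_that("the learning rate only ever decays by the configured factor", {
  segs <- tiny_labeled_segments(n_per_class = 10)
  lab <- mfsense:::labeled_subset(segs)
  fit <- mf_cnn(lab, spec = tiny_spec(),
                control = train_config(batch_size = 8, lr_init = 1e-3,
                                       min_epochs = 20, max_epochs = 25,
                                       seed = 2))
  lr <- fit$history$lr
  expect_true(all(diff(lr) <= 0))
  d <- round(log(lr / lr[1]) / log(0.8))
  expect_equal(lr, lr[1] * 0.8^d, tolerance = 1e-12)
})

test_that("identical seeds reproduce identical fits", {
  segs <- tiny_labeled_segments(n_per_class = 8)
  lab <- mfsense:::labeled_subset(segs)
  ctl <- train_config(batch_size = 8, min_epochs = 15, max_epochs = 16,
                      seed = 11)
  f1 <- mf_cnn(lab, spec = tiny_spec(), control = ctl)
  f2 <- mf_cnn(lab, spec = tiny_spec(), control = ctl)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("training rejects degenerate label sets", {
  segs <- tiny_labeled_segments(n_per_class = 8)
  segs$labels[] <- "low"
  expect_error(mf_cnn(mfsense:::labeled_subset(segs), spec = tiny_spec()),
               "2 classes")
  few <- tiny_labeled_segments(n_per_class = 2)
  expect_error(
    train_cv(few, spec = tiny_spec(),
             control = train_config(folds = 2, max_epochs = 16)),
    "split too small")
})

test_that("cross-validation aggregates the configured number of folds", {
  segs <- tiny_labeled_segments(n_per_class = 15)
  cv <- train_cv(segs, spec = tiny_spec(),
                 control = train_config(folds = 3, batch_size = 32,
                                        lr_init = 1e-2, min_epochs = 15,
                                        max_epochs = 20, seed = 5))
  expect_s3_class(cv, "mf_cv")
  expect_equal(nrow(cv$folds), 3L)
  expect_true(all(cv$folds$test_acc >= 0 & cv$folds$test_acc <= 1))
  expect_equal(cv$mean_acc, mean(cv$folds$test_acc))
  expect_s3_class(cv$best_model, "mf_cnn")
  expect_s3_class(cv$best_normalizer, "segment_normalizer")
  rep_lines <- format_cv_report(cv)
  expect_match(rep_lines[length(rep_lines)], "avg \\+/- std")
})

test_that("block splits keep each partition contiguous within a class", {
  y <- rep(c(1L, 2L), each = 20)
  parts <- mfsense:::block_split(y, c(train = 0.6, val = 0.2, test = 0.2),
                                 fold = 1)
  expect_length(parts$train, 24)
  expect_length(parts$val, 8)
  expect_length(parts$test, 8)
  expect_length(intersect(parts$train, parts$test), 0)
  # class-1 training indices form one circular run
  tr1 <- sort(parts$train[parts$train <= 20])
  gaps <- diff(tr1)
  expect_lte(sum(gaps > 1), 1)
})
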