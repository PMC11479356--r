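test_that("the residual network is small and yields proper probabilities", {
  m <- build_model(model_config(n_classes = 12, seed = 3))
  expect_lt(n_params(m), 100000)
  f <- clip_mel(synth_clip("microwave", 1, seed = 1))
  p <- predict(m, f, type = "prob")
  expect_equal(ncol(p), 12)
  expect_equal(sum(as.matrix(p)), 1, tolerance = 1e-6)
  expect_true(all(as.matrix(p) >= 0))

  m2 <- build_model(model_config(n_classes = 12, seed = 3))
  expect_identical(m$params, m2$params) # seeded init
  m3 <- build_model(model_config(n_classes = 12, seed = 4))
  expect_false(identical(m$params, m3$params))
})

test_that("training reduces loss on a separable three-class toy", {
  labs <- c("watering1", "hitting", "speech")
  pool <- synth_pool(n_per_label = 40, seed = 31, labels = labs)
  fit <- train_cnn(
    build_model(model_config(n_classes = 3, epochs = 3, seed = 7)),
    pool$feature, pool$label
  )
  h <- tidy(fit)
  expect_equal(nrow(h), 3)
  expect_true(all(diff(h$loss) < 0.02)) # non-increasing up to noise
  expect_gt(h$accuracy[3], h$accuracy[1])
  g <- glance(fit)
  expect_equal(g$epochs, 3)
})

test_that("shuffled labels train to chance accuracy", {
  pool <- shared_train_pool()
  idx <- unlist(lapply(split(seq_len(nrow(pool)), pool$label), `[`, 1:40))
  shuffled <- withr::with_seed(5, sample(pool$label[idx]))
  fit <- train_cnn(
    build_model(model_config(n_classes = 12, epochs = 1, seed = 7)),
    pool$feature[idx], shuffled
  )
  test <- shared_test_pool()
  acc <- evaluate_model(fit, test$feature, test$label)$accuracy
  expect_lt(abs(acc - 1 / 12), 0.05)
})

test_that("evaluation metrics equal a hand-rolled confusion oracle", {
  levels <- c("a", "b", "c")
  truth <- c(
    "a", "a", "a", "a", "b", "b", "b", "b", "b", "c",
    "c", "c", "c", "c", "c", "a", "b", "c", "a", "b"
  )
  pred <- c(
    "a", "a", "b", "c", "b", "b", "b", "a", "c", "c",
    "c", "c", "a", "b", "c", "a", "b", "b", "a", "b"
  )
  probs <- matrix(0.05, nrow = 20, ncol = 3, dimnames = list(NULL, levels))
  probs[cbind(1:20, match(pred, levels))] <- 0.9
  ev <- adlsound:::evaluate_predictions(probs, truth, levels)

  # independent oracle: count every cell with explicit loops
  cm <- matrix(0L, 3, 3, dimnames = list(levels, levels))
  for (i in 1:20) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  expect_equal(unclass(ev$confusion), unclass(cm), ignore_attr = TRUE)
  expect_equal(ev$accuracy, sum(diag(cm)) / 20)
  f1s <- numeric(3)
  for (k in 1:3) {
    tp <- cm[k, k]
    f1s[k] <- 2 * tp / (2 * tp + (sum(cm[, k]) - tp) + (sum(cm[k, ]) - tp))
  }
  expect_equal(ev$macro_f1, mean(f1s))
})

test_that("degenerate predictors score as expected", {
  levels <- c("a", "b", "c", "d")
  truth <- rep(levels, each = 5)
  perfect <- matrix(0.01, 20, 4, dimnames = list(NULL, levels))
  perfect[cbind(1:20, match(truth, levels))] <- 0.97
  ev <- adlsound:::evaluate_predictions(perfect, truth, levels)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$macro_f1, 1)

  constant <- matrix(0.1, 20, 4, dimnames = list(NULL, levels))
  constant[, 1] <- 0.7
  ev2 <- adlsound:::evaluate_predictions(constant, truth, levels)
  expect_equal(ev2$accuracy, 0.25)
})

test_that("metrics are invariant to consistent class permutation", {
  levels <- c("a", "b", "c")
  truth <- rep(levels, times = c(4, 3, 5))
  probs <- withr::with_seed(8, {
    p <- matrix(stats::rexp(36), 12, 3)
    p / rowSums(p)
  })
  colnames(probs) <- levels
  ev <- adlsound:::evaluate_predictions(probs, truth, levels)
  perm <- c(3, 1, 2)
  ev_p <- adlsound:::evaluate_predictions(
    probs[, perm], truth, levels[perm]
  )
  expect_equal(ev$accuracy, ev_p$accuracy)
  expect_equal(ev$macro_f1, ev_p$macro_f1)
  expect_equal(ev$loss, ev_p$loss)
})

test_that("int8 weights stay in range and near their float source", {
  qm <- shared_quant_model()
  fit <- shared_model()
  folded <- adlsound:::fold_bn(fit)
  for (nm in names(qm$weights_int)) {
    q <- qm$weights_int[[nm]]
    s <- qm$weight_scale[[nm]]
    expect_true(all(q >= -128 & q <= 127))
    expect_lte(max(abs(q * s - folded[[nm]])), s / 2 + 1e-12)
  }
})

test_that("quantized inference accepts quantized features", {
  qm <- shared_quant_model()
  test <- shared_test_pool()
  f <- test$feature[[1]]
  qf <- quantize_feature(
    f, qm$feature_qparams$scale,
    qm$feature_qparams$zero_point
  )
  p1 <- predict(qm, f, type = "prob")
  p2 <- predict(qm, qf, type = "prob")
  expect_equal(as.matrix(p1), as.matrix(p2), tolerance = 1e-12)
})

test_that("resampling and augmentation each help on imbalanced data", {
  labs <- c("watering1", "hitting", "microwave", "speech")
  test <- synth_pool(n_per_label = 30, seed = 500, labels = labs)
  counts <- c(watering1 = 120, hitting = 12, microwave = 8, speech = 6)
  run <- function(cond, seed) {
    pool <- synth_pool(n_per_label = 120, seed = seed, labels = labs)
    pool <- dplyr::bind_rows(lapply(labs, function(l) {
      rows <- pool[pool$label == l, ]
      rows[seq_len(counts[[l]]), ]
    }))
    if (cond != "none") {
      pool <- dplyr::bind_rows(lapply(labs, function(l) {
        balance_label(pool[pool$label == l, ],
          target = 120, seed = seed,
          label = l
        )
      }))
    }
    feats <- pool$feature
    y <- pool$label
    if (cond == "resaug") {
      aug <- purrr::imap(feats, ~ augment_mask(.x, seed = seed * 1000 + .y))
      feats <- c(feats, purrr::flatten(aug))
      y <- c(y, rep(y, each = 2))
    }
    fit <- train_cnn(build_model(model_config(
      n_classes = 4, epochs = 3,
      batch_size = 32, seed = seed
    )), feats, y)
    evaluate_model(fit, test$feature, test$label)$accuracy
  }
  accs <- vapply(1:3, function(s) {
    c(run("none", s), run("res", s), run("resaug", s))
  }, numeric(3))
  expect_lt(mean(accs[1, ]), mean(accs[2, ]))
  expect_lte(mean(accs[2, ]), mean(accs[3, ]) + 0.02)
})
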