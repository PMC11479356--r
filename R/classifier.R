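#' Model configuration for the residual sound classifier
#'
#' A small ResNet-style network over 48 x 32 x 1 log-Mel inputs: a 3 x 3
#' convolution stem, three residual stages (one identity block each: two
#' 3 x 3 convolutions with a skip projection) with stride-2 downsampling at
#' stage entry, global average pooling, and a softmax output. The default
#' widths (8, 8/16/32) put the parameter count in the low tens of thousands,
#' the regime a microcontroller deployment needs.
#'
#' @param n_classes Number of output classes (>= 2).
#' @param widths Integer vector: stem width followed by one width per stage.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience on validation loss (epochs);
#'   only used when a validation set is supplied.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A `model_config` list.
#' @export
model_config <- function(n_classes = 12L, widths = c(8L, 8L, 16L, 32L),
                         epochs = 30L, batch_size = 64L, lr = 1e-3,
                         patience = 5L, seed = 1L) {
  stopifnot(n_classes >= 2L, length(widths) >= 2L, all(widths >= 1L))
  structure(
    list(
      n_classes = as.integer(n_classes), widths = as.integer(widths),
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      lr = lr, patience = as.integer(patience), seed = as.integer(seed),
      h = 48L, w = 32L
    ),
    class = "model_config"
  )
}

conv_defs <- function(config) {
  widths <- config$widths
  defs <- list(list(name = "conv0", cin = 1L, cout = widths[1], k = 3L))
  cin <- widths[1]
  for (s in seq_len(length(widths) - 1L)) {
    co <- widths[s + 1L]
    p <- paste0("s", s)
    defs <- c(defs, list(
      list(name = paste0(p, "a"), cin = cin, cout = co, k = 3L),
      list(name = paste0(p, "b"), cin = co, cout = co, k = 3L),
      list(name = paste0(p, "p"), cin = cin, cout = co, k = 1L)
    ))
    cin <- co
  }
  defs
}

bn_names <- function(config) {
  c("bn0", purrr::map(
    seq_len(length(config$widths) - 1L),
    ~ paste0("s", .x, c("a", "b", "p"))
  ) |> unlist())
}

bn_width <- function(nm, config) {
  widths <- config$widths
  if (nm == "bn0") {
    return(widths[1])
  }
  widths[as.integer(substr(nm, 2, 2)) + 1L]
}

#' Build an untrained classifier
#'
#' Initializes weights (He-scaled normal, seeded) for the architecture
#' described in [model_config()].
#'
#' @param config A [model_config()].
#' @return An `adl_cnn` object (untrained).
#' @export
#' @examples
#' m <- build_model(model_config(n_classes = 3))
#' n_params(m)
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  params <- withr::with_seed(config$seed, {
    p <- list()
    for (d in conv_defs(config)) {
      fan_in <- d$cin * d$k^2
      p[[paste0(d$name, "_w")]] <- matrix(
        stats::rnorm(d$cout * fan_in, sd = sqrt(2 / fan_in)),
        nrow = d$cout
      )
    }
    feat <- config$widths[length(config$widths)]
    p$fc_w <- matrix(stats::rnorm(config$n_classes * feat,
      sd = sqrt(1 / feat)
    ), nrow = config$n_classes)
    p$fc_b <- numeric(config$n_classes)
    for (nm in bn_names(config)) {
      wd <- bn_width(nm, config)
      p[[paste0(nm, "_g")]] <- rep(1, wd)
      p[[paste0(nm, "_b")]] <- numeric(wd)
    }
    p
  })
  running <- list()
  for (nm in bn_names(config)) {
    wd <- bn_width(nm, config)
    running[[paste0(nm, "_m")]] <- numeric(wd)
    running[[paste0(nm, "_v")]] <- rep(1, wd)
  }
  structure(
    list(
      params = params, running = running, config = config,
      arch = list(
        widths = config$widths, n_classes = config$n_classes,
        h = config$h, w = config$w
      ),
      levels = NULL, history = NULL
    ),
    class = "adl_cnn"
  )
}

#' Number of trainable parameters
#' @param model An `adl_cnn`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(purrr::map_int(model$params, length))
}

#' @export
print.adl_cnn <- function(x, ...) {
  cat(sprintf(
    "<adl_cnn> residual CNN, widths %s, %d classes, %d parameters%s\n",
    paste(x$config$widths, collapse = "/"), x$config$n_classes,
    n_params(x),
    if (is.null(x$history)) " (untrained)" else sprintf(
      " (trained %d epochs)", nrow(x$history)
    )
  ))
  invisible(x)
}

# fixed input normalization: dB values (floor -80, max 0) to approx [-1, 1]
features_to_cube <- function(features, h = 48L, w = 32L) {
  b <- length(features)
  x <- array(0, dim = c(h, w, b))
  for (i in seq_len(b)) x[, , i] <- (features[[i]] + 40) / 40
  x
}

#' Train the residual classifier
#'
#' Mini-batch Adam with seeded shuffling, batch-norm running-statistic
#' tracking, and optional early stopping on validation loss. Reproducible
#' given the config seed.
#'
#' @param model An `adl_cnn` from [build_model()].
#' @param features List of 48 x 32 log-Mel matrices.
#' @param labels Character or factor labels, one per feature.
#' @param valid_features,valid_labels Optional held-out set monitored per
#'   epoch (never trained on; augmentation should be applied to the training
#'   split only).
#' @param verbose Print per-epoch progress?
#' @return The trained `adl_cnn`, with a `history` tibble (per-epoch
#'   accuracy, cross-entropy loss, and macro F1 where a validation set is
#'   given).
#' @export
train_cnn <- function(model, features, labels, valid_features = NULL,
                      valid_labels = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "adl_cnn"), length(features) == length(labels))
  levels <- sort(unique(as.character(labels)))
  if (length(levels) != model$config$n_classes) {
    stop(
      "training labels cover ", length(levels), " classes but the model has ",
      model$config$n_classes, " outputs",
      call. = FALSE
    )
  }
  y <- match(as.character(labels), levels) - 1L
  model$levels <- levels
  cfg <- model$config
  x_all <- features_to_cube(features, cfg$h, cfg$w)
  n <- length(y)

  adam_m <- purrr::map(model$params, ~ .x * 0)
  adam_v <- purrr::map(model$params, ~ .x * 0)
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  t_step <- 0
  momentum <- 0.9

  history <- list()
  best_val <- Inf
  best_state <- NULL
  wait <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    order <- withr::with_seed(
      derive_seed(cfg$seed, epoch),
      sample.int(n)
    )
    ep_loss <- 0
    ep_acc <- 0
    n_batches <- 0L
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- order[b0:min(b0 + cfg$batch_size - 1L, n)]
      if (length(idx) < 2L) next # batch norm needs >= 2 samples
      res <- cnn_fwd_bwd(
        model$params, x_all[, , idx, drop = FALSE],
        y[idx], model$arch
      )
      t_step <- t_step + 1
      lr_t <- cfg$lr * sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
      for (nm in names(res$grads)) {
        g <- res$grads[[nm]]
        if (is.null(dim(model$params[[nm]]))) g <- as.numeric(g)
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
        model$params[[nm]] <- model$params[[nm]] -
          lr_t * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
      }
      for (nm in names(res$bn_mean)) {
        model$running[[paste0(nm, "_m")]] <-
          momentum * model$running[[paste0(nm, "_m")]] +
          (1 - momentum) * as.numeric(res$bn_mean[[nm]])
        model$running[[paste0(nm, "_v")]] <-
          momentum * model$running[[paste0(nm, "_v")]] +
          (1 - momentum) * as.numeric(res$bn_var[[nm]])
      }
      ep_loss <- ep_loss + res$loss
      ep_acc <- ep_acc + res$acc
      n_batches <- n_batches + 1L
    }
    row <- tibble::tibble(
      epoch = epoch,
      loss = ep_loss / n_batches,
      accuracy = ep_acc / n_batches
    )
    if (!is.null(valid_features)) {
      ev <- evaluate_model(model, valid_features, valid_labels)
      row$val_loss <- ev$loss
      row$val_accuracy <- ev$accuracy
      row$val_macro_f1 <- ev$macro_f1
      if (ev$loss < best_val - 1e-6) {
        best_val <- ev$loss
        best_state <- list(params = model$params, running = model$running)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history[[epoch]] <- row
    if (verbose) {
      message(sprintf(
        "epoch %2d: loss %.4f acc %.3f%s", epoch, row$loss, row$accuracy,
        if (!is.null(valid_features)) {
          sprintf(" | val loss %.4f acc %.3f", row$val_loss, row$val_accuracy)
        } else {
          ""
        }
      ))
    }
    if (!is.null(valid_features) && wait >= cfg$patience) break
  }
  if (!is.null(best_state)) {
    model$params <- best_state$params
    model$running <- best_state$running
  }
  model$history <- dplyr::bind_rows(history)
  model
}

#' Predict class probabilities or labels
#'
#' @param object A trained `adl_cnn`.
#' @param features List of 48 x 32 log-Mel matrices (or a single matrix).
#' @param type `"prob"` for a tibble of per-class probabilities, `"class"`
#'   for a character vector of argmax labels.
#' @param batch_size Inference batch size.
#' @param ... Unused.
#' @return Tibble of probabilities (columns = class labels) or a character
#'   vector.
#' @export
predict.adl_cnn <- function(object, features, type = c("prob", "class"),
                            batch_size = 256L, ...) {
  type <- match.arg(type)
  if (is.matrix(features)) features <- list(features)
  probs <- infer_batched(features, batch_size, function(x) {
    cnn_infer(object$params, object$running, x, object$arch)
  }, object$config)
  finish_prediction(probs, object$levels, type)
}

infer_batched <- function(features, batch_size, fn, cfg) {
  chunks <- split(
    seq_along(features),
    ceiling(seq_along(features) / batch_size)
  )
  out <- purrr::map(chunks, function(idx) {
    fn(features_to_cube(features[idx], cfg$h, cfg$w))
  })
  do.call(rbind, out)
}

finish_prediction <- function(probs, levels, type) {
  if (is.null(levels)) levels <- paste0("class", seq_len(ncol(probs)))
  colnames(probs) <- levels
  if (type == "class") {
    levels[max.col(probs, ties.method = "first")]
  } else {
    tibble::as_tibble(probs)
  }
}

# fold batch-norm (running statistics) into the preceding convolution,
# yielding conv weights + per-channel biases
fold_bn <- function(model) {
  eps <- 1e-5
  params <- model$params
  folded <- list(fc_w = params$fc_w, fc_b = params$fc_b)
  bn_of <- function(conv) if (conv == "conv0") "bn0" else conv
  for (d in conv_defs(model$config)) {
    nm <- bn_of(d$name)
    g <- params[[paste0(nm, "_g")]]
    b <- params[[paste0(nm, "_b")]]
    m <- model$running[[paste0(nm, "_m")]]
    v <- model$running[[paste0(nm, "_v")]]
    invstd <- 1 / sqrt(v + eps)
    w <- params[[paste0(d$name, "_w")]] * (g * invstd)
    folded[[paste0(d$name, "_w")]] <- w
    folded[[paste0(d$name, "_bias")]] <- b - g * m * invstd
  }
  folded
}

#' Emulated 8-bit quantized inference path
#'
#' Builds the integer twin of a trained model the way an embedded runtime
#' would: batch norm is folded into the convolutions, weights are quantized
#' per-tensor symmetric int8, and activations are quantized per-tensor affine
#' int8 with scales calibrated from the min/max observed over a calibration
#' set. Input features are consumed through the same affine feature
#' quantization as [quantize_feature()]. Inference emits probabilities like
#' the float path.
#'
#' @param model A trained `adl_cnn`.
#' @param calibration Nonempty list of log-Mel feature matrices.
#' @return An `adl_cnn_quant` object.
#' @export
quantize_model <- function(model, calibration) {
  stopifnot(inherits(model, "adl_cnn"))
  if (!is.list(calibration) || length(calibration) == 0) {
    stop("calibration set must be a nonempty list of features", call. = FALSE)
  }
  folded <- fold_bn(model)
  weights_int <- list()
  weight_scale <- list()
  qparams <- folded
  for (nm in names(folded)) {
    if (!grepl("_w$", nm)) next
    w <- folded[[nm]]
    s <- max(abs(w)) / 127
    if (s == 0) s <- 1e-8
    q <- matrix(pmax(-128, pmin(127, round(w / s))), nrow = nrow(w))
    weights_int[[nm]] <- q
    weight_scale[[nm]] <- s
    qparams[[nm]] <- q * s # dequantized int8 weights used in arithmetic
  }
  feat_q <- calibrate_quantization(calibration)
  # calibrate activation ranges through the folded int8-weight network
  cfg <- model$config
  ranges <- NULL
  chunks <- split(
    seq_along(calibration),
    ceiling(seq_along(calibration) / 256L)
  )
  for (idx in chunks) {
    x <- features_to_cube(purrr::map(calibration[idx], function(f) {
      dequantize_feature(quantize_feature(f, feat_q$scale, feat_q$zero_point))
    }), cfg$h, cfg$w)
    r <- cnn_infer_folded(qparams, x, model$arch, TRUE, NULL, NULL)
    ranges <- if (is.null(ranges)) {
      cbind(r$mins, r$maxs)
    } else {
      cbind(pmin(ranges[, 1], r$mins), pmax(ranges[, 2], r$maxs))
    }
  }
  act_scale <- (ranges[, 2] - ranges[, 1]) / 255
  act_scale[act_scale <= 0] <- 1e-8
  act_zp <- as.integer(pmax(-128, pmin(127, round(-128 - ranges[, 1] /
    act_scale))))
  act_scale[1] <- 0 # input point handled by feature quantization instead
  structure(
    list(
      params = qparams, weights_int = weights_int,
      weight_scale = weight_scale, act_scale = act_scale, act_zp = act_zp,
      feature_qparams = feat_q, arch = model$arch, config = cfg,
      levels = model$levels
    ),
    class = "adl_cnn_quant"
  )
}

#' @export
print.adl_cnn_quant <- function(x, ...) {
  cat(sprintf(
    "<adl_cnn_quant> int8 inference path, %d classes, feature scale %.4g\n",
    x$config$n_classes, x$feature_qparams$scale
  ))
  invisible(x)
}

#' @rdname predict.adl_cnn
#' @export
predict.adl_cnn_quant <- function(object, features, type = c("prob", "class"),
                                  batch_size = 256L, ...) {
  type <- match.arg(type)
  if (is.matrix(features)) features <- list(features)
  if (inherits(features, "quantized_feature")) features <- list(features)
  qp <- object$feature_qparams
  feats <- purrr::map(features, function(f) {
    if (inherits(f, "quantized_feature")) {
      dequantize_feature(f)
    } else {
      dequantize_feature(quantize_feature(f, qp$scale, qp$zero_point))
    }
  })
  probs <- infer_batched(feats, batch_size, function(x) {
    cnn_infer_folded(
      object$params, x, object$arch, FALSE,
      object$act_scale, object$act_zp
    )$probs
  }, object$config)
  finish_prediction(probs, object$levels, type)
}

#' Evaluate a classifier on a held-out set
#'
#' Computes accuracy, mean cross-entropy loss, macro F1 (unweighted mean of
#' per-class F1 over the model's classes) and the confusion matrix.
#'
#' @param model A trained `adl_cnn` or `adl_cnn_quant`.
#' @param features List of feature matrices (disjoint from training).
#' @param labels True labels.
#' @return List with `accuracy`, `loss`, `macro_f1`, `confusion`.
#' @export
evaluate_model <- function(model, features, labels) {
  if (length(features) == 0) stop("empty test set", call. = FALSE)
  probs <- as.matrix(predict(model, features, type = "prob"))
  evaluate_predictions(probs, as.character(labels), colnames(probs))
}

evaluate_predictions <- function(probs, labels, levels) {
  pred <- levels[max.col(probs, ties.method = "first")]
  truth <- factor(labels, levels = levels)
  predf <- factor(pred, levels = levels)
  confusion <- table(truth = truth, predicted = predf)
  p_true <- probs[cbind(seq_along(labels), match(labels, levels))]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  f1 <- purrr::map_dbl(seq_along(levels), function(k) {
    tp <- confusion[k, k]
    fp <- sum(confusion[, k]) - tp
    fn <- sum(confusion[k, ]) - tp
    if (2 * tp + fp + fn == 0) {
      return(NA_real_)
    }
    2 * tp / (2 * tp + fp + fn)
  })
  list(
    accuracy = mean(pred == labels),
    loss = loss,
    macro_f1 = mean(f1, na.rm = TRUE),
    confusion = confusion
  )
}

#' @export
tidy.adl_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has not been trained", call. = FALSE)
  }
  x$history
}

#' @export
glance.adl_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has not been trained", call. = FALSE)
  }
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    n_params = n_params(x),
    epochs = nrow(x$history),
    loss = last$loss,
    accuracy = last$accuracy,
    val_loss = if ("val_loss" %in% names(last)) last$val_loss else NA_real_,
    val_accuracy = if ("val_accuracy" %in% names(last)) {
      last$val_accuracy
    } else {
      NA_real_
    }
  )
}

#' @export
autoplot.adl_cnn <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch",
    names_to = "metric",
    values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
    color = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "epoch", y = NULL,
      title = "training history"
    )
}
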