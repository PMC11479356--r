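# Shared fixtures, built once per test run and memoised: a 12-class training
# pool (500 clips/label), a test pool (100 clips/label) and a residual CNN
# trained on the training pool. Several test files reuse them.

.shared <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.shared[[key]])) .shared[[key]] <- force(expr)
  .shared[[key]]
}

shared_train_pool <- function() {
  memo("train_pool", synth_pool(n_per_label = 500, seed = 20))
}

shared_test_pool <- function() {
  memo("test_pool", synth_pool(n_per_label = 100, seed = 21))
}

shared_model <- function() {
  memo("model", {
    pool <- shared_train_pool()
    train_cnn(
      build_model(model_config(n_classes = 12, epochs = 6, seed = 7)),
      pool$feature, pool$label
    )
  })
}

shared_quant_model <- function() {
  memo("quant_model", {
    pool <- shared_train_pool()
    quantize_model(shared_model(), pool$feature[seq(1, 6000, by = 30)])
  })
}

# ten-minute scripted bathroom session: water events, brushing, ventilation,
# plus transient flushes and impacts, over a ventilation-level noise floor
# that keeps the energy gate open
bathroom_script <- function() {
  session_script(data.frame(
    label = c(
      "watering2", "brushing", "flushing", "hitting", "watering1",
      "peeing", "flushing", "hitting", "brushing", "watering2",
      "airutils", "hitting"
    ),
    onset = c(30, 90, 140, 160, 200, 270, 300, 330, 360, 420, 480, 560),
    duration = c(40, 30, 3.5, 0.3, 40, 20, 3.5, 0.3, 30, 40, 60, 0.3),
    level_db = c(0, 3, 5, 5, 0, 3, 5, 5, 3, 0, 0, 5)
  ), total_duration = 600, noise_floor_db = -10)
}

# brute-force re-count of the voting rule, independent of vote()
oracle_vote <- function(p, threshold, kinds) {
  n <- nrow(p)
  out <- list()
  for (j in seq_len(ncol(p))) {
    cnt <- 0L
    supra <- c()
    for (i in seq_len(n)) {
      if (p[i, j] > threshold) {
        cnt <- cnt + 1L
        supra <- c(supra, p[i, j])
      }
    }
    if (kinds[j] == "instant") {
      occ <- cnt >= 1L
      conf <- if (occ) sum(supra) / length(supra) else 0
    } else {
      occ <- cnt > n / 2
      conf <- if (occ) sum(p[, j]) / n else 0
    }
    out[[j]] <- c(count = cnt, occurred = occ, confidence = conf)
  }
  do.call(rbind, out)
}
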