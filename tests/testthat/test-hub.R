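test_that("node config validates and round-trips through YAML", {
  node <- node_config(name = "bath1", location = "bathroom")
  expect_false("tv" %in% node$allowed_labels) # location exclusion applied
  expect_true("flushing" %in% node$allowed_labels)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_node_config(node, f)
  back <- read_node_config(f)
  expect_equal(back$location, "bathroom")
  expect_setequal(back$allowed_labels, node$allowed_labels)
  expect_equal(back$post$window_size, node$post$window_size)
  expect_error(node_config(allowed_labels = "doorbell"), "class list")
})

test_that("merged logs are a chronologically sorted permutation", {
  mk <- function(loc, n, seed) {
    withr::with_seed(seed, tibble::tibble(
      label = sample(adl_labels(), n, replace = TRUE),
      start_time = stats::runif(n, 0, 500),
      end_time = NA_real_, duration = 1, location = loc,
      confidence = stats::runif(n), event_count = 1L
    ))
  }
  logs <- list(mk("bathroom", 100, 1), mk("kitchen", 100, 2), mk("living", 100, 3))
  merged <- merge_logs(logs)
  expect_equal(nrow(merged), 300)
  expect_true(!is.unsorted(merged$start_time))
  all_starts <- sort(unlist(purrr::map(logs, "start_time")))
  expect_equal(merged$start_time, all_starts) # permutation, sort oracle
  one <- merge_logs(logs[1])
  expect_equal(nrow(one), 100)
  expect_setequal(one$start_time, logs[[1]]$start_time)
  expect_equal(merge_logs(list(
    mk("a", 1, 4) |> dplyr::mutate(start_time = 3),
    mk("b", 1, 5) |> dplyr::mutate(start_time = 1)
  ))$start_time, c(1, 3))
  expect_error(merge_logs(list(data.frame(x = 1))), "start_time")
})

test_that("log scoring counts overlap matches one-to-one", {
  truth <- tibble::tibble(
    label = c("watering1", "brushing", "hitting"),
    start = c(10, 50, 80), end = c(30, 70, 80.3)
  )
  exact <- tibble::tibble(
    label = truth$label, start_time = truth$start,
    end_time = truth$end, location = "bathroom"
  )
  s <- score_log(exact, truth)
  expect_equal(s$precision, 1)
  expect_equal(s$recall, 1)
  expect_equal(s$f1, 1)

  empty <- exact[0, ]
  expect_equal(score_log(empty, truth)$recall, 0)

  # one detection missing, one spurious record added
  partial <- tibble::tibble(
    label = c("watering1", "hitting", "speech"),
    start_time = c(12, 79.9, 100), end_time = c(28, 80.4, 110),
    location = "bathroom"
  )
  s2 <- score_log(partial, truth)
  expect_equal(s2$tp, 2L)
  expect_equal(s2$precision, 2 / 3)
  expect_equal(s2$recall, 2 / 3)

  # background records are ignored by default
  with_bg <- dplyr::bind_rows(exact, tibble::tibble(
    label = "background", start_time = 0, end_time = 100,
    location = "bathroom"
  ))
  expect_equal(score_log(with_bg, truth)$precision, 1)
})

test_that("activity logs round-trip through CSV and JSONL", {
  log <- tibble::tibble(
    label = c("watering2", "hitting"), start_time = c(1.5, 9),
    end_time = c(20.5, 9.5), duration = c(19, 0.5),
    location = "bathroom", confidence = c(0.93, 0.7), event_count = c(30L, 1L)
  )
  for (fmt in c("csv", "jsonl")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_activity_log(log, f, format = fmt)
    back <- read_activity_log(f, format = fmt)
    expect_equal(back$label, log$label)
    expect_equal(back$start_time, log$start_time)
    expect_equal(back$confidence, log$confidence)
  }
})

test_that("a silent recording produces an empty activity log", {
  node <- node_config(location = "bathroom")
  log <- run_node(audio_clip(numeric(8 * 16000)), node, shared_model())
  expect_equal(nrow(log), 0)
  expect_error(run_node(audio_clip(numeric(16000)), node, "not a model"),
    "model"
  )
})

test_that("node runs are deterministic and find a scripted event", {
  sc <- session_script(
    data.frame(label = "watering2", onset = 6, duration = 20, level_db = 0),
    total_duration = 40, noise_floor_db = -10
  )
  sess <- synth_session(sc, seed = 44)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(sess$clip, f)
  node <- node_config(location = "bathroom")
  log1 <- run_node(f, node, shared_model())
  log2 <- run_node(f, node, shared_model())
  expect_identical(log1, log2)
  w <- log1[log1$label == "watering2", ]
  expect_equal(nrow(w), 1)
  expect_lt(w$start_time, 26)
  expect_gt(w$end_time, 6)
  # the activity interval overlaps the scripted one substantially
  ov <- min(w$end_time, 26) - max(w$start_time, 6)
  expect_gte(ov, 10)
})

test_that("a full scripted bathroom session reconstructs its events", {
  node <- node_config(location = "bathroom")
  f1 <- numeric(3)
  for (seed in 1:3) {
    sess <- synth_session(bathroom_script(), seed = seed)
    log <- run_node(sess$clip, node, shared_model())
    f1[seed] <- score_log(log, sess$truth)$f1
    if (seed == 1) {
      # every scripted event >= 3 s yields exactly one overlapping activity
      long_truth <- sess$truth[sess$truth$end - sess$truth$start >= 3, ]
      for (i in seq_len(nrow(long_truth))) {
        hits <- log[log$label == long_truth$label[i] &
          log$start_time < long_truth$end[i] &
          log$end_time > long_truth$start[i], ]
        expect_equal(nrow(hits), 1)
      }
      expect_identical(log$duration, log$end_time - log$start_time)
    }
  }
  expect_gte(min(f1), 0.8)
})
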