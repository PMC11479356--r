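make_stream <- function(p, labels = colnames(p)) {
  tibble::tibble(time = seq(0.5, by = 0.5, length.out = nrow(p))) |>
    dplyr::bind_cols(tibble::as_tibble(p))
}

test_that("windows slide by one frame once the buffer fills", {
  pred <- make_stream(matrix(0.1, 20, 1, dimnames = list(NULL, "tv")))
  expect_length(stream_windows(pred, 7), 14)
  expect_length(stream_windows(pred[1:7, ], 7), 1)
  expect_length(stream_windows(pred[1:6, ], 7), 0)
  shuffled <- pred[c(2, 1, 3:20), ]
  expect_error(stream_windows(shuffled, 7), "increasing")
})

test_that("voting follows the continuous and instant rules", {
  cfg <- post_config()
  w <- make_stream(matrix(c(0.9, 0.9, 0.9, 0.9, 0.9, 0.1, 0.1),
    ncol = 1, dimnames = list(NULL, "watering1")
  ))
  v <- vote(w, cfg)
  expect_true(v$occurred)
  expect_equal(v$count, 5L)
  expect_equal(v$confidence, (5 * 0.9 + 2 * 0.1) / 7)

  # 3 of 7 above threshold fails the strict majority
  w2 <- make_stream(matrix(c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1, 0.1),
    ncol = 1, dimnames = list(NULL, "watering1")
  ))
  expect_false(vote(w2, cfg)$occurred)

  # one supra-threshold frame suffices for an instant label
  w3 <- make_stream(matrix(c(0, 0, 0.8, 0, 0, 0, 0),
    ncol = 1, dimnames = list(NULL, "hitting")
  ))
  v3 <- vote(w3, cfg)
  expect_true(v3$occurred)
  expect_equal(v3$confidence, 0.8)

  # labels are judged independently and may co-occur
  both <- make_stream(cbind(
    watering1 = rep(0.9, 7),
    hitting = c(0, 0.7, 0, 0, 0, 0, 0)
  ))
  v4 <- vote(both, cfg)
  expect_true(all(v4$occurred))
})

test_that("voting equals a brute-force re-count on random windows", {
  cfg <- post_config()
  kinds <- unname(adl_event_types()[adl_labels()])
  withr::with_seed(99, {
    for (rep in 1:1000) {
      p <- matrix(stats::runif(7 * 12), 7, 12,
        dimnames = list(NULL, adl_labels())
      )
      v <- vote(make_stream(p), cfg)
      o <- oracle_vote(p, cfg$threshold, kinds)
      if (!isTRUE(all.equal(v$count, unname(as.integer(o[, "count"])))) ||
        !identical(v$occurred, unname(o[, "occurred"] == 1)) ||
        !isTRUE(all.equal(v$confidence, unname(o[, "confidence"])))) {
        fail(sprintf("vote mismatch at window %d", rep))
      }
    }
    succeed()
  })
})

test_that("raising the threshold never turns continuous events on", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      p <- matrix(stats::runif(7 * 3), 7, 3,
        dimnames = list(NULL, c("watering1", "tv", "speech"))
      )
      v_lo <- vote(make_stream(p), post_config(threshold = 0.3))
      v_hi <- vote(make_stream(p), post_config(threshold = 0.6))
      expect_true(all(v_hi$count <= v_lo$count))
      expect_true(all(v_hi$occurred <= v_lo$occurred))
    }
  })
})

test_that("an instant frame is attributed once across overlapping windows", {
  p <- matrix(0, 20, 1, dimnames = list(NULL, "hitting"))
  p[10, 1] <- 0.9
  ev <- vote_stream(make_stream(p), post_config())
  expect_equal(sum(ev$occurred), 1)
  # attributed at the first window containing frame 10 (window 4, newest = 10)
  expect_equal(ev$window_time[ev$occurred], 10 * 0.5)
})

test_that("tolerance merges short gaps and splits long ones", {
  cfg <- post_config()
  mk <- function(gap) {
    tibble::tibble(
      label = "tv", kind = "continuous",
      occurred = c(rep(TRUE, 5), rep(FALSE, gap), rep(TRUE, 5)),
      confidence = c(rep(0.9, 5), rep(0, gap), rep(0.7, 5)),
      window_time = seq(3.5, by = 0.5, length.out = 10 + gap)
    )
  }
  merged <- accumulate_activities(mk(8), cfg) # gap < tolerance 10
  expect_equal(nrow(merged), 1)
  expect_equal(merged$confidence, mean(c(rep(0.9, 5), rep(0.7, 5))))
  split <- accumulate_activities(mk(12), cfg) # gap > tolerance
  expect_equal(nrow(split), 2)
  expect_equal(split$duration, split$end_time - split$start_time)
})

test_that("activities carry exact duration and mean confidence", {
  conf <- seq(0.8, 0.99, length.out = 20)
  ev <- tibble::tibble(
    label = "watering1", kind = "continuous",
    occurred = c(rep(TRUE, 20), rep(FALSE, 15)),
    confidence = c(conf, rep(0, 15)),
    window_time = seq(3.5, by = 0.5, length.out = 35)
  )
  a <- accumulate_activities(ev, post_config(), location = "bathroom")
  expect_equal(nrow(a), 1)
  expect_equal(a$duration, 9.5)
  expect_identical(a$duration, a$end_time - a$start_time)
  expect_equal(a$confidence, mean(conf))
  expect_equal(a$event_count, 20L)
  expect_equal(a$location, "bathroom")
  # stream end flushes the open activity even without trailing silence
  flush <- accumulate_activities(ev[1:20, ], post_config())
  expect_equal(nrow(flush), 1)
  expect_equal(flush$end_time, ev$window_time[20])
})

test_that("log filtering drops short, weak and disallowed records", {
  recs <- tibble::tibble(
    label = c("tv", "watering1", "hitting", "peeing"),
    start_time = c(1, 2, 3, 4), end_time = c(11, 12, 3.4, 14),
    duration = c(10, 10, 0.4, 10), location = "bathroom",
    confidence = c(0.9, 0.3, 0.9, 0.8), event_count = 5L
  )
  cfg <- post_config(min_duration = 0.5, min_confidence = 0.5)
  kept <- filter_logs(recs, cfg, allowed_labels = setdiff(
    adl_labels(),
    c("tv", "microwave", "cooking")
  ))
  expect_equal(kept$label, "peeing")
  # identity when nothing is constrained
  expect_identical(filter_logs(recs, post_config()), recs)
})

test_that("voting recovers frame-flip noise on continuous streams", {
  labels <- adl_labels()
  n_frames <- 120
  block <- rep(c("watering1", "speech", "microwave", "tv"), each = 30)
  wins <- 0L
  for (seed in 1:20) {
    p <- withr::with_seed(seed, {
      p <- matrix(0.15 / 11, n_frames, 12, dimnames = list(NULL, labels))
      for (i in seq_len(n_frames)) p[i, block[i]] <- 0.85
      flip <- stats::runif(n_frames) < 0.1
      for (i in which(flip)) {
        other <- sample(setdiff(labels, block[i]), 1)
        p[i, ] <- 0.15 / 11
        p[i, other] <- 0.85
      }
      p
    })
    raw_acc <- mean(labels[max.col(p)] == block)
    ev <- vote_stream(make_stream(p), post_config())
    continuous <- names(which(adl_event_types() == "continuous"))
    # judge windows lying fully inside one ground-truth block
    interior <- which(vapply(
      seq_len(n_frames - 6),
      function(w) length(unique(block[w:(w + 6)])) == 1, logical(1)
    ))
    win_acc <- mean(vapply(interior, function(w) {
      e <- ev[ev$window_time == (w + 6) * 0.5 & ev$occurred &
        ev$label %in% continuous, ]
      nrow(e) == 1 && e$label == block[w]
    }, logical(1)))
    if (win_acc > raw_acc) wins <- wins + 1L
  }
  expect_gte(wins, 18)
})
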