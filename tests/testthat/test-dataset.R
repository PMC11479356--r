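test_that("continuous recordings cut into whole one-second segments", {
  segs <- segment_continuous(synth_clip("watering2", 10, seed = 1), "watering2")
  expect_equal(nrow(segs), 10)
  segs2 <- segment_continuous(synth_clip("watering2", 10.7, seed = 1), "watering2")
  expect_equal(nrow(segs2), 10) # 0.7 s remainder dropped
  src <- synth_clip("watering2", 3.2, seed = 5)
  out <- segment_continuous(src, "watering2")
  expect_identical(out$clip[[2]]$samples, src$samples[16001:32000])
  expect_equal(unique(out$event_type), "continuous")
  expect_error(
    segment_continuous(synth_clip("hitting", 0.4, 1), "hitting"),
    "pad_short_event"
  )
})

test_that("short events pad to one second preserving their content", {
  ev <- synth_clip("hitting", 0.3, seed = 2)
  padded <- pad_short_event(ev, "hitting", seed = 10)
  expect_equal(nrow(padded), 1)
  x <- padded$clip[[1]]$samples
  expect_length(x, 16000)
  expect_equal(sum(abs(x)), sum(abs(ev$samples)))
  # different seeds shift the event, not its content
  x2 <- pad_short_event(ev, "hitting", seed = 11)$clip[[1]]$samples
  expect_false(identical(x, x2))
  expect_identical(x[x != 0], x2[x2 != 0])
  expect_error(pad_short_event(synth_clip("tv", 1.5, 1), "tv"), "1 s")
})

test_that("balancing hits the target with fair repetition", {
  pool300 <- as.list(seq_len(300))
  out <- balance_label(pool300, target = 1500, seed = 3)
  expect_length(out, 1500)
  counts <- table(unlist(out))
  expect_true(all(counts == 5)) # 1500/300 exactly

  pool1500 <- as.list(seq_len(1500))
  expect_identical(balance_label(pool1500, 1500, 3), pool1500)

  pool2000 <- as.list(seq_len(2000))
  sub <- balance_label(pool2000, 1500, 3)
  expect_length(sub, 1500)
  expect_equal(length(unique(unlist(sub))), 1500) # without replacement

  # non-divisible oversampling: originals appear floor or ceiling times
  out7 <- balance_label(as.list(seq_len(700)), 1500, 4)
  counts7 <- table(unlist(out7))
  expect_true(all(counts7 %in% c(2, 3)))
  expect_error(balance_label(list(), 1500, 1, label = "peeing"), "peeing")
})

test_that("mask augmentation produces two bounded erasures per clip", {
  f <- clip_mel(synth_clip("cooking", 1, seed = 8))
  aug <- augment_mask(f, seed = 5)
  expect_length(aug, 2)
  for (a in aug) {
    changed <- a != f
    expect_true(all(a[changed] == -80))
    expect_gte(sum(changed), 1) # never a bit-identical copy
    # at most 2 time bands (<=8 frames) and 2 mel bands (<=8 bands)
    expect_lte(sum(changed), 2 * 8 * 48 + 2 * 8 * 32)
  }
  expect_identical(f, clip_mel(synth_clip("cooking", 1, seed = 8))) # untouched
  expect_identical(aug, augment_mask(f, seed = 5)) # seeded
})

test_that("training-set build honours the 1500:250 ratio and augmentation", {
  labs <- c("watering1", "hitting", "speech")
  feat <- function(n, s) {
    lapply(seq_len(n), function(i) {
      matrix(stats::rnorm(48 * 32, sd = 5), 48, 32)
    })
  }
  base <- tibble::tibble(
    label = rep(labs, times = c(40, 30, 35)),
    feature = feat(105)
  )
  domain <- tibble::tibble(
    label = rep("watering1", 12),
    feature = feat(12)
  )
  built <- build_training_set(base, domain,
    seed = 2,
    balance_target = 150, domain_target = 25
  )
  counts <- table(built$label)
  expect_equal(unname(counts[["watering1"]]), (150 + 25) * 3)
  expect_equal(unname(counts[["hitting"]]), 150 * 3)
  expect_equal(unname(counts[["speech"]]), 150 * 3)
  expect_true(all(counts >= 150 * 3))
  man <- dataset_manifest(built)
  expect_false("feature" %in% names(man))
  expect_true(all(man$aug %in% 0:2))
  # augmented rows never duplicate their source feature
  orig <- built$feature[built$aug == 0]
  for (i in which(built$aug > 0)[1:20]) {
    src <- built$feature[built$id == built$id[i - built$aug[i]]][[1]]
    expect_false(identical(built$feature[[i]], src))
  }
  expect_error(
    build_training_set(base[base$label != "speech", ], domain = tibble::tibble(
      label = "speech", feature = feat(1)
    ), seed = 1),
    "missing from base"
  )
})

test_that("splits are disjoint at the source-clip level", {
  base <- tibble::tibble(
    label = rep(c("peeing", "tv"), each = 20),
    feature = lapply(1:40, function(i) matrix(i, 48, 32))
  )
  built <- build_training_set(base,
    seed = 3, balance_target = 60,
    domain_target = 0
  )
  sp <- split_dataset(built, prop = 0.8, seed = 4)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(built))
  expect_length(intersect(sp$train$source_id, sp$test$source_id), 0)
  # deterministic given the seed
  sp2 <- split_dataset(built, prop = 0.8, seed = 4)
  expect_identical(sp$train$id, sp2$train$id)
})
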