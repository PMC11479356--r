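#' Segment a continuous recording into one-second training clips
#'
#' Continuous sounds (running water, appliance hum, ...) are cut into
#' non-overlapping one-second segments; a trailing remainder shorter than one
#' second is dropped. Clips shorter than one second belong to
#' [pad_short_event()] instead.
#'
#' @param clip An [audio_clip()] of duration >= 1 s.
#' @param label Class label.
#' @param origin `"base"` or `"domain"` dataset origin tag.
#' @return Tibble with list-column `clip` plus `label`, `event_type`,
#'   `origin`.
#' @export
#' @examples
#' nrow(segment_continuous(synth_clip("cooking", 3.7, seed = 1), "cooking"))
segment_continuous <- function(clip, label, origin = "base") {
  stopifnot(inherits(clip, "audio_clip"))
  if (length(clip$samples) < 16000L) {
    stop("clip shorter than 1 s; use pad_short_event()", call. = FALSE)
  }
  n_seg <- length(clip$samples) %/% 16000L
  clips <- purrr::map(seq_len(n_seg), function(i) {
    audio_clip(clip$samples[((i - 1L) * 16000L + 1L):(i * 16000L)])
  })
  tibble::tibble(
    clip = clips,
    label = label,
    event_type = unname(adl_event_types()[label]),
    origin = origin
  )
}

#' Pad a short sound event into a one-second training clip
#'
#' Short-duration events (impacts, flushes) yield a single training clip per
#' event: the event is placed at a seeded random offset inside a zero
#' one-second buffer such that it is fully contained.
#'
#' @param clip An [audio_clip()] shorter than 1 s.
#' @param label Class label.
#' @param seed Integer seed for the placement offset.
#' @param origin Dataset origin tag.
#' @return One-row tibble in the [segment_continuous()] layout.
#' @export
pad_short_event <- function(clip, label, seed = 1L, origin = "base") {
  stopifnot(inherits(clip, "audio_clip"))
  n <- length(clip$samples)
  if (n >= 16000L) {
    stop("clip is >= 1 s; use segment_continuous()", call. = FALSE)
  }
  offset <- withr::with_seed(
    as.integer(seed) %% 2147483647L,
    sample.int(16000L - n + 1L, 1L) - 1L
  )
  x <- numeric(16000L)
  x[(offset + 1L):(offset + n)] <- clip$samples
  tibble::tibble(
    clip = list(audio_clip(x)),
    label = label,
    event_type = unname(adl_event_types()[label]),
    origin = origin
  )
}

#' Resample one label's clips to a fixed count
#'
#' Class-imbalance correction. Under-represented labels are oversampled by
#' whole-set repetition plus a seeded random remainder draw, so each original
#' appears either `floor(target/n)` or `ceiling(target/n)` times;
#' over-represented labels are subsampled without replacement; a label already
#' at `target` is returned unchanged.
#'
#' @param clips List (or tibble) of one label's clips/features.
#' @param target Desired count (default 1500).
#' @param seed Integer seed.
#' @param label Label name, used in diagnostics.
#' @return An object of the same kind as `clips` with exactly `target`
#'   elements/rows.
#' @export
#' @examples
#' length(balance_label(as.list(1:300), target = 1500, seed = 1))
balance_label <- function(clips, target = 1500L, seed = 1L, label = NULL) {
  n <- if (is.data.frame(clips)) nrow(clips) else length(clips)
  if (n == 0L) {
    stop("no clips for label ", if (is.null(label)) "<unnamed>" else label,
      call. = FALSE
    )
  }
  idx <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    if (n == target) {
      seq_len(n)
    } else if (n > target) {
      sort(sample.int(n, target))
    } else {
      reps <- target %/% n
      rem <- target - reps * n
      c(rep(seq_len(n), reps), sort(sample.int(n, rem)))
    }
  })
  if (is.data.frame(clips)) clips[idx, , drop = FALSE] else clips[idx]
}

#' Mask-based feature augmentation
#'
#' Produces `n_augment` augmented copies of a log-Mel feature, each with 1-2
#' random contiguous time-frame bands (width <= `max_time_width`) and 1-2
#' random contiguous Mel bands (height <= `max_mel_width`) erased to the dB
#' floor. The original is untouched.
#'
#' @param feature 48 x 32 log-Mel matrix.
#' @param seed Integer seed.
#' @param n_augment Number of augmented copies (default 2).
#' @param max_time_width,max_mel_width Maximum band extents.
#' @param db_floor Fill value for masked cells.
#' @return List of `n_augment` masked feature matrices.
#' @export
augment_mask <- function(feature, seed = 1L, n_augment = 2L,
                         max_time_width = 8L, max_mel_width = 8L,
                         db_floor = -80) {
  stopifnot(is.matrix(feature))
  n_mel <- nrow(feature)
  n_t <- ncol(feature)
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    purrr::map(seq_len(n_augment), function(i) {
      out <- feature
      for (k in seq_len(sample(1:2, 1))) { # time bands
        w <- sample.int(max_time_width, 1)
        s <- sample.int(n_t - w + 1L, 1)
        out[, s:(s + w - 1L)] <- db_floor
      }
      for (k in seq_len(sample(1:2, 1))) { # mel bands
        h <- sample.int(max_mel_width, 1)
        s <- sample.int(n_mel - h + 1L, 1)
        out[s:(s + h - 1L), ] <- db_floor
      }
      out
    })
  })
}

#' Build a balanced, augmented training set
#'
#' Per label: the base pool is resampled to `balance_target` clips and the
#' domain pool (site-specific recordings; may cover only a subset of labels)
#' to `domain_target`, then every resulting clip contributes itself plus
#' `n_augment` mask-augmented copies. A label present in both pools therefore
#' yields `(balance_target + domain_target) * (1 + n_augment)` rows (5250 with
#' defaults) and a base-only label `balance_target * (1 + n_augment)` (4500).
#'
#' @param base Tibble with columns `label` and list-column `feature`
#'   (48 x 32 matrices); must cover every label it claims.
#' @param domain Optional tibble in the same layout; may cover a label subset.
#' @param seed Integer seed.
#' @param balance_target,domain_target Per-label resampling counts.
#' @param n_augment Augmented copies per clip.
#' @param db_floor Mask fill value.
#' @return Tibble (manifest + data) with columns `id`, `label`, `event_type`,
#'   `origin`, `aug` (0 = original, 1..n = augmented copy), `source_id`
#'   (originating clip, shared by oversampled repeats and augmentations) and
#'   list-column `feature`.
#' @export
build_training_set <- function(base, domain = NULL, seed = 1L,
                               balance_target = 1500L, domain_target = 250L,
                               n_augment = 2L, db_floor = -80) {
  stopifnot(is.data.frame(base), all(c("label", "feature") %in% names(base)))
  labels <- unique(base$label)
  if (!is.null(domain)) {
    extra <- setdiff(unique(domain$label), labels)
    if (length(extra)) {
      stop("domain labels missing from base pool: ",
        paste(extra, collapse = ", "),
        call. = FALSE
      )
    }
  }
  types <- adl_event_types()
  pools <- list(
    base = list(data = base, target = balance_target),
    domain = list(data = domain, target = domain_target)
  )
  out <- purrr::imap(pools, function(pool, origin) {
    if (is.null(pool$data)) {
      return(NULL)
    }
    purrr::map(intersect(labels, unique(pool$data$label)), function(lab) {
      rows <- pool$data[pool$data$label == lab, , drop = FALSE]
      rows$source_id <- paste0(origin, "-", lab, "-", seq_len(nrow(rows)))
      balance_label(rows,
        target = pool$target,
        seed = derive_seed(seed, match(lab, labels) +
          1000L * (origin == "domain")), label = lab
      )
    })
  })
  balanced <- dplyr::bind_rows(
    dplyr::bind_rows(out$base) |> dplyr::mutate(origin = "base"),
    if (!is.null(out$domain)) {
      dplyr::bind_rows(out$domain) |> dplyr::mutate(origin = "domain")
    }
  )
  # augmentation after resampling diversifies the oversampled repeats
  expanded <- purrr::pmap(
    list(balanced$feature, seq_len(nrow(balanced))),
    function(feat, i) {
      masked <- augment_mask(feat,
        seed = derive_seed(seed, 7000000L + i),
        n_augment = n_augment, db_floor = db_floor
      )
      c(list(feat), masked)
    }
  )
  n_copies <- n_augment + 1L
  res <- tibble::tibble(
    label = rep(balanced$label, each = n_copies),
    event_type = unname(types[rep(balanced$label, each = n_copies)]),
    origin = rep(balanced$origin, each = n_copies),
    aug = rep(0:n_augment, times = nrow(balanced)),
    source_id = rep(balanced$source_id, each = n_copies),
    feature = purrr::flatten(expanded)
  )
  res$id <- sprintf("clip-%06d", seq_len(nrow(res)))
  res[, c(
    "id", "label", "event_type", "origin", "aug", "source_id",
    "feature"
  )]
}

#' Manifest view of a built training set
#'
#' @param training_set Result of [build_training_set()].
#' @return The manifest tibble (all columns except the feature data).
#' @export
dataset_manifest <- function(training_set) {
  training_set[, setdiff(names(training_set), "feature")]
}

#' Stratified train/test split at the source-clip level
#'
#' All rows derived from one original clip (oversampled repeats and their
#' augmentations) land on the same side of the split, so the test set never
#' contains near-duplicates of training rows.
#'
#' @param pool Tibble with `label` and either `source_id` (a built training
#'   set) or one row per clip.
#' @param prop Training proportion.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(pool, prop = 0.8, seed = 1L) {
  stopifnot(is.data.frame(pool), "label" %in% names(pool))
  key <- if ("source_id" %in% names(pool)) pool$source_id else
    as.character(seq_len(nrow(pool)))
  groups <- tibble::tibble(key = key, label = pool$label) |>
    dplyr::distinct()
  pick <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    groups |>
      dplyr::group_by(.data$label) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(train = dplyr::row_number() <=
        round(prop * dplyr::n())) |>
      dplyr::ungroup()
  })
  train_keys <- pick$key[pick$train]
  list(
    train = pool[key %in% train_keys, , drop = FALSE],
    test = pool[!key %in% train_keys, , drop = FALSE]
  )
}
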