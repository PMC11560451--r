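test_that("channel selection reorders to the canonical montage", {
  set.seed(4)
  sig <- matrix(rnorm(22 * 100), 22)
  rec <- raw_recording(sig)
  expect_identical(select_channels(rec)$signal, rec$signal)

  perm <- sample(22)
  shuffled <- rec
  shuffled$signal <- rec$signal[perm, ]
  shuffled$channel_names <- rec$channel_names[perm]
  rownames(shuffled$signal) <- shuffled$channel_names
  out <- select_channels(shuffled)
  expect_identical(out$channel_names, canonical_channels())
  # index-permutation oracle: row content preserved
  expect_equal(unname(out$signal), unname(rec$signal))

  # case/whitespace/suffix normalization
  messy <- shuffled
  messy$channel_names <- paste0(tolower(messy$channel_names),
                                ifelse(seq_len(22) %% 2 == 0, "-0", ""))
  rownames(messy$signal) <- messy$channel_names
  expect_equal(unname(select_channels(messy)$signal), unname(rec$signal))

  missing <- rec
  keep <- which(rec$channel_names != "FT9-FT10")
  missing$signal <- rec$signal[keep, ]
  missing$channel_names <- rec$channel_names[keep]
  expect_error(select_channels(missing), "FT9-FT10")
})

test_that("band-pass filter has the specified frequency response", {
  fs <- 256
  tt <- seq(1 / fs, 40, by = 1 / fs)
  mid <- seq(length(tt) %/% 4, 3 * length(tt) %/% 4)
  gain_at <- function(f) {
    rec <- raw_recording(matrix(sin(2 * pi * f * tt), 1), fs)
    out <- bandpass(rec)
    sqrt(mean(out$signal[1, mid]^2)) / sqrt(mean(sin(2 * pi * f * tt[mid])^2))
  }
  expect_gt(gain_at(10), 0.95)
  expect_lt(gain_at(10), 1.05)
  expect_lt(gain_at(100), 0.2)

  dc <- bandpass(raw_recording(matrix(1, 1, 40 * fs), fs))
  expect_lt(max(abs(dc$signal[1, mid])), 1e-3)

  expect_error(bandpass(raw_recording(matrix(rnorm(fs), 1), fs),
                        high_hz = 130), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(8)
  rec <- raw_recording(matrix(rnorm(2 * 2048), 2))
  a <- 3.7
  scaled <- rec
  scaled$signal <- a * rec$signal
  expect_equal(bandpass(scaled)$signal, a * bandpass(rec)$signal,
               tolerance = 1e-9)
})

test_that("segmentation enumerates ictal and interictal windows correctly", {
  fs <- 256
  sig <- matrix(rnorm(22 * 10 * fs), 22)
  ictal <- segment_record(raw_recording(sig, fs, list(c(0, 10))))
  expect_equal(n_segments(ictal), 5L)          # starts 0, 1.5, 3, 4.5, 6
  expect_true(all(ictal$labels == 1L))

  inter <- segment_record(raw_recording(sig, fs))
  expect_equal(n_segments(inter), 3L)          # starts 0, 3, 6
  expect_true(all(inter$labels == 0L))

  # slice-equality oracle: each segment equals the corresponding raw slice
  expect_equal(ictal$x[, , 2], sig[, (1.5 * fs + 1):(4.5 * fs)])
  expect_equal(inter$x[, , 3], sig[, (6 * fs + 1):(9 * fs)])

  expect_warning(empty <- segment_record(raw_recording(matrix(rnorm(22 * 2 * fs), 22), fs)),
                 "shorter")
  expect_equal(n_segments(empty), 0L)
})

test_that("windows straddling a seizure boundary are discarded", {
  fs <- 256
  sig <- matrix(rnorm(4 * 20 * fs), 4)
  segs <- segment_record(raw_recording(sig, fs, list(c(7.2, 12.8))))
  # ictal: starts 7.2, 8.7 (10.2 + 3 > 12.8 fails at 11.7? 11.7+... enumerate)
  st_ict <- seq(7.2, 12.8 - 3, by = 1.5)
  st_pre <- seq(0, 7.2 - 3, by = 3)
  st_post <- seq(12.8, 20 - 3, by = 3)
  expect_equal(sum(segs$labels == 1L), length(st_ict))
  expect_equal(sum(segs$labels == 0L), length(st_pre) + length(st_post))
})

test_that("rebalancing keeps ictal segments and subsamples interictal 5:1", {
  segs <- fake_segments(40, 1000)
  out <- rebalance_pool(segs, 5, seed = 2)
  expect_equal(sum(out$labels == 1L), 40L)
  expect_equal(sum(out$labels == 0L), 200L)

  clamped <- rebalance_pool(fake_segments(40, 100), 5, seed = 2)
  expect_equal(sum(clamped$labels == 0L), 100L)

  again <- rebalance_pool(segs, 5, seed = 2)
  expect_identical(out$x, again$x)
  expect_error(rebalance_pool(fake_segments(0, 10) , 5), "no ictal")
})

test_that("patient-specific folds are stratified, disjoint and covering", {
  segs <- fake_segments(40, 60)
  folds <- make_splits(segs, "patient_specific", n_folds = 5L, seed = 3)
  expect_length(folds, 5L)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), seq_len(100))
  for (f in folds) {
    expect_equal(length(f$test), 20L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
    expect_length(intersect(f$train, f$val), 0L)
    # stratification: ictal fraction preserved per fold
    expect_equal(sum(segs$labels[f$test] == 1L), 8L)
  }
  expect_error(make_splits(fake_segments(5, 5, patients = c("A", "B")),
                           "patient_specific"), "single patient")
})

test_that("leave-one-subject-out never leaks the test patient", {
  pats <- rep(sprintf("P%02d", 1:5), each = 20)
  segs <- fake_segments(50, 50, patients = "x", seed = 2)
  segs$patient_ids <- pats
  folds <- make_splits(segs, "patient_independent", seed = 3)
  expect_length(folds, 5L)
  for (i in seq_along(folds)) {
    tp <- attr(folds[[i]], "test_patient")
    expect_true(all(segs$patient_ids[folds[[i]]$test] == tp))
    expect_false(tp %in% segs$patient_ids[folds[[i]]$train])
    expect_false(tp %in% segs$patient_ids[folds[[i]]$val])
  }
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), seq_len(100))

  two <- segs
  two$patient_ids <- rep(c("A", "B"), 50)
  expect_error(make_splits(two, "patient_independent"), ">= 3")
})

test_that("segment serialization round-trips with its JSON sidecar", {
  segs <- fake_segments(5, 10)
  path <- tempfile(fileext = ".rds")
  write_segments(segs, path)
  back <- read_segments(path)
  expect_equal(back$x, segs$x)
  expect_equal(back$labels, segs$labels)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$n_segments, 15L)
})
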