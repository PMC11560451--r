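test_that("generator is deterministic and validates its spec", {
  spec <- synth_spec(duration_s = 20, seizure_intervals = list(c(5, 10)),
                     seed = 11)
  r1 <- generate_recording(spec)
  r2 <- generate_recording(spec)
  expect_identical(r1$signal, r2$signal)
  expect_equal(dim(r1$signal), c(22L, 20 * 256))

  expect_error(synth_spec(duration_s = 10, seizure_intervals = list(c(5, 3))),
               "offset must exceed onset")
  expect_error(synth_spec(duration_s = 10, seizure_intervals = list(c(2, 12))),
               "within")
  expect_error(synth_spec(duration_s = 10,
                          seizure_intervals = list(c(1, 5), c(4, 8))),
               "disjoint")
  expect_error(synth_spec(duration_s = 10, background_corr = 0.5,
                          ictal_sync = 0.3), "ictal_sync")
})

test_that("sample labels mark exactly the seizure intervals", {
  spec <- synth_spec(duration_s = 30, seizure_intervals = list(c(4, 9), c(20, 25)),
                     seed = 3)
  rec <- generate_recording(spec)
  lab <- sample_labels(rec)
  expect_equal(sum(lab), length(unlist(lapply(list(c(4, 9), c(20, 25)),
    function(iv) (floor(iv[1] * 256) + 1):min(ceiling(iv[2] * 256), 30 * 256)))))
  expect_true(all(lab[(4 * 256 + 2):(9 * 256 - 1)] == 1))
  expect_true(all(lab[1:(4 * 256)] == 0))
  expect_true(all(lab[(9 * 256 + 2):(20 * 256)] == 0))
})

test_that("interictal background has the specified inter-channel correlation", {
  rec <- generate_recording(synth_spec(duration_s = 360, background_corr = 0.2,
                                       seed = 5))
  segs <- segment_record(rec)
  expect_gte(n_segments(segs), 100L)
  mean_absrho <- mean(vapply(seq_len(100), function(k) {
    C <- cor(t(segs$x[, , k]))
    mean(abs(C[upper.tri(C)]))
  }, 0))
  expect_lt(abs(mean_absrho - 0.2), 0.05)
})

test_that("degenerate spec (gain 1, sync = background) hides the seizures", {
  rec <- generate_recording(synth_spec(duration_s = 400,
    seizure_intervals = list(c(50, 150), c(200, 300)),
    background_corr = 0.2, ictal_sync = 0.2, ictal_gain = 1, seed = 6))
  segs <- segment_record(rec)
  v <- apply(segs$x, 3, var)
  p <- stats::t.test(v[segs$labels == 1][1:50], v[segs$labels == 0][1:50])$p.value
  expect_gt(p, 0.01)
})

test_that("seizures raise pairwise synchrony above the interictal level", {
  rec <- generate_recording(synth_spec(duration_s = 400,
    seizure_intervals = list(c(50, 150), c(200, 300)),
    background_corr = 0.15, ictal_sync = 0.8, ictal_gain = 3, seed = 7))
  segs <- segment_record(rec)
  mean_rho <- function(k) {
    C <- cor(t(segs$x[, , k]))
    mean(C[upper.tri(C)])
  }
  ict <- vapply(which(segs$labels == 1)[1:50], mean_rho, 0)
  int <- vapply(which(segs$labels == 0)[1:50], mean_rho, 0)
  expect_gt(mean(ict), mean(int))
  expect_gt(mean(ict) - mean(int), 0.2)
})

test_that("cohort generation perturbs parameters and keeps ids unique", {
  base <- synth_spec(duration_s = 15, seizure_intervals = list(c(5, 10)),
                     seed = 2)
  cohort <- generate_cohort(5L, base, variability = 0.2, seed = 9)
  expect_length(cohort, 5L)
  expect_length(unique(vapply(cohort, `[[`, "", "patient_id")), 5L)

  same <- generate_cohort(3L, base, variability = 0, seed = 9)
  # identical parameters, different noise realizations
  expect_false(identical(same[[1]]$signal, same[[2]]$signal))
  expect_identical(same[[1]]$seizure_intervals, same[[2]]$seizure_intervals)

  expect_error(generate_cohort(1L, base), ">= 2")
  expect_error(generate_cohort(3L, base, variability = -0.1), "nonnegative")
})
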