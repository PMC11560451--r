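test_that("cross-entropy loss matches closed-form values", {
  expect_equal(bce_loss(1, 1), -log(1 - 1e-7), tolerance = 1e-10)
  expect_lt(bce_loss(1, 1), 1e-6)
  expect_equal(bce_loss(0.5, 1), 0.6931, tolerance = 1e-4)
  expect_equal(bce_loss(0.9, 0), 2.3026, tolerance = 1e-4)
  # explicit l2 penalty on the parameter norm
  params <- list(a = matrix(c(3, 4), 1))
  expect_equal(bce_loss(0.5, 1, params, tau = 0.1),
               -log(0.5) + 0.1 * 5, tolerance = 1e-10)
})

test_that("epoch subsets are exactly class-balanced and vary across epochs", {
  segs <- fake_segments(40, 200)
  idx <- balanced_epoch_subset(segs, seed_epoch = 1)
  expect_length(idx, 80L)
  expect_equal(sum(segs$labels[idx] == 1L), 40L)
  expect_equal(sum(segs$labels[idx] == 0L), 40L)

  even <- fake_segments(40, 40)
  expect_length(balanced_epoch_subset(even, seed_epoch = 1), 80L)

  # consecutive epochs: same ictal set, different interictal draws
  draws <- lapply(1:10, function(e) balanced_epoch_subset(segs, seed_epoch = e))
  ict_sets <- lapply(draws, function(d) sort(d[segs$labels[d] == 1L]))
  expect_true(all(vapply(ict_sets, identical, TRUE, ict_sets[[1]])))
  inter_sets <- lapply(draws, function(d) sort(d[segs$labels[d] == 0L]))
  expect_gt(length(unique(inter_sets)), 1L)

  only <- fake_segments(10, 0)
  expect_error(balanced_epoch_subset(only), "both classes")
})

test_that("a short fit runs, records history and stays finite", {
  segs <- fake_segments(8, 16, n_ch = 6L, W = 32L)
  split <- list(train = 1:16, val = 17:20, test = 21:24)
  m <- mgcna_init(tiny_config(), seed = 1)
  fit <- fit_mgcna(m, segs, split, train_config(epochs = 1L, batch_size = 8L,
                                                seed = 1L))
  expect_equal(nrow(fit$history), 1L)
  expect_true(all(is.finite(unlist(fit$history[, 1:5]))))
  expect_true(all(is.finite(unlist(fit$model$params))))
  # audited per-epoch class balance
  expect_equal(fit$history$n_ictal, fit$history$n_interictal)
})

test_that("training is reproducible under a fixed seed", {
  segs <- fake_segments(8, 16, n_ch = 6L, W = 32L)
  split <- list(train = 1:16, val = 17:20, test = 21:24)
  tc <- train_config(epochs = 3L, batch_size = 8L, seed = 7L)
  f1 <- fit_mgcna(mgcna_init(tiny_config(), seed = 2), segs, split, tc)
  f2 <- fit_mgcna(mgcna_init(tiny_config(), seed = 2), segs, split, tc)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$model$params, f2$model$params)
})

test_that("gradient w.r.t. the adaptive adjacency matches finite differences", {
  cfg <- tiny_config()
  m <- mgcna_init(cfg, seed = 3)
  set.seed(42)
  x <- array(rnorm(6 * 32 * 4), c(6, 32, 4))
  y <- c(1, 0, 1, 0)
  lg <- mgcna_loss_grads(m, x, y, train = TRUE, dropout = FALSE)
  ij <- which(abs(lg$grads$a3) == max(abs(lg$grads$a3)), arr.ind = TRUE)[1, ]
  eps <- 1e-5
  bump <- function(e) {
    mp <- m
    mp$params$a3[ij[1], ij[2]] <- mp$params$a3[ij[1], ij[2]] + e
    mgcna_loss_grads(mp, x, y, train = TRUE, dropout = FALSE)$loss
  }
  fd <- (bump(eps) - bump(-eps)) / (2 * eps)
  expect_lt(abs(fd - lg$grads$a3[ij[1], ij[2]]) / abs(fd), 1e-3)
})

test_that("the adaptive adjacency is only trainable when its branch exists", {
  mfull <- mgcna_init(tiny_config(), seed = 1)
  expect_false(is.null(mfull$params$a3))
  m1 <- mgcna_init(ablation_config(tiny_config(), "h1"), seed = 1)
  expect_null(m1$params$a3)                  # no parameter, hence no gradient
  set.seed(1)
  x <- array(rnorm(6 * 32 * 2), c(6, 32, 2))
  lg <- mgcna_loss_grads(m1, x, c(1, 0), train = TRUE, dropout = FALSE)
  expect_null(lg$grads$a3)
})

test_that("explicit l2 mode adds the norm gradient", {
  segs <- fake_segments(6, 6, n_ch = 6L, W = 32L)
  split <- list(train = 1:8, val = 9:10, test = 11:12)
  tc <- train_config(epochs = 1L, batch_size = 4L, seed = 1L,
                     l2_mode = "explicit", tau = 0.01)
  fit <- fit_mgcna(mgcna_init(tiny_config(), seed = 4), segs, split, tc)
  expect_true(all(is.finite(unlist(fit$model$params))))
})

test_that("ablation configs flip the intended switches", {
  base <- model_config()
  expect_equal(unname(ablation_config(base, "h1")$branches),
               c(TRUE, FALSE, FALSE))
  expect_equal(unname(ablation_config(base, "h2")$branches),
               c(FALSE, TRUE, FALSE))
  expect_equal(unname(ablation_config(base, "h3")$branches),
               c(FALSE, FALSE, TRUE))
  expect_false(ablation_config(base, "no_attention")$attention)
  expect_true(all(ablation_config(base, "full")$branches))
})
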