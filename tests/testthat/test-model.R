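test_that("depthwise extractor halves resolution without cross-channel mixing", {
  set.seed(1)
  x <- matrix(rnorm(22 * 768), 22)
  N <- intrachannel_extract(x, k = 2)
  expect_equal(dim(N), c(22L, 192L))

  expect_equal(intrachannel_extract(x, k = 0), x)

  # perturbing channel 5 changes only row 5 (depthwise property)
  m <- mgcna_init(tiny_config(), seed = 2)
  x6 <- matrix(rnorm(6 * 32), 6)
  x6b <- x6
  x6b[5, ] <- x6b[5, ] + rnorm(32)
  N1 <- intrachannel_extract(x6, k = 2, weights = m$params$ext)
  N2 <- intrachannel_extract(x6b, k = 2, weights = m$params$ext)
  expect_false(isTRUE(all.equal(N1[5, ], N2[5, ])))
  expect_equal(N1[-5, ], N2[-5, ])

  expect_error(intrachannel_extract(matrix(rnorm(4 * 30), 4), k = 2),
               "divisible")
})

test_that("gcn layer implements the symmetric-normalized propagation rule", {
  # zero adjacency: reduces to a per-node dense map ReLU(H theta)
  set.seed(2)
  H <- matrix(rnorm(12), 4)
  theta <- matrix(rnorm(9), 3)
  expect_equal(gcn_layer(H, matrix(0, 4, 4), theta),
               mgcna:::relu(H %*% theta))

  # 2x2 hand computation
  H2 <- matrix(c(1, 3, 0, 0), 2)
  out <- gcn_layer(H2, matrix(c(0, 1, 1, 0), 2))
  expect_equal(out, matrix(c(2, 2, 0, 0), 2))

  # constant features on a regular graph stay constant (spectral property)
  cyc <- matrix(0, 4, 4)
  cyc[cbind(1:4, c(2, 3, 4, 1))] <- 1
  cyc <- cyc + t(cyc)
  Hc <- cbind(rep(2, 4), rep(-1, 4))
  theta2 <- matrix(rnorm(4), 2)
  outc <- gcn_layer(Hc, cyc, theta2)
  expect_equal(apply(outc, 2, function(col) max(col) - min(col)), c(0, 0))

  expect_error(gcn_layer(H, matrix(0, 3, 4)), "square")
})

test_that("multi-branch forward stacks per-branch outputs with unshared weights", {
  m <- mgcna_init(model_config(), seed = 2)
  set.seed(3)
  N <- matrix(rnorm(22 * 192), 22)
  Z <- multibranch_forward(m, N)
  expect_equal(dim(Z), c(3L, 22L, 64L))

  mh1 <- mgcna_init(ablation_config(model_config(), "h1"), seed = 2)
  expect_equal(dim(multibranch_forward(mh1, N)), c(1L, 22L, 64L))

  # identical adjacency + copied weights => identical branch outputs
  m2 <- m
  m2$params$gcn$connectivity <- m2$params$gcn$distance
  A <- build_distance_adjacency(electrode_layout(), 0.4)$matrix
  Z2 <- multibranch_forward(m2, N, adjacencies = list(
    distance = A, connectivity = A, adaptive = A))
  expect_equal(Z2[1, , ], Z2[2, , ])

  expect_error(multibranch_forward(m, N, adjacencies = list(distance = A)),
               "per enabled branch")
})

test_that("separable attention preserves shape, normalizes scores and isolates the residual path", {
  m <- mgcna_init(model_config(), seed = 4)
  set.seed(5)
  Z <- array(rnorm(3 * 22 * 64), c(3, 22, 64))
  out <- separable_attention(m, Z, details = TRUE)
  expect_equal(dim(out$Zp), dim(Z))
  sums <- apply(out$scores, c(1, 3), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-6)

  # zeroing the post-concatenation convolution leaves only the residual path
  m0 <- m
  m0$params$att$cw[] <- 0
  m0$params$att$cb[] <- 0
  Zp0 <- separable_attention(m0, Z)
  expect_equal(Zp0, Z / sqrt(1 + 1e-5), tolerance = 1e-10)
})

test_that("classifier head applies sigmoid and breaks ties to interictal", {
  m <- mgcna_init(model_config(), seed = 6)
  set.seed(7)
  Zf <- array(rnorm(3 * 22 * 64), c(3, 22, 64))

  m0 <- m
  m0$params$clf$lw[] <- 0
  m0$params$clf$lb[] <- 0
  tie <- classify(m0, Zf)
  expect_equal(tie$probs, c(0.5, 0.5))
  expect_equal(tie$class, 0L)               # tie -> interictal

  m1 <- m
  m1$params$clf$lw[] <- 0
  m1$params$clf$lb <- c(-10, 10)
  strong <- classify(m1, Zf)
  expect_equal(strong$probs, c(sigmoid_ <- 1 / (1 + exp(10)), 1 - sigmoid_),
               tolerance = 1e-9)
  expect_equal(strong$class, 1L)

  # eval mode is deterministic (dropout off)
  expect_identical(classify(m, Zf), classify(m, Zf))
})

test_that("branch outputs are node-permutation equivariant", {
  cfg <- tiny_config()
  m <- mgcna_init(cfg, seed = 8)
  set.seed(9)
  N <- matrix(rnorm(6 * 8), 6)
  A <- oracle_distance_adjacency(random_layout(6, 3)$coords, 0.8)
  set.seed(10)
  Araw <- matrix(runif(36), 6)
  adjs <- list(distance = A, connectivity = A, adaptive = Araw)
  Z <- multibranch_forward(m, N, adjacencies = adjs)
  perm <- c(4, 1, 6, 2, 5, 3)
  adjp <- lapply(adjs, function(a) a[perm, perm])
  Zp <- multibranch_forward(m, N[perm, ], adjacencies = adjp)
  for (b in 1:3)
    expect_equal(Zp[b, , ], Z[b, perm, ], tolerance = 1e-10)
})

test_that("forward pass stays finite across many random inputs", {
  cfg <- tiny_config()
  m <- mgcna_init(cfg, seed = 1)
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    x <- array(rnorm(6 * 32 * 2) * 10, c(6, 32, 2))
    fw <- mgcna_forward(m, x)
    all(is.finite(fw$probs)) && all(is.finite(fw$logits))
  }, logical(1))
  expect_true(all(ok))
})

test_that("parameter counts are reported and batch-size independent", {
  m <- mgcna_init(model_config(), seed = 1)
  invisible(capture.output(df <- mgcna_describe(m)))
  total <- df$params[df$component == "total"]
  expect_equal(total, sum(df$params[df$component != "total"]))
  # parameter count is independent of batch size and window count
  x1 <- array(rnorm(22 * 768 * 1), c(22, 768, 1))
  x3 <- array(rnorm(22 * 768 * 3), c(22, 768, 3))
  invisible(mgcna_forward(m, x1))
  invisible(mgcna_forward(m, x3))
  invisible(capture.output(df2 <- mgcna_describe(m)))
  expect_equal(df2$params[df2$component == "total"], total)
})

test_that("separable attention cost is linear in the token count", {
  base <- model_config()
  doubled <- model_config(gcn_dim = 128L)
  ratio <- attention_flops(doubled) / attention_flops(base)
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("checkpoints round-trip weights, config and state", {
  cfg <- tiny_config()
  m <- mgcna_init(cfg, seed = 5)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, m$params)
  set.seed(11)
  x <- array(rnorm(6 * 32 * 2), c(6, 32, 2))
  expect_equal(mgcna_forward(back, x)$probs, mgcna_forward(m, x)$probs)
})
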