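collinear_layout <- function() {
  coords <- cbind(x = c(0, 1, 2), y = c(0, 0, 0))
  rownames(coords) <- c("A", "B", "C")
  structure(list(names = c("A", "B", "C"), coords = coords),
            class = "electrode_layout")
}

test_that("distance adjacency reproduces the collinear hand computation", {
  A <- build_distance_adjacency(collinear_layout(), R1 = 0.6)$matrix
  # normalized distances {0.5, 0.5, 1}, population sd 0.2357,
  # exp(-0.25 / (2 * 0.05556)) = 0.1054
  expect_equal(A[1, 2], 0.1054, tolerance = 1e-3)
  expect_equal(A[2, 3], 0.1054, tolerance = 1e-3)
  expect_equal(A[1, 3], 0)
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(0, 3), ignore_attr = TRUE)
})

test_that("distance adjacency handles thresholds and degenerate layouts", {
  # R1 = 0: only exactly coincident pairs pass
  lay <- electrode_layout()
  A0 <- build_distance_adjacency(lay, R1 = 0)$matrix
  i <- which(lay$names == "T7-P7"); j <- which(lay$names == "P7-T7")
  expect_equal(A0[i, j], 1)                  # coincident midpoints: exp(0) = 1
  A0[i, j] <- 0; A0[j, i] <- 0
  expect_true(all(A0 == 0))

  coincident <- collinear_layout()
  coincident$coords[] <- 0
  expect_error(build_distance_adjacency(coincident), "coincide")
})

test_that("correlation adjacency reproduces the hand-computed Pearson cases", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  A <- build_correlation_adjacency(x, R2 = 0.25)$matrix
  expect_equal(A[1, 2], 0)                   # rho = -1 -> 0 < R2

  y <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 4, 3))
  B <- build_correlation_adjacency(y, R2 = 0.25)$matrix
  expect_equal(B[1, 2], 0.9, tolerance = 1e-12)   # rho = 0.8 -> 0.9

  z <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(5, 1, 2, 9))
  C <- build_correlation_adjacency(z, R2 = 0.25)$matrix
  expect_equal(C[1, 2], 1)                   # identical up to scale: rho = 1

  bad <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(build_correlation_adjacency(bad), "zero-variance.*a")
})

test_that("both static builders match the brute-force oracle exactly", {
  for (s in 1:12) {
    lay <- random_layout(6, seed = s)
    got <- build_distance_adjacency(lay, R1 = 0.5)$matrix
    expect_equal(unname(got), oracle_distance_adjacency(lay$coords, 0.5),
                 tolerance = 1e-12)
    set.seed(100 + s)
    x <- matrix(rnorm(6 * 30), 6)
    got2 <- build_correlation_adjacency(x, R2 = 0.3)$matrix
    expect_equal(unname(got2), oracle_correlation_adjacency(x, 0.3),
                 tolerance = 1e-12)
  }
})

test_that("distance adjacency is permutation equivariant", {
  lay <- random_layout(8, seed = 1)
  A <- build_distance_adjacency(lay, R1 = 0.6)$matrix
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  playout <- lay
  playout$names <- lay$names[perm]
  playout$coords <- lay$coords[perm, ]
  Ap <- build_distance_adjacency(playout, R1 = 0.6)$matrix
  expect_equal(unname(Ap), unname(A[perm, perm]), tolerance = 1e-12)
})

test_that("correlation adjacency is invariant to per-channel affine rescaling", {
  set.seed(2)
  x <- matrix(rnorm(5 * 40), 5)
  y <- x * c(2, 0.5, 10, 1, 3) + c(-1, 4, 0, 7, 2)
  expect_equal(build_correlation_adjacency(y, 0.2)$matrix,
               build_correlation_adjacency(x, 0.2)$matrix, tolerance = 1e-9)
})

test_that("adaptive constraint standardizes, shifts and rectifies", {
  raw <- matrix(c(1, 2, -1, 0), 2)          # row-major [[1,-1],[2,0]]
  A <- constrain_adaptive_adjacency(raw)$matrix
  expect_equal(A, matrix(c(0.4472, 1.3416, 0, 0), 2), tolerance = 1e-3)
  expect_true(all(A >= 0))

  const <- constrain_adaptive_adjacency(matrix(5, 3, 3))$matrix
  expect_equal(const, matrix(0, 3, 3))       # standardized to ~0, ReLU -> 0

  set.seed(3)
  anyraw <- matrix(rnorm(16), 4)
  expect_true(all(constrain_adaptive_adjacency(anyraw)$matrix >= 0))
})

test_that("threshold sweep is monotone and reproducible by enumeration", {
  lay <- electrode_layout()
  sw <- threshold_sweep("distance", grid = seq(0.2, 0.7, by = 0.05),
                        layout = lay)
  expect_true(all(diff(sw$edge_count) >= 0))

  set.seed(5)
  x <- matrix(rnorm(6 * 50), 6)
  swc <- threshold_sweep("connectivity", grid = seq(0.1, 0.5, by = 0.05),
                         segment = x)
  expect_true(all(diff(swc$edge_count) <= 0))

  # R2 = 0 retains every pair
  sw0 <- threshold_sweep("connectivity", grid = 0, segment = x)
  expect_equal(sw0$edge_count, 6 * 5 / 2)

  # brute-force enumeration on the collinear example
  swd <- threshold_sweep("distance", grid = c(0.4, 0.6, 1.0),
                         layout = collinear_layout())
  expect_equal(swd$edge_count, c(0L, 2L, 3L))
  expect_equal(swd$mean_weight[2], 0.1054, tolerance = 1e-3)
})

test_that("adjacency CSV round-trips with channel names", {
  A <- build_distance_adjacency(electrode_layout(), R1 = 0.4)
  path <- tempfile(fileext = ".csv")
  write_adjacency_csv(A, path)
  back <- read_adjacency_csv(path)
  expect_equal(back$matrix, A$matrix, tolerance = 1e-12)

  lpath <- tempfile(fileext = ".csv")
  write_layout_csv(electrode_layout(), lpath)
  lay <- read_layout_csv(lpath)
  expect_equal(lay$names, canonical_channels())
})
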