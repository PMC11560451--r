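#' Spatial-distance adjacency from an electrode layout
#'
#' Builds the distance-graph view of the montage. Pairwise Euclidean distances
#' between derivation midpoints are normalized by the maximum pairwise distance
#' (so thresholds live on a `[0, 1]` scale), and edge weights follow a Gaussian
#' kernel `exp(-d^2 / (2 * delta^2))` where `delta` is the standard deviation of
#' the normalized off-diagonal unique-pair distances. Pairs farther apart than
#' the sparsity threshold `R1` get weight 0. The diagonal is 0; self-loops are
#' added once, later, by the GCN normalizer.
#'
#' @param layout An [electrode_layout()].
#' @param R1 Sparsity threshold on the normalized distance scale, in `[0, 1]`.
#'   Default 0.4.
#' @param half_kernel_denominator If `TRUE` (default) the kernel denominator is
#'   `2 * delta^2` (heat-kernel convention); `FALSE` drops the factor 2.
#' @return An object of class `adjacency`: list with `matrix` (n x n, named),
#'   and `kind = "distance"`.
#' @examples
#' A1 <- build_distance_adjacency(electrode_layout(), R1 = 0.4)
#' sum(A1$matrix > 0) / 2  # retained edges
#' @export
build_distance_adjacency <- function(layout, R1 = 0.4,
                                     half_kernel_denominator = TRUE) {
  abort_if(!inherits(layout, "electrode_layout"), "`layout` must be an electrode_layout")
  n <- length(layout$names)
  abort_if(n < 2L, "layout needs at least 2 nodes")
  abort_if(!is_scalar(R1) || R1 < 0 || R1 > 1, "`R1` must be in [0, 1]")
  D <- as.matrix(stats::dist(layout$coords))
  mx <- max(D)
  abort_if(mx == 0, "all electrode positions coincide; distance graph undefined")
  D <- D / mx
  dvals <- D[upper.tri(D)]
  # population standard deviation of the unique-pair distances
  delta <- sqrt(mean((dvals - mean(dvals))^2))
  denom <- if (half_kernel_denominator) 2 * delta^2 else delta^2
  A <- exp(-D^2 / denom)
  A[D > R1] <- 0
  diag(A) <- 0
  dimnames(A) <- list(layout$names, layout$names)
  new_adjacency(A, "distance")
}

#' Functional-connectivity adjacency from a multichannel segment
#'
#' Pearson correlation between channel feature vectors, affinely mapped to
#' `[0, 1]` (`(rho + 1) / 2` by default, `|rho|` optionally), then thresholded:
#' entries below `R2` are dropped. In the full model the input rows are the
#' intrachannel feature vectors extracted from a segment; the builder itself
#' accepts any channels-by-samples matrix. Diagonal is 0.
#'
#' @param segment Numeric matrix, channels x samples (>= 2 samples).
#' @param R2 Threshold on the normalized correlation, in `[0, 1]`. Default 0.25.
#' @param normalization `"affine"` for `(rho + 1) / 2` (default) or `"abs"` for
#'   `|rho|`.
#' @return An `adjacency` with `kind = "connectivity"`.
#' @examples
#' x <- matrix(rnorm(4 * 50), 4)
#' build_correlation_adjacency(x, R2 = 0.25)$matrix
#' @export
build_correlation_adjacency <- function(segment, R2 = 0.25,
                                        normalization = c("affine", "abs")) {
  normalization <- match.arg(normalization)
  abort_if(!is.matrix(segment) || ncol(segment) < 2L,
           "`segment` must be a channels x samples matrix with >= 2 samples")
  abort_if(!is_scalar(R2) || R2 < 0 || R2 > 1, "`R2` must be in [0, 1]")
  v <- apply(segment, 1L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- rownames(segment)[bad] %||% as.character(bad)
    stop("zero-variance channel(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  rho <- stats::cor(t(segment))
  A <- if (normalization == "affine") (rho + 1) / 2 else abs(rho)
  A[A < R2] <- 0
  diag(A) <- 0
  if (!is.null(rownames(segment))) dimnames(A) <- list(rownames(segment), rownames(segment))
  new_adjacency(A, "connectivity")
}

#' Constrain a raw trainable adjacency
#'
#' The adaptive graph view keeps an unconstrained real n x n parameter matrix;
#' before use it is standardized over all entries (subtract the mean, divide by
#' the population standard deviation plus `eps`), passed through a learnable
#' affine map (initialized to identity), and rectified, yielding a nonnegative
#' adjacency. This is the functional form of the constraint; during training the
#' same transform runs inside the forward pass with gradients flowing back to
#' the raw matrix.
#'
#' @param raw Numeric n x n matrix (finite).
#' @param gamma,beta Affine scale and shift (scalars; defaults 1 and 0).
#' @param eps Stabilizer added to the standard deviation. Default `1e-5`.
#' @return An `adjacency` with `kind = "adaptive"`.
#' @examples
#' constrain_adaptive_adjacency(matrix(c(1, -1, 2, 0), 2, byrow = TRUE))$matrix
#' @export
constrain_adaptive_adjacency <- function(raw, gamma = 1, beta = 0, eps = 1e-5) {
  abort_if(!is.matrix(raw) || !all(is.finite(raw)), "`raw` must be a finite matrix")
  abort_if(nrow(raw) != ncol(raw), "`raw` must be square")
  mu <- mean(raw)
  sd_ <- sqrt(mean((raw - mu)^2))
  z <- (raw - mu) / (sd_ + eps)
  A <- pmax(gamma * z + beta, 0)
  new_adjacency(A, "adaptive")
}

new_adjacency <- function(matrix, kind) {
  structure(list(matrix = matrix, kind = kind), class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  n <- nrow(x$matrix)
  ne <- sum(x$matrix[upper.tri(x$matrix)] > 0)
  cat(sprintf("<adjacency:%s> %d nodes, %d retained upper-triangle edges\n",
              x$kind, n, ne))
  invisible(x)
}

#' Symmetric GCN normalizer
#'
#' Computes `D^-1/2 (A + I) D^-1/2` where `D` is the diagonal degree matrix of
#' `A + I`. Self-loops are introduced here, exactly once.
#'
#' @param A Numeric square adjacency matrix (weights, diagonal typically 0).
#' @return The normalized propagation matrix.
#' @export
normalize_adjacency <- function(A) {
  if (inherits(A, "adjacency")) A <- A$matrix
  abort_if(!is.matrix(A) || nrow(A) != ncol(A), "`A` must be square")
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  di <- 1 / sqrt(d)
  di * At * rep(di, each = nrow(At))
}

#' Sparsity diagnostics over a threshold grid
#'
#' Rebuilds an adjacency at each threshold in `grid` and tabulates retained
#' edge count (upper-triangle, nonzero) and mean retained weight. Used to study
#' how the sparsity thresholds shape the distance graph (grid 0.2-0.7) and the
#' connectivity graph (grid 0.1-0.5, stride 0.05).
#'
#' @param builder `"distance"` or `"connectivity"`.
#' @param grid Ascending numeric vector of thresholds.
#' @param layout Required for the distance builder.
#' @param segment Required for the connectivity builder.
#' @param ... Passed to the underlying builder.
#' @return data.frame with columns `threshold`, `edge_count`, `mean_weight`
#'   (`NA` when no edge is retained).
#' @export
threshold_sweep <- function(builder = c("distance", "connectivity"), grid,
                            layout = NULL, segment = NULL, ...) {
  builder <- match.arg(builder)
  abort_if(length(grid) == 0L, "`grid` must be nonempty")
  abort_if(is.unsorted(grid, strictly = FALSE), "`grid` must be ascending")
  rows <- lapply(grid, function(th) {
    A <- if (builder == "distance") {
      abort_if(is.null(layout), "distance sweep needs `layout`")
      build_distance_adjacency(layout, R1 = th, ...)$matrix
    } else {
      abort_if(is.null(segment), "connectivity sweep needs `segment`")
      build_correlation_adjacency(segment, R2 = th, ...)$matrix
    }
    w <- A[upper.tri(A)]
    w <- w[w > 0]
    data.frame(threshold = th, edge_count = length(w),
               mean_weight = if (length(w)) mean(w) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Read or write an adjacency matrix as CSV
#'
#' Dense CSV with channel names as header row and first column.
#'
#' @param adj An `adjacency` (or bare matrix for writing).
#' @param path File path.
#' @param kind Kind label used when reading.
#' @return `read_adjacency_csv()` returns an `adjacency`.
#' @export
write_adjacency_csv <- function(adj, path) {
  M <- if (inherits(adj, "adjacency")) adj$matrix else adj
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @export
read_adjacency_csv <- function(path, kind = "distance") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  new_adjacency(as.matrix(df), kind)
}
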