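#' Network architecture configuration
#'
#' All architectural hyperparameters of the multi-branch GCN with separable
#' attention, including every value the method leaves open (recorded here
#' explicitly with its default).
#'
#' @param n_channels Number of EEG channels / graph nodes. Default 22.
#' @param window_samples Samples per segment `C` (default 768 = 3 s at 256 Hz);
#'   must be divisible by `2^k_depthwise`.
#' @param k_depthwise Depthwise halving layers `k`. Default 2.
#' @param gcn_layers GCN depth `m` per branch. Default 2.
#' @param gcn_dim GCN width `P` (node feature dimension). Default 64.
#' @param n_heads Attention heads `h`. Default 3.
#' @param head_dim Per-head key/value channel count `d`. Default 1.
#' @param dropout Dropout rate before the output linear layer. Default 0.5.
#' @param classifier_channels Channel counts of the two classifier convolutions.
#'   Default `c(16, 32)`.
#' @param n_classes Output classes. Default 2 (interictal, ictal).
#' @param branches Named logical vector enabling the `distance`, `connectivity`
#'   and `adaptive` graph branches (ablation switches). At least one must be on.
#' @param attention Enable the separable multi-head attention fusion; when off,
#'   branch outputs are concatenated directly (the no-attention ablation).
#' @param R1 Sparsity threshold of the distance graph. Default 0.4.
#' @param R2 Threshold of the connectivity graph. Default 0.25.
#' @param corr_normalization Map from Pearson rho to `[0, 1]`: `"affine"`
#'   (`(rho+1)/2`, default) or `"abs"`.
#' @param half_kernel_denominator Gaussian kernel denominator convention for the
#'   distance graph (see [build_distance_adjacency()]).
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_channels = 22L, window_samples = 768L,
                         k_depthwise = 2L, gcn_layers = 2L, gcn_dim = 64L,
                         n_heads = 3L, head_dim = 1L, dropout = 0.5,
                         classifier_channels = c(16L, 32L), n_classes = 2L,
                         branches = c(distance = TRUE, connectivity = TRUE,
                                      adaptive = TRUE),
                         attention = TRUE, R1 = 0.4, R2 = 0.25,
                         corr_normalization = c("affine", "abs"),
                         half_kernel_denominator = TRUE) {
  corr_normalization <- match.arg(corr_normalization)
  abort_if(window_samples %% 2^k_depthwise != 0,
           "window_samples must be divisible by 2^k_depthwise")
  abort_if(!any(branches), "at least one graph branch must be enabled")
  abort_if(!all(names(branches) %in% c("distance", "connectivity", "adaptive")) ||
             length(branches) != 3L,
           "branches must be a named logical vector over distance/connectivity/adaptive")
  abort_if(n_classes != 2L, "only binary (ictal vs interictal) output is supported")
  abort_if(n_heads < 1L || head_dim < 1L, "n_heads and head_dim must be >= 1")
  structure(list(n_channels = as.integer(n_channels),
                 window_samples = as.integer(window_samples),
                 k_depthwise = as.integer(k_depthwise),
                 gcn_layers = as.integer(gcn_layers),
                 gcn_dim = as.integer(gcn_dim),
                 n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
                 dropout = dropout,
                 classifier_channels = as.integer(classifier_channels),
                 n_classes = as.integer(n_classes),
                 branches = branches, attention = attention,
                 R1 = R1, R2 = R2, corr_normalization = corr_normalization,
                 half_kernel_denominator = half_kernel_denominator),
            class = "model_config")
}

enabled_branches <- function(cfg) names(cfg$branches)[cfg$branches]

# fan-in scaled uniform init
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

#' Initialize a model
#'
#' Builds the full parameter set (seeded, fan-in-scaled uniform), batch-norm
#' running state, the frozen distance-graph normalizer from the electrode
#' layout.
#'
#' @param config A [model_config()].
#' @param layout An [electrode_layout()] matching `n_channels`; only needed when
#'   the distance branch is enabled. When `n_channels` differs from 22 and no
#'   layout is given, a generic circular layout is used.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `mgcna_model`.
#' @export
mgcna_init <- function(config, layout = NULL, seed = 1L) {
  n <- config$n_channels
  D <- config$window_samples %/% 2L^config$k_depthwise
  P <- config$gcn_dim
  h <- config$n_heads; hd <- config$n_heads * config$head_dim
  br <- enabled_branches(config)
  B <- length(br)
  c12 <- config$classifier_channels

  if (is.null(layout)) {
    layout <- if (n == 22L) electrode_layout() else generic_layout(n)
  }
  abort_if(length(layout$names) != n, "layout size must match n_channels")

  with_seed(seed, {
    params <- list()
    params$ext <- lapply(seq_len(config$k_depthwise), function(l) {
      list(w1 = stats::runif(n, -1, 1) / sqrt(2),
           w2 = stats::runif(n, -1, 1) / sqrt(2),
           b = numeric(n))
    })
    gcn_branch <- function() {
      lapply(seq_len(config$gcn_layers), function(l) {
        fin <- if (l == 1L) D else P
        list(theta = init_mat(fin, P, fin), bn_g = rep(1, P), bn_b = numeric(P))
      })
    }
    params$gcn <- stats::setNames(lapply(br, function(b) gcn_branch()), br)
    if (config$branches[["adaptive"]]) {
      params$a3 <- matrix(stats::runif(n * n, 0, 1 / n), n, n)
      params$a3_aff <- c(g = 1, b = 0)
    }
    if (config$attention) {
      params$att <- list(
        wq = init_mat(h, B, B), bq = numeric(h),
        wk = init_mat(hd, B, B), bk = numeric(hd),
        wv = init_mat(hd, B, B), bv = numeric(hd),
        cw = init_mat(B, hd * 9L, hd * 9L), cb = numeric(B),
        bn14_g = rep(1, B), bn14_b = numeric(B),
        bn15_g = rep(1, B), bn15_b = numeric(B))
    }
    params$clf <- list(
      c1w = init_mat(c12[1L], B * 9L, B * 9L), c1b = numeric(c12[1L]),
      c2w = init_mat(c12[2L], c12[1L] * 9L, c12[1L] * 9L),
      c2b = numeric(c12[2L]),
      lw = init_mat(config$n_classes, c12[2L], c12[2L]),
      lb = numeric(config$n_classes))
  })

  state <- list(
    gcn = stats::setNames(lapply(br, function(b) {
      lapply(seq_len(config$gcn_layers), function(l)
        list(rm = numeric(P), rv = rep(1, P)))
    }), br),
    a3 = list(rm = 0, rv = 1),
    bn14 = list(rm = numeric(B), rv = rep(1, B)),
    bn15 = list(rm = numeric(B), rv = rep(1, B)))

  fixed <- list(layout = layout)
  if (config$branches[["distance"]]) {
    A1 <- build_distance_adjacency(layout, R1 = config$R1,
                                   half_kernel_denominator = config$half_kernel_denominator)
    fixed$A1 <- A1$matrix
    fixed$S1 <- normalize_adjacency(A1$matrix)
  }

  structure(list(config = config, params = params, state = state,
                 fixed = fixed, seed = seed),
            class = "mgcna_model")
}

generic_layout <- function(n) {
  ang <- 2 * pi * seq_len(n) / n
  coords <- cbind(x = cos(ang), y = sin(ang))
  nm <- sprintf("CH%02d", seq_len(n))
  rownames(coords) <- nm
  structure(list(names = nm, coords = coords), class = "electrode_layout")
}

#' @export
print.mgcna_model <- function(x, ...) {
  cat(sprintf("<mgcna_model> %d nodes, branches [%s], attention %s, %s parameters\n",
              x$config$n_channels,
              paste(enabled_branches(x$config), collapse = ", "),
              if (x$config$attention) "on" else "off",
              format(param_count(x$params), big.mark = ",")))
  invisible(x)
}

# ---- forward pieces ----------------------------------------------------------

# x: (n, C, batch) array -> stacked (batch*n) x C matrix, segment-major rows
stack_segments <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  m <- aperm(x, c(1L, 3L, 2L))
  dim(m) <- c(d[1L] * d[3L], d[2L])
  m
}

fwd_extract <- function(model, M, bt) {
  n <- model$config$n_channels
  chidx <- rep.int(seq_len(n), bt)
  cache <- vector("list", model$config$k_depthwise)
  for (l in seq_len(model$config$k_depthwise)) {
    p <- model$params$ext[[l]]
    odd <- seq(1L, ncol(M), by = 2L)
    Modd <- M[, odd, drop = FALSE]
    Meven <- M[, odd + 1L, drop = FALSE]
    cache[[l]] <- list(Modd = Modd, Meven = Meven)
    M <- Modd * p$w1[chidx] + Meven * p$w2[chidx] + p$b[chidx]
  }
  list(N = M, cache = cache, chidx = chidx)
}

# Pearson connectivity normalizers, one per segment, computed from the current
# intrachannel features and treated as constants in the backward pass.
compute_S2 <- function(model, N, bt) {
  n <- model$config$n_channels
  lapply(seq_len(bt), function(s) {
    Ns <- N[((s - 1L) * n + 1L):(s * n), , drop = FALSE]
    sds <- sqrt(rowSums((Ns - rowMeans(Ns))^2))
    rho <- matrix(0, n, n)
    ok <- sds > 0
    if (any(ok)) rho[ok, ok] <- stats::cor(t(Ns[ok, , drop = FALSE]))
    A <- if (model$config$corr_normalization == "affine") (rho + 1) / 2 else abs(rho)
    A[A < model$config$R2] <- 0
    diag(A) <- 0
    normalize_adjacency(A)
  })
}

# Constrained adaptive adjacency and its normalizer, with backward cache.
compute_S3 <- function(model, train) {
  a3 <- model$params$a3
  eps <- 1e-5
  if (train) {
    mu <- mean(a3)
    sd_ <- sqrt(mean((a3 - mu)^2))
  } else {
    mu <- model$state$a3$rm
    sd_ <- sqrt(max(model$state$a3$rv, 0))
  }
  z <- (a3 - mu) / (sd_ + eps)
  aff <- model$params$a3_aff[["g"]] * z + model$params$a3_aff[["b"]]
  A3 <- pmax(aff, 0)
  At <- A3 + diag(nrow(a3))
  dvec <- rowSums(At)
  di <- 1 / sqrt(dvec)
  S3 <- di * At * rep(di, each = nrow(At))
  list(S = S3, cache = list(z = z, sd_ = sd_, aff = aff, At = At, d = dvec,
                            train = train, mu = mu))
}

# Apply a shared n x n propagation matrix to every segment block of G
apply_shared_S <- function(S, G, n, bt) {
  P <- ncol(G)
  dim(G) <- c(n, bt * P)
  Y <- S %*% G
  dim(Y) <- c(n * bt, P)
  Y
}

apply_perseg_S <- function(Slist, G, n, bt) {
  Y <- G
  for (s in seq_len(bt)) {
    rows <- ((s - 1L) * n + 1L):(s * n)
    Y[rows, ] <- Slist[[s]] %*% G[rows, , drop = FALSE]
  }
  Y
}

fwd_gcn_branch <- function(model, branch, N, Sobj, bt, train) {
  cfg <- model$config
  n <- cfg$n_channels
  H <- N
  caches <- vector("list", cfg$gcn_layers)
  state <- model$state$gcn[[branch]]
  for (l in seq_len(cfg$gcn_layers)) {
    p <- model$params$gcn[[branch]][[l]]
    G <- H %*% p$theta
    Y <- if (is.list(Sobj)) apply_perseg_S(Sobj, G, n, bt)
         else apply_shared_S(Sobj, G, n, bt)
    R <- relu(Y)
    bn <- bn_forward(R, p$bn_g, p$bn_b, state[[l]]$rm, state[[l]]$rv, train)
    caches[[l]] <- list(H_in = H, G = G, Y = Y, bn = bn$cache)
    state[[l]]$rm <- bn$rm; state[[l]]$rv <- bn$rv
    H <- bn$y
  }
  list(z = H, caches = caches, state = state)
}

# z: (bt*n) x P -> (L, bt) slab with position index l = (p-1)*n + i
z_to_slab <- function(z, n, bt) {
  P <- ncol(z)
  dim(z) <- c(n, bt, P)
  z <- aperm(z, c(1L, 3L, 2L))
  dim(z) <- c(n * P, bt)
  z
}

slab_to_z <- function(s, n, bt) {
  P <- length(s) / (n * bt)
  dim(s) <- c(n, P, bt)
  s <- aperm(s, c(1L, 3L, 2L))
  dim(s) <- c(n * bt, P)
  s
}

fwd_attention <- function(model, Zarr, bt, train) {
  cfg <- model$config
  n <- cfg$n_channels; P <- cfg$gcn_dim
  h <- cfg$n_heads; d <- cfg$head_dim; hd <- h * d
  L <- n * P
  B <- dim(Zarr)[1L]
  p <- model$params$att
  Zmat <- Zarr; dim(Zmat) <- c(B, L * bt)
  Qm <- p$wq %*% Zmat + p$bq
  Km <- p$wk %*% Zmat + p$bk
  Vm <- p$wv %*% Zmat + p$bv
  Qa <- Qm; dim(Qa) <- c(h, L, bt)
  Ka <- Km; dim(Ka) <- c(hd, L, bt)
  Va <- Vm; dim(Va) <- c(hd, L, bt)
  Sa <- softmax_positions(Qa)
  headof <- rep(seq_len(h), each = d)
  Sexp <- Sa[headof, , , drop = FALSE]
  cv <- sum_positions(Ka * Sexp)                  # (hd, bt) context vectors
  cvb <- broadcast_positions(cv, L)
  Vr <- relu(Va)
  attn <- Vr * cvb
  co <- conv3x3_forward(attn, p$cw, p$cb, n, P)
  m14 <- co$y; dim(m14) <- c(B, L * bt)
  bn14 <- bn_forward(t(m14), p$bn14_g, p$bn14_b,
                     model$state$bn14$rm, model$state$bn14$rv, train)
  ma <- relu(bn14$y)                                # (L*bt) x B
  MA <- t(ma); dim(MA) <- c(B, L, bt)
  Zsum <- Zarr + MA
  m15 <- Zsum; dim(m15) <- c(B, L * bt)
  bn15 <- bn_forward(t(m15), p$bn15_g, p$bn15_b,
                     model$state$bn15$rm, model$state$bn15$rv, train)
  Zp <- t(bn15$y); dim(Zp) <- c(B, L, bt)
  list(Zp = Zp,
       cache = list(Zmat = Zmat, Qa = Qa, Ka = Ka, Va = Va, Sa = Sa,
                    Sexp = Sexp, cv = cv, cvb = cvb, Vr = Vr, conv = co,
                    bn14 = bn14$cache, ma = ma, bn15 = bn15$cache,
                    headof = headof, B = B, L = L, bt = bt),
       state = list(bn14 = list(rm = bn14$rm, rv = bn14$rv),
                    bn15 = list(rm = bn15$rm, rv = bn15$rv)),
       scores = Sa)
}

fwd_classifier <- function(model, Zp, bt, train, dropout) {
  cfg <- model$config
  L <- cfg$n_channels * cfg$gcn_dim
  p <- model$params$clf
  co1 <- conv3x3_forward(Zp, p$c1w, p$c1b, cfg$n_channels, cfg$gcn_dim)
  R1 <- relu(co1$y)
  co2 <- conv3x3_forward(R1, p$c2w, p$c2b, cfg$n_channels, cfg$gcn_dim)
  R2 <- relu(co2$y)
  gap <- sum_positions(R2) / L
  if (train && dropout && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(stats::rbinom(length(gap), 1L, keep), nrow(gap)) / keep
  } else mask <- NULL
  gap_d <- if (is.null(mask)) gap else gap * mask
  logits <- p$lw %*% gap_d + p$lb
  probs <- sigmoid(logits)
  list(probs = probs, logits = logits,
       cache = list(co1 = co1, R1 = R1, co2 = co2, R2 = R2, gap = gap,
                    mask = mask, gap_d = gap_d))
}

#' Full network forward pass
#'
#' Runs segments through the intrachannel extractor, the enabled GCN branches
#' (with the distance, per-segment connectivity and constrained adaptive
#' normalizers), the separable multi-head attention fusion, and the classifier.
#'
#' @param model An `mgcna_model`.
#' @param x A single channels x samples matrix or a channels x samples x batch
#'   array.
#' @param train Use batch statistics and (optionally) dropout.
#' @param dropout Apply dropout when `train = TRUE`. Default `train`.
#' @param keep_cache Retain intermediate activations (for the backward pass).
#' @return List with `probs` (n_classes x batch, per-class sigmoid outputs),
#'   `pred` (0/1, ties broken to class 0), plus `cache`/`state` internals.
#' @export
mgcna_forward <- function(model, x, train = FALSE, dropout = train,
                          keep_cache = FALSE) {
  cfg <- model$config
  n <- cfg$n_channels
  M <- stack_segments(x)
  abort_if(ncol(M) != cfg$window_samples,
           "input has ", ncol(M), " samples per channel; config expects ",
           cfg$window_samples)
  bt <- nrow(M) %/% n
  ext <- fwd_extract(model, M, bt)
  N <- ext$N
  br <- enabled_branches(cfg)

  Sobjs <- list()
  s3 <- NULL
  if ("distance" %in% br) Sobjs$distance <- model$fixed$S1
  if ("connectivity" %in% br) Sobjs$connectivity <- compute_S2(model, N, bt)
  if ("adaptive" %in% br) {
    s3 <- compute_S3(model, train)
    Sobjs$adaptive <- s3$S
  }

  gcn_out <- list(); gcn_state <- model$state$gcn
  L <- n * cfg$gcn_dim
  Zarr <- array(0, c(length(br), L, bt))
  for (i in seq_along(br)) {
    g <- fwd_gcn_branch(model, br[i], N, Sobjs[[br[i]]], bt, train)
    gcn_out[[br[i]]] <- g
    gcn_state[[br[i]]] <- g$state
    Zarr[i, , ] <- z_to_slab(g$z, n, bt)
  }

  att <- NULL
  if (cfg$attention) {
    att <- fwd_attention(model, Zarr, bt, train)
    Zp <- att$Zp
  } else Zp <- Zarr

  clf <- fwd_classifier(model, Zp, bt, train, dropout)
  pred <- as.integer(clf$probs[2L, ] > clf$probs[1L, ])

  out <- list(probs = clf$probs, logits = clf$logits, pred = pred, bt = bt)
  out$state <- list(gcn = gcn_state,
                    bn14 = if (!is.null(att)) att$state$bn14 else model$state$bn14,
                    bn15 = if (!is.null(att)) att$state$bn15 else model$state$bn15,
                    a3 = if (!is.null(s3) && train)
                      list(rm = 0.9 * model$state$a3$rm + 0.1 * s3$cache$mu,
                           rv = 0.9 * model$state$a3$rv + 0.1 * s3$cache$sd_^2)
                    else model$state$a3)
  if (keep_cache) {
    out$cache <- list(ext = ext, N = N, Sobjs = Sobjs, s3 = s3,
                      gcn = gcn_out, Zarr = Zarr, att = att, clf = clf$cache,
                      bt = bt)
  }
  out
}

# ---- backward ----------------------------------------------------------------

# Gradient of loss w.r.t. a shared propagation matrix:  Y_s = S G_s  per
# segment, so dS = sum_s dY_s t(G_s).
accum_dS <- function(dY, G, n, bt) {
  dS <- matrix(0, n, n)
  for (s in seq_len(bt)) {
    rows <- ((s - 1L) * n + 1L):(s * n)
    dS <- dS + dY[rows, , drop = FALSE] %*% t(G[rows, , drop = FALSE])
  }
  dS
}

# Backward through S = D^-1/2 (A+I) D^-1/2 w.r.t. the unnormalized A + I,
# including the degree path: dAt_kl = GS_kl / sqrt(d_k d_l) + c_k with
# c_k = -(rowSums(GS*S)_k + colSums(GS*S)_k) / (2 d_k).
normalizer_backward <- function(GS, At, dvec) {
  di <- 1 / sqrt(dvec)
  S <- di * At * rep(di, each = nrow(At))
  term1 <- di * GS * rep(di, each = nrow(At))
  GSS <- GS * S
  ck <- -(rowSums(GSS) + colSums(GSS)) / (2 * dvec)
  term1 + matrix(ck, nrow(At), ncol(At))
}

mgcna_backward <- function(model, fw, labels, loss_mode = "positive_unit") {
  cfg <- model$config
  n <- cfg$n_channels; P <- cfg$gcn_dim
  ch <- fw$cache
  bt <- ch$bt
  L <- n * P
  eps_p <- 1e-7
  p1 <- pmin(pmax(fw$probs[2L, ], eps_p), 1 - eps_p)
  loss <- -mean(labels * log(p1) + (1 - labels) * log(1 - p1))
  dlogits <- matrix(0, cfg$n_classes, bt)
  dlogits[2L, ] <- (fw$probs[2L, ] - labels) / bt
  if (loss_mode == "two_unit") {
    p0 <- pmin(pmax(fw$probs[1L, ], eps_p), 1 - eps_p)
    loss <- loss - mean((1 - labels) * log(p0) + labels * log(1 - p0))
    dlogits[1L, ] <- (fw$probs[1L, ] - (1 - labels)) / bt
  }

  grads <- param_zeros_like(model$params)
  clf <- ch$clf; pc <- model$params$clf

  grads$clf$lw <- dlogits %*% t(clf$gap_d)
  grads$clf$lb <- rowSums(dlogits)
  dgap_d <- crossprod(pc$lw, dlogits)
  dgap <- if (is.null(clf$mask)) dgap_d else dgap_d * clf$mask
  dR2 <- broadcast_positions(dgap / L, L)
  dY2 <- drelu(dR2, clf$co2$y)
  cb2 <- conv3x3_backward(dY2, pc$c2w, clf$co2)
  grads$clf$c2w <- cb2$dW; grads$clf$c2b <- cb2$db
  dY1 <- drelu(cb2$dx, clf$co1$y)
  cb1 <- conv3x3_backward(dY1, pc$c1w, clf$co1)
  grads$clf$c1w <- cb1$dW; grads$clf$c1b <- cb1$db
  dZp <- cb1$dx

  br <- enabled_branches(cfg)
  B <- length(br)
  if (cfg$attention) {
    at <- ch$att$cache; pa <- model$params$att
    dm15 <- dZp; dim(dm15) <- c(B, L * bt)
    b15 <- bn_backward(t(dm15), at$bn15)
    grads$att$bn15_g <- b15$dg; grads$att$bn15_b <- b15$db
    dZsum <- t(b15$dx); dim(dZsum) <- c(B, L, bt)
    dZarr <- dZsum
    dMA <- dZsum
    dma <- dMA; dim(dma) <- c(B, L * bt)
    dma <- t(dma) * (at$ma > 0)
    b14 <- bn_backward(dma, at$bn14)
    grads$att$bn14_g <- b14$dg; grads$att$bn14_b <- b14$db
    dCO <- t(b14$dx); dim(dCO) <- c(B, L, bt)
    cba <- conv3x3_backward(dCO, pa$cw, at$conv)
    grads$att$cw <- cba$dW; grads$att$cb <- cba$db
    dattn <- cba$dx
    dVr <- dattn * at$cvb
    dcv <- sum_positions(dattn * at$Vr)
    dVa <- drelu(dVr, at$Va)
    dcvb <- broadcast_positions(dcv, L)
    dKa <- at$Sexp * dcvb
    dSexp <- at$Ka * dcvb
    if (cfg$head_dim == 1L) dSa <- dSexp
    else {
      dm <- dSexp; dim(dm) <- c(length(at$headof), L * bt)
      dm <- rowsum(dm, group = at$headof)
      dSa <- array(dm, c(cfg$n_heads, L, bt))
    }
    dQa <- softmax_positions_backward(dSa, at$Sa)
    dQm <- dQa; dim(dQm) <- c(cfg$n_heads, L * bt)
    dKm <- dKa; dim(dKm) <- c(length(at$headof), L * bt)
    dVm <- dVa; dim(dVm) <- c(length(at$headof), L * bt)
    grads$att$wq <- dQm %*% t(at$Zmat); grads$att$bq <- rowSums(dQm)
    grads$att$wk <- dKm %*% t(at$Zmat); grads$att$bk <- rowSums(dKm)
    grads$att$wv <- dVm %*% t(at$Zmat); grads$att$bv <- rowSums(dVm)
    dZmat <- crossprod(pa$wq, dQm) + crossprod(pa$wk, dKm) +
      crossprod(pa$wv, dVm)
    dZarr <- dZarr + array(dZmat, c(B, L, bt))
  } else dZarr <- dZp

  dN <- matrix(0, bt * n, ncol(ch$N))
  dS3 <- NULL
  for (i in seq_along(br)) {
    b <- br[i]
    dH <- slab_to_z(dZarr[i, , ], n, bt)
    for (l in rev(seq_len(cfg$gcn_layers))) {
      lc <- ch$gcn[[b]]$caches[[l]]
      bnb <- bn_backward(dH, lc$bn)
      grads$gcn[[b]][[l]]$bn_g <- bnb$dg
      grads$gcn[[b]][[l]]$bn_b <- bnb$db
      dY <- drelu(bnb$dx, lc$Y)
      Sobj <- ch$Sobjs[[b]]
      if (b == "adaptive") {
        dS3 <- (dS3 %||% matrix(0, n, n)) + accum_dS(dY, lc$G, n, bt)
      }
      dG <- if (is.list(Sobj)) {
        out <- dY
        for (s in seq_len(bt)) {
          rows <- ((s - 1L) * n + 1L):(s * n)
          out[rows, ] <- crossprod(Sobj[[s]], dY[rows, , drop = FALSE])
        }
        out
      } else apply_shared_S(t(Sobj), dY, n, bt)
      grads$gcn[[b]][[l]]$theta <- crossprod(lc$H_in, dG)
      dH <- tcrossprod(dG, model$params$gcn[[b]][[l]]$theta)
    }
    dN <- dN + dH
  }

  if (!is.null(dS3)) {
    s3 <- ch$s3$cache
    dAt <- normalizer_backward(dS3, s3$At, s3$d)
    dAff <- dAt * (s3$aff > 0)
    grads$a3_aff[["g"]] <- sum(dAff * s3$z)
    grads$a3_aff[["b"]] <- sum(dAff)
    dz <- dAff * model$params$a3_aff[["g"]]
    sden <- s3$sd_ + 1e-5
    if (s3$train) {
      vterm <- if (s3$sd_ > 0) s3$z * mean(dz * s3$z) / s3$sd_ else 0
      grads$a3 <- (dz - mean(dz)) / sden - vterm
    } else grads$a3 <- dz / sden
  }

  dM <- dN
  chidx <- ch$ext$chidx
  for (l in rev(seq_len(cfg$k_depthwise))) {
    ec <- ch$ext$cache[[l]]
    pe <- model$params$ext[[l]]
    grads$ext[[l]]$w1 <- as.numeric(rowsum(rowSums(dM * ec$Modd), chidx))
    grads$ext[[l]]$w2 <- as.numeric(rowsum(rowSums(dM * ec$Meven), chidx))
    grads$ext[[l]]$b <- as.numeric(rowsum(rowSums(dM), chidx))
    if (l > 1L) {
      dPrev <- matrix(0, nrow(dM), 2L * ncol(dM))
      odd <- seq(1L, ncol(dPrev), by = 2L)
      dPrev[, odd] <- dM * pe$w1[chidx]
      dPrev[, odd + 1L] <- dM * pe$w2[chidx]
      dM <- dPrev
    }
  }

  list(loss = loss, grads = grads)
}

#' Loss and parameter gradients on a batch
#'
#' Forward pass in training mode followed by the analytic backward pass.
#' Binary cross-entropy is computed on the positive-class (ictal) sigmoid unit
#' (optionally on both units), probabilities clamped at `1e-7`.
#'
#' @param model An `mgcna_model`.
#' @param x Batch array (channels x samples x batch) or single matrix.
#' @param labels 0/1 vector, one per segment.
#' @param train Training mode (batch-norm batch statistics). Default `TRUE`.
#' @param dropout Apply dropout. Default `FALSE` (callers that optimize enable
#'   it; gradient checks keep it off for determinism).
#' @param loss_mode `"positive_unit"` or `"two_unit"`.
#' @return List with `loss`, `grads` (parameter-shaped), `probs`, and updated
#'   batch-norm `state`.
#' @export
mgcna_loss_grads <- function(model, x, labels, train = TRUE, dropout = FALSE,
                             loss_mode = c("positive_unit", "two_unit")) {
  loss_mode <- match.arg(loss_mode)
  fw <- mgcna_forward(model, x, train = train, dropout = dropout,
                      keep_cache = TRUE)
  bw <- mgcna_backward(model, fw, labels, loss_mode)
  list(loss = bw$loss, grads = bw$grads, probs = fw$probs, state = fw$state)
}

#' Predict ictal probabilities for segments
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no dropout),
#' batched for memory.
#'
#' @param model A trained `mgcna_model`.
#' @param segs A `segment_set`, or a channels x samples x batch array.
#' @param indices Optional segment indices to score.
#' @param batch_size Internal batch size. Default 64.
#' @return List with `prob_ictal` (positive-unit sigmoid output), `pred`
#'   (0/1, tie broken to 0).
#' @export
predict_mgcna <- function(model, segs, indices = NULL, batch_size = 64L) {
  x <- if (inherits(segs, "segment_set")) segs$x else segs
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  idx <- indices %||% seq_len(dim(x)[3L])
  prob <- numeric(length(idx))
  p0 <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[start:min(start + batch_size - 1L, length(idx))]
    fw <- mgcna_forward(model, x[, , sel, drop = FALSE], train = FALSE)
    prob[start:(start + length(sel) - 1L)] <- fw$probs[2L, ]
    p0[start:(start + length(sel) - 1L)] <- fw$probs[1L, ]
  }
  list(prob_ictal = prob, pred = as.integer(prob > p0))
}

# ---- exposed per-stage operations -------------------------------------------

#' Depthwise intrachannel feature extraction
#'
#' `k` successive depthwise convolutions (kernel width 2, stride 2, no padding,
#' no cross-channel mixing), each halving the temporal resolution. With `C`
#' input samples the output is `n x C/2^k`. When no weights are given, an
#' averaging kernel (`w1 = w2 = 0.5`) is used.
#'
#' @param x Channels x samples matrix (`C` divisible by `2^k`).
#' @param k Number of halving layers.
#' @param weights Optional list of per-layer lists `w1`, `w2`, `b` (each length
#'   n), e.g. `model$params$ext` of a fitted model.
#' @return n x (C / 2^k) feature matrix.
#' @export
intrachannel_extract <- function(x, k = 2L, weights = NULL) {
  abort_if(!is.matrix(x), "`x` must be a channels x samples matrix")
  abort_if(ncol(x) %% 2L^k != 0, "sample count must be divisible by 2^k")
  n <- nrow(x)
  if (is.null(weights))
    weights <- replicate(max(k, 0L), list(w1 = rep(0.5, n), w2 = rep(0.5, n),
                                          b = numeric(n)), simplify = FALSE)
  M <- x
  for (l in seq_len(k)) {
    odd <- seq(1L, ncol(M), by = 2L)
    M <- M[, odd, drop = FALSE] * weights[[l]]$w1 +
      M[, odd + 1L, drop = FALSE] * weights[[l]]$w2 + weights[[l]]$b
  }
  M
}

#' One graph-convolution layer
#'
#' `ReLU(D^-1/2 (A + I) D^-1/2 H theta)`: symmetric-normalized neighborhood
#' aggregation followed by a linear map and rectification. Per-layer batch
#' normalization is applied by the full network; here it is optional so the
#' propagation rule can be inspected in isolation.
#'
#' @param H n x F node-feature matrix.
#' @param A n x n adjacency (matrix or `adjacency` object), diagonal zero.
#' @param theta F x F' weight matrix (default identity).
#' @return n x F' activated features.
#' @export
gcn_layer <- function(H, A, theta = NULL) {
  if (inherits(A, "adjacency")) A <- A$matrix
  abort_if(!is.matrix(A) || nrow(A) != ncol(A), "`A` must be square")
  abort_if(nrow(H) != nrow(A), "H row count must match A")
  if (is.null(theta)) theta <- diag(ncol(H))
  relu(normalize_adjacency(A) %*% H %*% theta)
}

#' Multi-branch GCN forward for one segment
#'
#' Runs the intrachannel feature matrix `N` through every enabled branch of the
#' model (identical structure, unshared parameters) and stacks the outputs.
#'
#' @param model An `mgcna_model`.
#' @param N n x D feature matrix (the extractor output).
#' @param adjacencies Optional named list overriding the branch adjacencies
#'   (entries `distance`, `connectivity`, `adaptive`; matrices, un-normalized).
#' @param train Batch-statistics mode for the per-layer normalization.
#' @return Array of shape (branches, n, P).
#' @export
multibranch_forward <- function(model, N, adjacencies = NULL, train = FALSE) {
  cfg <- model$config
  n <- cfg$n_channels
  abort_if(nrow(N) != n, "N must have n_channels rows")
  br <- enabled_branches(cfg)
  if (!is.null(adjacencies))
    abort_if(!all(br %in% names(adjacencies)),
             "`adjacencies` must name one matrix per enabled branch")
  Z <- array(0, c(length(br), n, cfg$gcn_dim))
  for (i in seq_along(br)) {
    b <- br[i]
    Sobj <- if (!is.null(adjacencies)) normalize_adjacency(adjacencies[[b]])
    else switch(b,
                distance = model$fixed$S1,
                connectivity = compute_S2(model, N, 1L)[[1L]],
                adaptive = compute_S3(model, train)$S)
    g <- fwd_gcn_branch(model, b, N, Sobj, 1L, train)
    Z[i, , ] <- g$z
  }
  Z
}

#' Separable multi-head attention fusion for one segment
#'
#' Unshared 1x1 convolutions over the branch axis produce queries, keys and
#' values; per head, a softmax over all `n * P` positions of the query forms
#' context scores, the score-weighted sum of the key forms a context vector,
#' and the rectified value is modulated elementwise by the broadcast context.
#' Head outputs are concatenated, passed through a 3x3 convolution with batch
#' normalization and ReLU, added residually to the input, and normalized.
#' Output shape equals input shape.
#'
#' @param model An `mgcna_model` (attention enabled).
#' @param Z (branches, n, P) array from [multibranch_forward()].
#' @param train Batch-statistics mode.
#' @param details Also return the per-head softmax scores.
#' @return Fused array of the same shape; with `details`, a list with `Zp` and
#'   `scores` (heads x positions x 1).
#' @export
separable_attention <- function(model, Z, train = FALSE, details = FALSE) {
  cfg <- model$config
  abort_if(!cfg$attention, "model was built without the attention module")
  n <- cfg$n_channels; P <- cfg$gcn_dim
  B <- dim(Z)[1L]
  Zarr <- array(aperm(Z, c(1L, 2L, 3L)), c(B, n * P, 1L))
  out <- fwd_attention(model, Zarr, 1L, train)
  Zp <- array(out$Zp, c(B, n, P))
  if (details) list(Zp = Zp, scores = out$scores) else Zp
}

#' Classifier head for one segment
#'
#' Two 3x3 convolutions with ReLU, global average pooling, dropout (training
#' only), a linear map to the class units, and elementwise sigmoid. The
#' predicted class is the index of the larger probability; an exact tie breaks
#' to class 0 (interictal).
#'
#' @param model An `mgcna_model`.
#' @param Zf (branches, n, P) fused array.
#' @param train Enable dropout.
#' @return List with `probs` (length n_classes) and `class` (0 or 1).
#' @export
classify <- function(model, Zf, train = FALSE) {
  cfg <- model$config
  Zarr <- array(Zf, c(dim(Zf)[1L], cfg$n_channels * cfg$gcn_dim, 1L))
  out <- fwd_classifier(model, Zarr, 1L, train, dropout = train)
  probs <- as.numeric(out$probs)
  list(probs = probs, class = as.integer(probs[2L] > probs[1L]))
}

#' Describe a model's layers and parameter counts
#'
#' @param model An `mgcna_model`.
#' @return Invisibly, a data.frame of components and parameter counts (printed).
#' @export
mgcna_describe <- function(model) {
  cfg <- model$config
  rows <- list()
  add <- function(name, shape, count) {
    rows[[length(rows) + 1L]] <<- data.frame(component = name, shape = shape,
                                             params = count)
  }
  D <- cfg$window_samples %/% 2L^cfg$k_depthwise
  add("intrachannel extractor",
      sprintf("(%d,1,%d) -> (%d,%d), k=%d", cfg$n_channels, cfg$window_samples,
              cfg$n_channels, D, cfg$k_depthwise),
      param_count(model$params$ext))
  for (b in enabled_branches(cfg))
    add(paste0("gcn branch: ", b),
        sprintf("%d layers, width %d", cfg$gcn_layers, cfg$gcn_dim),
        param_count(model$params$gcn[[b]]))
  if (!is.null(model$params$a3))
    add("adaptive adjacency", sprintf("%dx%d", cfg$n_channels, cfg$n_channels),
        param_count(model$params$a3) + param_count(model$params$a3_aff))
  if (cfg$attention)
    add("separable attention",
        sprintf("h=%d, d=%d", cfg$n_heads, cfg$head_dim),
        param_count(model$params$att))
  add("classifier",
      sprintf("conv %d/%d, linear %d", cfg$classifier_channels[1L],
              cfg$classifier_channels[2L], cfg$n_classes),
      param_count(model$params$clf))
  df <- do.call(rbind, rows)
  df <- rbind(df, data.frame(component = "total", shape = "",
                             params = param_count(model$params)))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Floating-point operation count of the attention module
#'
#' Closed-form multiply-add count of one separable-attention forward pass as a
#' function of the configuration; linear in the token count `n * P`, which is
#' the point of the separable formulation.
#'
#' @param config A [model_config()].
#' @return Numeric operation count.
#' @export
attention_flops <- function(config) {
  L <- config$n_channels * config$gcn_dim
  B <- sum(config$branches)
  h <- config$n_heads; hd <- h * config$head_dim
  qkv <- 2 * (h + 2 * hd) * B * L
  soft <- 5 * h * L
  context <- 2 * hd * L
  modulate <- 2 * hd * L
  conv <- 2 * 9 * hd * B * L
  norm <- 8 * B * L
  qkv + soft + context + modulate + conv + norm
}

#' Save or load a model checkpoint
#'
#' Single-file archive holding the weights, the configuration (also mirrored as
#' JSON next to the file), the batch-norm state and the frozen distance
#' adjacency.
#'
#' @param model An `mgcna_model`.
#' @param path Checkpoint path.
#' @return `load_checkpoint()` returns the `mgcna_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               state = model$state, seed = model$seed,
               layout = unclass(model$fixed$layout),
               A1 = model$fixed$A1), path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "model_config")
  layout <- structure(obj$layout, class = "electrode_layout")
  model <- mgcna_init(cfg, layout = layout, seed = obj$seed)
  model$params <- obj$params
  model$state <- obj$state
  model
}
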