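# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately re-derive every quantity with plain double
# loops so they share no code with the implementation they check.

# -- adjacency oracles --------------------------------------------------------

oracle_distance_adjacency <- function(coords, R1, half = TRUE) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  D <- D / max(D)
  dv <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) dv <- c(dv, D[i, j])
  delta <- sqrt(mean((dv - mean(dv))^2))
  denom <- if (half) 2 * delta^2 else delta^2
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && D[i, j] <= R1) A[i, j] <- exp(-D[i, j]^2 / denom)
  }
  A
}

oracle_correlation_adjacency <- function(x, R2) {
  n <- nrow(x)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    rho <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    w <- (rho + 1) / 2
    if (w >= R2) A[i, j] <- w
  }
  A
}

# -- metric oracles -----------------------------------------------------------

oracle_confusion <- function(labels, pred) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (labels[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (labels[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (labels[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       acc = (tp + tn) / length(labels),
       sens = tp / (tp + fn), spec = tn / (tn + fp),
       f1 = {
         prec <- tp / (tp + fp); rec <- tp / (tp + fn)
         2 * prec * rec / (prec + rec)
       })
}

oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# -- fixtures -----------------------------------------------------------------

tiny_config <- function(...) {
  model_config(n_channels = 6L, window_samples = 32L, k_depthwise = 2L,
               gcn_layers = 2L, gcn_dim = 8L, n_heads = 3L, head_dim = 1L,
               classifier_channels = c(4L, 5L), ...)
}

raw_recording <- function(signal, fs = 256, intervals = list(), id = "TST") {
  nm <- if (nrow(signal) == 22L) canonical_channels()
        else sprintf("CH%02d", seq_len(nrow(signal)))
  rownames(signal) <- nm
  structure(list(signal = signal, fs = fs, channel_names = nm,
                 seizure_intervals = intervals, patient_id = id),
            class = "eeg_recording")
}

random_layout <- function(n, seed) {
  set.seed(seed)
  coords <- cbind(x = runif(n, -1, 1), y = runif(n, -1, 1))
  nm <- sprintf("CH%02d", seq_len(n))
  rownames(coords) <- nm
  structure(list(names = nm, coords = coords), class = "electrode_layout")
}

# small labeled segment set with arbitrary class counts
fake_segments <- function(n_ictal, n_interictal, n_ch = 4L, W = 16L,
                          patients = "P01", seed = 1) {
  set.seed(seed)
  K <- n_ictal + n_interictal
  x <- array(rnorm(n_ch * W * K), c(n_ch, W, K))
  labels <- c(rep(1L, n_ictal), rep(0L, n_interictal))
  mgcna:::new_segment_set(x, labels,
                          rep_len(patients, K), 256, W / 256,
                          sprintf("CH%02d", seq_len(n_ch)))
}
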