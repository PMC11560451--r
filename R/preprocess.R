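norm_channel_name <- function(x) {
  x <- toupper(gsub("[[:space:]]+", "", x))
  # unify duplicate-suffix labels ("T8-P8-0") to their base derivation
  sub("-[0-9]+$", "", x)
}

#' Select and order montage channels
#'
#' Reorders the rows of a recording to a wanted channel list (by default the
#' canonical 22-derivation montage). Matching is case-insensitive and ignores
#' whitespace and duplicate-numbering suffixes; when a derivation appears more
#' than once, the first occurrence is kept. A missing derivation is an error
#' naming the absent channel -- never silently zero-filled.
#'
#' @param rec An `eeg_recording`.
#' @param wanted Ordered character vector of derivation names.
#' @return An `eeg_recording` with rows in `wanted` order.
#' @export
select_channels <- function(rec, wanted = canonical_channels()) {
  have <- norm_channel_name(rec$channel_names)
  want <- norm_channel_name(wanted)
  idx <- match(want, have)
  if (anyNA(idx))
    stop("missing channel(s): ", paste(wanted[is.na(idx)], collapse = ", "),
         call. = FALSE)
  out <- rec
  out$signal <- rec$signal[idx, , drop = FALSE]
  out$channel_names <- wanted
  rownames(out$signal) <- wanted
  out
}

# Butterworth band-pass as analytically derived second-order sections:
# prototype poles -> low-pass-to-band-pass transform -> bilinear map. Each
# biquad keeps the exact (z-1)(z+1) zeros and is normalized to unit gain at
# the band center, so the cascade is numerically well-conditioned even for a
# 0.5 Hz edge -- unlike a direct-form transfer function of order 2n.
butter_bandpass_sos <- function(low_hz, high_hz, fs, order) {
  w1 <- 2 * fs * tan(pi * low_hz / fs)       # prewarped edges (rad/s)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  Bw <- w2 - w1
  w0sq <- w1 * w2
  theta0 <- 2 * atan(sqrt(w0sq) / (2 * fs))  # digital band center
  bilinear <- function(s) (1 + s / (2 * fs)) / (1 - s / (2 * fs))
  bp_pair <- function(p) {                   # analog band-pass poles of one
    disc <- sqrt(as.complex((Bw * p)^2 - 4 * w0sq))   # prototype pole
    c((Bw * p + disc) / 2, (Bw * p - disc) / 2)
  }
  sections <- list()
  add_biquad <- function(z1, z2) {
    a <- c(1, -Re(z1 + z2), Re(z1 * z2))
    ejw <- exp(1i * theta0)
    h <- (ejw^2 - 1) / (ejw^2 + a[2L] * ejw + a[3L])
    sections[[length(sections) + 1L]] <<-
      list(b = c(1, 0, -1) / Mod(h), a = a)
  }
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  for (p in proto[Im(proto) > 1e-9]) {
    sp <- bp_pair(p)
    add_biquad(bilinear(sp[1L]), Conj(bilinear(sp[1L])))
    add_biquad(bilinear(sp[2L]), Conj(bilinear(sp[2L])))
  }
  if (order %% 2L == 1L) {
    sp <- bp_pair(-1 + 0i)
    add_biquad(bilinear(sp[1L]), bilinear(sp[2L]))
  }
  sections
}

sos_filtfilt <- function(sections, x) {
  pass <- function(v) {
    for (s in sections)
      v <- as.numeric(signal::filter(signal::Arma(b = s$b, a = s$a), v))
    v
  }
  rev(pass(rev(pass(x))))
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass (default fifth order, 0.5-70 Hz) applied to each
#' channel independently. The filter runs as a cascade of analytically derived
#' second-order sections, applied forward-backward (zero phase; the effective
#' order doubles and phase distortion cancels -- standard EEG practice).
#'
#' @param rec An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Filter order (per pass). Default 5.
#' @return Filtered `eeg_recording`.
#' @export
bandpass <- function(rec, low_hz = 0.5, high_hz = 70, order = 5L) {
  abort_if(!(low_hz > 0 && low_hz < high_hz), "need 0 < low_hz < high_hz")
  abort_if(high_hz >= rec$fs / 2,
           "high_hz must be below the Nyquist frequency fs/2")
  sos <- butter_bandpass_sos(low_hz, high_hz, rec$fs, order)
  out <- rec
  out$signal <- t(apply(rec$signal, 1L, function(x) sos_filtfilt(sos, x)))
  rownames(out$signal) <- rec$channel_names
  out
}

new_segment_set <- function(x, labels, patient_ids, fs, window_s, channel_names) {
  structure(list(x = x, labels = as.integer(labels),
                 patient_ids = patient_ids, fs = fs, window_s = window_s,
                 channel_names = channel_names),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments (%d ictal / %d interictal), %d ch x %g s @ %g Hz\n",
              n_segments(x), sum(x$labels == 1L), sum(x$labels == 0L),
              dim(x$x)[1L], x$window_s, x$fs))
  invisible(x)
}

#' Number of segments in a segment set
#' @param segs A `segment_set`.
#' @export
n_segments <- function(segs) length(segs$labels)

#' Window a recording into labeled fixed-length segments
#'
#' Ictal stretches are windowed with stride `window_s * (1 - ictal_overlap)`
#' (default 50% overlap, to multiply the scarce ictal class); interictal
#' stretches use non-overlapping windows. A window is labeled ictal only when
#' it lies entirely inside a seizure interval; windows straddling an onset or
#' offset are discarded. Seizure intervals are half-open `[onset, offset)`.
#'
#' @param rec An `eeg_recording`.
#' @param window_s Window length in seconds; `window_s * fs` must be integral.
#' @param ictal_overlap Fractional overlap for ictal windows, in `[0, 1)`.
#' @return A `segment_set` whose `x` is a channels x samples x segments array.
#'   A record shorter than one window yields an empty set with a warning.
#' @export
segment_record <- function(rec, window_s = 3, ictal_overlap = 0.5) {
  W <- window_s * rec$fs
  abort_if(abs(W - round(W)) > 1e-9, "window_s * fs must be integral")
  W <- as.integer(round(W))
  abort_if(ictal_overlap < 0 || ictal_overlap >= 1,
           "ictal_overlap must be in [0, 1)")
  dur <- ncol(rec$signal) / rec$fs
  ivs <- rec$seizure_intervals
  if (length(ivs)) ivs <- ivs[order(vapply(ivs, `[`, 0, 1L))]

  starts <- numeric(0); labels <- integer(0)
  add_windows <- function(a, b, stride, lab) {
    if (b - a >= window_s) {
      st <- seq(a, b - window_s, by = stride)
      starts <<- c(starts, st)
      labels <<- c(labels, rep(lab, length(st)))
    }
  }
  stride_ict <- window_s * (1 - ictal_overlap)
  prev <- 0
  for (iv in ivs) {
    add_windows(prev, iv[1L], window_s, 0L)      # interictal gap before
    add_windows(iv[1L], iv[2L], stride_ict, 1L)  # inside the seizure
    prev <- iv[2L]
  }
  add_windows(prev, dur, window_s, 0L)

  if (!length(starts)) {
    warning("record shorter than one window; empty segment set")
    return(new_segment_set(array(0, c(nrow(rec$signal), W, 0L)), integer(0),
                           character(0), rec$fs, window_s, rec$channel_names))
  }
  K <- length(starts)
  x <- array(0, c(nrow(rec$signal), W, K))
  for (k in seq_len(K)) {
    i0 <- round(starts[k] * rec$fs) + 1L
    x[, , k] <- rec$signal[, i0:(i0 + W - 1L)]
  }
  new_segment_set(x, labels, rep(rec$patient_id, K), rec$fs, window_s,
                  rec$channel_names)
}

#' Concatenate segment sets
#'
#' @param sets List of `segment_set`s sharing fs, window and channels.
#' @return A single `segment_set`.
#' @export
bind_segment_sets <- function(sets) {
  abort_if(!length(sets), "no segment sets to bind")
  fs <- sets[[1L]]$fs; ws <- sets[[1L]]$window_s
  for (s in sets) abort_if(s$fs != fs || s$window_s != ws,
                           "segment sets differ in fs or window length")
  W <- dim(sets[[1L]]$x)[2L]; n <- dim(sets[[1L]]$x)[1L]
  K <- sum(vapply(sets, n_segments, 0L))
  x <- array(0, c(n, W, K))
  at <- 0L
  for (s in sets) {
    k <- n_segments(s)
    if (k) x[, , at + seq_len(k)] <- s$x
    at <- at + k
  }
  new_segment_set(x, unlist(lapply(sets, `[[`, "labels")),
                  unlist(lapply(sets, `[[`, "patient_ids")),
                  fs, ws, sets[[1L]]$channel_names)
}

subset_segments <- function(segs, idx) {
  new_segment_set(segs$x[, , idx, drop = FALSE], segs$labels[idx],
                  segs$patient_ids[idx], segs$fs, segs$window_s,
                  segs$channel_names)
}

#' Rebalance the interictal/ictal segment pool
#'
#' Keeps every ictal segment and randomly subsamples interictal segments
#' (without replacement, seeded) so that at most `interictal_to_ictal` of them
#' remain per ictal segment. Default ratio 5.
#'
#' @param segs A `segment_set` containing both classes.
#' @param interictal_to_ictal Maximum interictal:ictal ratio. Default 5.
#' @param seed Integer seed.
#' @return A `segment_set` (segment order: original order of the kept indices).
#' @export
rebalance_pool <- function(segs, interictal_to_ictal = 5, seed = 1L) {
  ict <- which(segs$labels == 1L)
  inter <- which(segs$labels == 0L)
  abort_if(!length(ict), "no ictal segments; cannot rebalance")
  n_keep <- min(length(inter), round(interictal_to_ictal * length(ict)))
  keep <- with_seed(derive_seed(seed, "rebalance"),
                    sort(sample(inter, n_keep)))
  subset_segments(segs, sort(c(ict, keep)))
}

#' Build cross-validation splits
#'
#' Patient-specific mode: stratified `n_folds`-fold over the segments of a
#' single subject; fold `i` is the test set, the next fold cyclically is the
#' validation set, the rest train. Patient-independent mode: leave-one-subject
#' -out -- one fold per patient whose segments form the test set; of the
#' remaining patients one (seeded choice) is held out for validation and the
#' others train. Test folds are disjoint and cover all segments in both modes.
#'
#' @param segs A `segment_set`.
#' @param mode `"patient_specific"` or `"patient_independent"`.
#' @param n_folds Number of folds for patient-specific mode. Default 5.
#' @param seed Integer seed.
#' @return List of folds; each fold is `list(train, val, test)` index vectors.
#'   Carries attributes `mode` and (LOSO) `test_patient` per fold.
#' @export
make_splits <- function(segs, mode = c("patient_specific", "patient_independent"),
                        n_folds = 5L, seed = 1L) {
  mode <- match.arg(mode)
  pats <- unique(segs$patient_ids)
  if (mode == "patient_specific") {
    abort_if(length(pats) != 1L,
             "patient_specific mode requires a single patient")
    folds_of <- integer(n_segments(segs))
    with_seed(derive_seed(seed, "folds"), {
      for (cl in unique(segs$labels)) {
        idx <- sample(which(segs$labels == cl))
        folds_of[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    })
    folds <- lapply(seq_len(n_folds), function(i) {
      val_fold <- (i %% n_folds) + 1L
      list(train = which(!folds_of %in% c(i, val_fold)),
           val = which(folds_of == val_fold),
           test = which(folds_of == i))
    })
  } else {
    abort_if(length(pats) < 3L,
             "patient_independent (leave-one-subject-out) requires >= 3 patients")
    folds <- lapply(seq_along(pats), function(i) {
      test_p <- pats[i]
      held_in <- setdiff(pats, test_p)
      val_p <- with_seed(derive_seed(seed, "loso-val", i),
                         sample(held_in, 1L))
      f <- list(train = which(segs$patient_ids %in% setdiff(held_in, val_p)),
                val = which(segs$patient_ids == val_p),
                test = which(segs$patient_ids == test_p))
      attr(f, "test_patient") <- test_p
      f
    })
  }
  attr(folds, "mode") <- mode
  folds
}

#' Preprocess recordings into a pooled segment set
#'
#' Convenience pipeline: channel selection (when the montage matches), band-pass
#' filtering, windowed segmentation, pooling across recordings, and 5:1
#' rebalancing. This is the preprocessing used by the evaluation protocols.
#'
#' @param recs List of `eeg_recording`s (or a single one).
#' @param low_hz,high_hz,order Band-pass parameters (defaults 0.5, 70, 5).
#' @param window_s,ictal_overlap Segmentation parameters (defaults 3, 0.5).
#' @param ratio Interictal:ictal rebalancing ratio (default 5); `Inf` disables.
#' @param seed Seed for the rebalancing draw.
#' @return A `segment_set`.
#' @export
prepare_segments <- function(recs, low_hz = 0.5, high_hz = 70, order = 5L,
                             window_s = 3, ictal_overlap = 0.5, ratio = 5,
                             seed = 1L) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  sets <- lapply(recs, function(r)
    segment_record(bandpass(r, low_hz, high_hz, order), window_s, ictal_overlap))
  segs <- bind_segment_sets(sets)
  if (is.finite(ratio)) segs <- rebalance_pool(segs, ratio, seed)
  segs
}

#' Serialize a segment set
#'
#' Array bundle (RDS) plus a JSON sidecar recording fs, window length, channel
#' names and per-patient segment counts.
#'
#' @param segs A `segment_set`.
#' @param path Output path for the bundle; the sidecar is `<path>.json`.
#' @return `read_segments()` returns the `segment_set`.
#' @export
write_segments <- function(segs, path) {
  saveRDS(unclass(segs), path, compress = "gzip")
  side <- list(fs = segs$fs, window_s = segs$window_s,
               n_segments = n_segments(segs),
               channel_names = segs$channel_names,
               patients = as.list(table(segs$patient_ids)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  obj <- readRDS(path)
  new_segment_set(obj$x, obj$labels, obj$patient_ids, obj$fs, obj$window_s,
                  obj$channel_names)
}
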