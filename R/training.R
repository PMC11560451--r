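#' Optimization configuration
#'
#' @param lr Adam learning rate. Default `3e-4`.
#' @param weight_decay Decoupled l2 weight decay applied to all trainable
#'   parameters (the l2 trade-off is realized through the optimizer).
#'   Default `1e-3`.
#' @param epochs Maximum training epochs. Default 100.
#' @param batch_size Segments per batch. Default 64.
#' @param seed Integer seed governing epoch resampling, dropout and shuffling.
#' @param early_stop_patience Epochs without validation-loss improvement before
#'   stopping (best weights are restored). Default 10.
#' @param l2_mode `"decoupled"` (default) or `"explicit"`, which instead adds
#'   `tau * ||Omega||_2` to the loss with its exact gradient.
#' @param tau Trade-off for `l2_mode = "explicit"`; defaults to `weight_decay`.
#' @param loss_mode `"positive_unit"` (binary cross-entropy on the ictal
#'   sigmoid unit, default) or `"two_unit"` (summed over both units).
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 3e-4, weight_decay = 1e-3, epochs = 100L,
                         batch_size = 64L, seed = 1L,
                         early_stop_patience = 10L,
                         l2_mode = c("decoupled", "explicit"), tau = NULL,
                         loss_mode = c("positive_unit", "two_unit")) {
  l2_mode <- match.arg(l2_mode)
  loss_mode <- match.arg(loss_mode)
  abort_if(!is_scalar(lr) || lr <= 0, "lr must be positive")
  abort_if(!is_count(epochs), "epochs must be >= 1")
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 l2_mode = l2_mode, tau = tau %||% weight_decay,
                 loss_mode = loss_mode),
            class = "train_config")
}

#' Binary cross-entropy loss with optional l2 penalty
#'
#' `-(y log p + (1 - y) log(1 - p))` on the positive-class probability,
#' clamped at `1e-7`, averaged over segments, plus `tau * ||Omega||_2` when a
#' parameter set is supplied.
#'
#' @param prob_pos Predicted positive-class probabilities.
#' @param label 0/1 labels.
#' @param params Optional parameter list (nested numeric arrays) for the
#'   penalty term.
#' @param tau Penalty trade-off. Default 0.
#' @return Scalar loss.
#' @export
bce_loss <- function(prob_pos, label, params = NULL, tau = 0) {
  p <- pmin(pmax(prob_pos, 1e-7), 1 - 1e-7)
  ce <- -mean(label * log(p) + (1 - label) * log(1 - p))
  if (!is.null(params) && tau > 0)
    ce <- ce + tau * sqrt(param_dot(params, params))
  ce
}

#' Class-balanced per-epoch training subset
#'
#' Every epoch keeps all ictal training segments and draws an equal number of
#' interictal segments uniformly without replacement (seeded per epoch), then
#' shuffles the union, yielding a balanced batch stream.
#'
#' @param segs A `segment_set`.
#' @param train_idx Indices forming the training pool (default: all segments).
#' @param seed_epoch Integer seed for this epoch's draw.
#' @return Shuffled integer index vector (into `segs`).
#' @export
balanced_epoch_subset <- function(segs, train_idx = NULL, seed_epoch = 1L) {
  idx <- train_idx %||% seq_len(n_segments(segs))
  ict <- idx[segs$labels[idx] == 1L]
  inter <- idx[segs$labels[idx] == 0L]
  abort_if(!length(ict) || !length(inter),
           "both classes must be present in the training pool")
  with_seed(seed_epoch, {
    draw <- if (length(inter) > length(ict)) sample(inter, length(ict))
            else inter
    sample(c(ict, draw))
  })
}

explicit_l2_grads <- function(grads, params, tau) {
  nrm <- sqrt(param_dot(params, params))
  if (nrm == 0) return(grads)
  param_map(function(g, p) g + tau * p / nrm, grads, params)
}

#' Train a model on one split
#'
#' Adam optimization (decoupled weight decay) of all trainable parameters
#' including the raw adaptive adjacency, on per-epoch class-balanced subsets,
#' with early stopping on validation loss and restoration of the best weights.
#' Fully seeded: identical configuration and seed reproduce the history
#' exactly on a single-threaded CPU backend.
#'
#' @param model An initialized `mgcna_model`.
#' @param segs A `segment_set`.
#' @param split A fold from [make_splits()]: `list(train, val, test)`.
#' @param tcfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best weights), `history` (per-epoch data.frame
#'   with losses, accuracies and the audited per-epoch class counts), and
#'   `best_epoch`.
#' @export
fit_mgcna <- function(model, segs, split, tcfg = train_config(),
                      verbose = FALSE) {
  opt <- adam_init(model$params)
  hist <- list()
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    eseed <- derive_seed(tcfg$seed, "epoch", epoch)
    idx <- balanced_epoch_subset(segs, split$train, eseed)
    n_ict <- sum(segs$labels[idx] == 1L)
    tr_loss <- 0; tr_n <- 0L; tr_correct <- 0L
    with_seed(derive_seed(tcfg$seed, "dropout", epoch), {
      for (start in seq(1L, length(idx), by = tcfg$batch_size)) {
        sel <- idx[start:min(start + tcfg$batch_size - 1L, length(idx))]
        lg <- mgcna_loss_grads(model, segs$x[, , sel, drop = FALSE],
                               segs$labels[sel], train = TRUE, dropout = TRUE,
                               loss_mode = tcfg$loss_mode)
        abort_if(!is.finite(lg$loss),
                 "training diverged (non-finite loss) at epoch ", epoch)
        grads <- lg$grads
        if (tcfg$l2_mode == "explicit")
          grads <- explicit_l2_grads(grads, model$params, tcfg$tau)
        st <- adam_step(model$params, grads, opt, tcfg$lr,
                        weight_decay = if (tcfg$l2_mode == "decoupled")
                          tcfg$weight_decay else 0)
        model$params <- st$params
        opt <- st$opt
        model$state <- lg$state
        tr_loss <- tr_loss + lg$loss * length(sel)
        tr_n <- tr_n + length(sel)
        tr_correct <- tr_correct +
          sum(as.integer(lg$probs[2L, ] > lg$probs[1L, ]) == segs$labels[sel])
      }
    })
    val <- predict_mgcna(model, segs, split$val, tcfg$batch_size)
    val_loss <- bce_loss(val$prob_ictal, segs$labels[split$val])
    val_acc <- mean(val$pred == segs$labels[split$val])
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tr_loss / tr_n,
      train_acc = tr_correct / tr_n,
      val_loss = val_loss, val_acc = val_acc,
      n_ictal = n_ict, n_interictal = length(idx) - n_ict)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f (acc %.3f)",
                      epoch, tr_loss / tr_n, val_loss, val_acc))
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = model$params,
                   state = model$state, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tcfg$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = do.call(rbind, hist), best_epoch = best$epoch)
}

#' Evaluate a model on held-out segments
#'
#' @param model A trained `mgcna_model`.
#' @param segs A `segment_set`.
#' @param idx Indices of the evaluation segments.
#' @return A `metric_report` (confusion counts, Acc/Sens/Spec/F1 and AUC from
#'   the ictal-unit probability).
#' @export
evaluate_mgcna <- function(model, segs, idx) {
  pr <- predict_mgcna(model, segs, idx)
  metric_report(segs$labels[idx], pr$pred, pr$prob_ictal)
}

#' Run a full evaluation protocol
#'
#' Orchestrates preprocessing (band-pass, segmentation, 5:1 rebalancing),
#' split construction, per-fold training and held-out evaluation, and reports
#' per-fold and mean Acc/Sens/Spec/F1/AUC.
#'
#' Patient-specific mode expects one recording (stratified 5-fold over its
#' segments); patient-independent mode expects a cohort and runs
#' leave-one-subject-out, testing each fold on the held-out patient.
#'
#' @param recordings An `eeg_recording` or list of them.
#' @param mode `"patient_specific"` or `"patient_independent"`.
#' @param model_cfg A [model_config()].
#' @param tcfg A [train_config()].
#' @param n_folds Folds for patient-specific mode. Default 5.
#' @param ratio Interictal:ictal rebalancing ratio. Default 5.
#' @param seed Master seed (fold-level seeds are derived from it).
#' @param verbose Print progress.
#' @return List with `metrics` (per-case data.frame plus a mean row),
#'   `reports`, `histories`, and `mode`.
#' @export
run_protocol <- function(recordings,
                         mode = c("patient_specific", "patient_independent"),
                         model_cfg = model_config(), tcfg = train_config(),
                         n_folds = 5L, ratio = 5, seed = tcfg$seed,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  segs <- prepare_segments(recordings, ratio = ratio, seed = seed)
  splits <- make_splits(segs, mode, n_folds = n_folds, seed = seed)
  reports <- list(); histories <- list()
  cases <- character(length(splits))
  for (f in seq_along(splits)) {
    cases[f] <- if (mode == "patient_specific") sprintf("fold%d", f)
                else attr(splits[[f]], "test_patient")
    if (verbose) message("== ", cases[f], " ==")
    fold_tcfg <- tcfg
    fold_tcfg$seed <- derive_seed(seed, "fit-fold", f)
    model <- mgcna_init(model_cfg, seed = derive_seed(seed, "model-init", f))
    fit <- fit_mgcna(model, segs, splits[[f]], fold_tcfg, verbose = verbose)
    reports[[cases[f]]] <- evaluate_mgcna(fit$model, segs, splits[[f]]$test)
    histories[[cases[f]]] <- fit$history
  }
  list(metrics = metrics_table(reports), reports = reports,
       histories = histories, mode = mode)
}

#' Configuration for an ablation variant
#'
#' Maps the named ablation variants onto branch/attention switches: `"h1"`
#' keeps only the spatial-distance branch, `"h2"` only functional
#' connectivity, `"h3"` only the adaptive graph, `"no_attention"` disables the
#' attention fusion (branch outputs concatenated directly), `"full"` is the
#' complete model.
#'
#' @param base A [model_config()].
#' @param variant One of `"full"`, `"h1"`, `"h2"`, `"h3"`, `"no_attention"`.
#' @return A `model_config`.
#' @export
ablation_config <- function(base, variant = c("full", "h1", "h2", "h3",
                                              "no_attention")) {
  variant <- match.arg(variant)
  cfg <- base
  sw <- c(distance = TRUE, connectivity = TRUE, adaptive = TRUE)
  if (variant == "h1") sw <- c(distance = TRUE, connectivity = FALSE, adaptive = FALSE)
  if (variant == "h2") sw <- c(distance = FALSE, connectivity = TRUE, adaptive = FALSE)
  if (variant == "h3") sw <- c(distance = FALSE, connectivity = FALSE, adaptive = TRUE)
  cfg$branches <- sw
  cfg$attention <- variant != "no_attention"
  cfg
}

#' Ablation experiment over model variants
#'
#' Trains each variant on the same split(s) across several seeds and collects
#' validation and test accuracy, mirroring the single-branch and no-attention
#' comparison grid.
#'
#' @param recordings Recording(s) as in [run_protocol()].
#' @param variants Character vector of [ablation_config()] variants.
#' @param model_cfg,tcfg Base configurations.
#' @param seeds Integer vector of replicate seeds.
#' @param ratio Rebalancing ratio.
#' @param verbose Print progress.
#' @return data.frame with one row per variant x seed (val/test accuracy and
#'   AUC).
#' @export
run_ablation <- function(recordings,
                         variants = c("full", "h1", "h2", "h3", "no_attention"),
                         model_cfg = model_config(), tcfg = train_config(),
                         seeds = 1:3, ratio = 5, verbose = FALSE) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  rows <- list()
  for (seed in seeds) {
    segs <- prepare_segments(recordings, ratio = ratio, seed = seed)
    split <- make_splits(segs, "patient_specific", seed = seed)[[1L]]
    for (v in variants) {
      if (verbose) message("variant ", v, " seed ", seed)
      cfg <- ablation_config(model_cfg, v)
      vt <- tcfg
      vt$seed <- derive_seed(seed, paste0("ablate-", v))
      model <- mgcna_init(cfg, seed = vt$seed)
      fit <- fit_mgcna(model, segs, split, vt)
      val <- predict_mgcna(fit$model, segs, split$val)
      rep <- evaluate_mgcna(fit$model, segs, split$test)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = seed,
        val_acc = mean(val$pred == segs$labels[split$val]),
        test_acc = rep$acc, test_auc = rep$auc)
    }
  }
  do.call(rbind, rows)
}
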