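#' @name evaluation
#' @title Experiment orchestration and accuracy reporting
#'
#' @description
#' The study design crosses three dataset variants (all five conditions on
#' full recordings; ANSB removed; ANSB removed and only the second half of
#' each recording) with three windowed feature spaces (time samples,
#' 0-16 Hz periodogram, eleven audio descriptors) and two learning modes
#' (unsupervised autoencoder plus an independent softmax probe, or a
#' supervised fine-tuned autoencoder), plus a whole-sequence study that
#' classifies one concatenated feature-track vector per subject. Reports
#' give per-class and overall accuracy in the class order
#' ANSB, flecainide, amiodarone, diltiazem, control.
NULL

CLASS_ORDER <- c("ansb", "flecainide", "amiodarone", "diltiazem", "control")

#' Confusion matrix and accuracy report
#'
#' @param predictions predicted label vector.
#' @param truth true label vector (same length).
#' @param classes ordered class labels.
#' @return a `vf_report`: list with `confusion` (rows = truth),
#'   `per_class_accuracy` (recall, percent), `overall_accuracy` (percent),
#'   `n_test_windows`.
#' @export
accuracy_table <- function(predictions, truth, classes = CLASS_ORDER) {
  if (length(predictions) != length(truth)) vf_input_error("length mismatch")
  bad <- setdiff(unique(c(predictions, truth)), classes)
  if (length(bad) > 0)
    vf_input_error("labels outside the class list: %s", paste(bad, collapse = ", "))
  cm <- table(factor(truth, classes), factor(predictions, classes))
  per_class <- 100 * diag(cm) / pmax(rowSums(cm), 1)
  structure(list(confusion = unclass(cm),
                 per_class_accuracy = stats::setNames(as.numeric(per_class), classes),
                 overall_accuracy = 100 * sum(diag(cm)) / length(truth),
                 n_test_windows = length(truth)),
            class = "vf_report")
}

#' @export
print.vf_report <- function(x, ...) {
  cat(sprintf("<vf_report> overall %.1f%% on %d windows\n",
              x$overall_accuracy, x$n_test_windows))
  print(round(x$per_class_accuracy, 1))
  invisible(x)
}

#' Describe one windowed experiment
#'
#' @param dataset_variant `"set1_all_full"`, `"set2_no_ansb"`, or
#'   `"set3_no_ansb_second_half"`.
#' @param feature_space `"time"`, `"spectral"`, or `"audio"`.
#' @param learning_mode `"unsupervised_plus_softmax"` or
#'   `"supervised_finetuned"`.
#' @param split a `vf_splitplan` (default: built per cohort with
#'   [default_split_plan()]).
#' @param seed integer seed for model initialization.
#' @param epochs,lr training configuration (defaults 200 / 3e-3).
#' @param scale,n_bands audio filterbank configuration (`"none"` uses the
#'   raw sub-50 Hz spectrum bins).
#' @return a `vf_experiment_config` list.
#' @export
experiment_config <- function(dataset_variant, feature_space, learning_mode,
                              split = NULL, seed = 0L, epochs = 200, lr = 3e-3,
                              scale = "none", n_bands = 64) {
  structure(list(
    dataset_variant = match.arg(dataset_variant,
      c("set1_all_full", "set2_no_ansb", "set3_no_ansb_second_half")),
    feature_space = match.arg(feature_space, c("time", "spectral", "audio")),
    learning_mode = match.arg(learning_mode,
      c("unsupervised_plus_softmax", "supervised_finetuned")),
    split = split, seed = seed, epochs = epochs, lr = lr,
    scale = scale, n_bands = n_bands), class = "vf_experiment_config")
}

variant_classes <- function(variant) {
  if (variant == "set1_all_full") CLASS_ORDER else setdiff(CLASS_ORDER, "ansb")
}

# Architectures: unsupervised stacks reconstruct their input; supervised
# stacks end in fully connected layers feeding the class head.
windowed_architecture <- function(feature_space, learning_mode, input_dim) {
  if (learning_mode == "unsupervised_plus_softmax")
    switch(feature_space,
           time = c(16, 3, 16, input_dim),
           spectral = c(30, 10, 3, 10, 30, input_dim),
           audio = c(8, 3, 8, input_dim))
  else
    switch(feature_space,
           time = c(16, 3, 10, 50),
           spectral = c(30, 10, 3, 10, 50),
           audio = c(8, 3, 10, 50))
}

mean_subtract <- function(recording) {
  new_vf_recording(recording$samples - mean(recording$samples), recording$fs,
                   recording$subject_id, recording$condition, recording$duration_s)
}

# Feature extraction for one list of recordings; normalization statistics
# are fitted on the training list only and reused verbatim on test.
windowed_features <- function(train_recs, test_recs, config) {
  fspace <- config$feature_space
  if (fspace == "time") {
    dec_tr <- lapply(train_recs, decimate_by_ten)
    dec_te <- lapply(test_recs, decimate_by_ten)
    s <- max(abs(unlist(lapply(dec_tr, `[[`, "samples"))))
    if (s == 0) vf_degenerate_error("all-zero training signals")
    scale_rec <- function(r) new_vf_recording(r$samples / s, r$fs, r$subject_id,
                                              r$condition, r$duration_s)
    wtr <- bind_windowsets(lapply(dec_tr, function(r) window_signal(scale_rec(r), 204, 102)))
    wte <- bind_windowsets(lapply(dec_te, function(r) window_signal(scale_rec(r), 204, 102)))
    Xtr <- wtr$windows; Xte <- wte$windows
    attr(Xtr, "labels") <- wtr$labels; attr(Xte, "labels") <- wte$labels
    attr(Xtr, "subject_ids") <- wtr$subject_ids
    attr(Xte, "subject_ids") <- wte$subject_ids
    return(list(train = Xtr, test = Xte))
  }
  win <- function(recs) bind_windowsets(lapply(recs, function(r)
    window_signal(mean_subtract(r), 2048, 1024)))
  wtr <- win(train_recs); wte <- win(test_recs)
  if (fspace == "spectral") {
    Xtr <- spectral_feature_matrix(wtr); Xte <- spectral_feature_matrix(wte)
    s <- max(abs(Xtr))
    out_tr <- Xtr / s; out_te <- Xte / s
    for (a in c("subject_ids", "labels")) {
      attr(out_tr, a) <- attr(Xtr, a); attr(out_te, a) <- attr(Xte, a)
    }
    return(list(train = out_tr, test = out_te))
  }
  Xtr <- audio_feature_matrix(wtr, scale = config$scale, n_bands = config$n_bands)
  Xte <- audio_feature_matrix(wte, scale = config$scale, n_bands = config$n_bands)
  ztr <- zscore_normalize(Xtr)
  zte <- zscore_normalize(Xte, stats = attr(ztr, "stats"))
  list(train = ztr, test = zte)
}

#' Run one windowed classification experiment end to end
#'
#' Applies the variant's subject filtering and halving, restores clipping,
#' extracts the configured feature space (all normalization statistics
#' fitted on training subjects only), trains the configured learner, and
#' scores the held-out subjects per window.
#'
#' @param cohort list of `vf_recording` objects.
#' @param config a `vf_experiment_config`.
#' @return a `vf_report` with the config attached as `$config`.
#' @export
run_windowed_experiment <- function(cohort, config) {
  classes <- variant_classes(config$dataset_variant)
  recs <- Filter(function(r) r$condition %in% classes, cohort)
  recs <- lapply(recs, restore_clipping)
  if (config$dataset_variant == "set3_no_ansb_second_half")
    recs <- lapply(recs, take_second_half)
  plan <- if (is.null(config$split)) default_split_plan(recs) else config$split
  sp <- subject_split(recs, plan)
  feats <- windowed_features(sp$train, sp$test, config)
  Xtr <- unclass(feats$train); Xte <- unclass(feats$test)
  ytr <- attr(feats$train, "labels"); yte <- attr(feats$test, "labels")
  arch <- windowed_architecture(config$feature_space, config$learning_mode, ncol(Xtr))
  if (config$learning_mode == "unsupervised_plus_softmax") {
    spec <- ae_spec(arch, ncol(Xtr), seed = config$seed)
    model <- train_autoencoder(init_autoencoder(spec), Xtr,
                               epochs = config$epochs, lr = config$lr)
    head <- train_softmax_head(encode(model, Xtr), ytr, classes)
    pred <- predict_labels(head, encode(model, Xte))
  } else {
    spec <- ae_spec(arch, ncol(Xtr), seed = config$seed)
    model <- fine_tune_supervised(spec, Xtr, ytr, classes,
                                  epochs_pre = config$epochs,
                                  epochs_ft = config$epochs, lr = config$lr)
    pred <- predict_labels(model, Xte)
  }
  rep <- accuracy_table(pred, yte, classes)
  rep$config <- config
  rep$model <- model
  rep
}

#' Run the whole-sequence feature-track experiment
#'
#' Per subject, the eleven audio feature tracks are computed over the full
#' recording, z-scored per feature with training statistics, and the JMI
#' selection (features as units, training windows pooled as samples) keeps
#' `k` tracks; the concatenated per-subject vectors feed single-latent-layer
#' autoencoders whose width is swept over `latent_sweep`. Every subject is
#' one example, so reports score one prediction per held-out subject.
#'
#' @param cohort list of `vf_recording` objects.
#' @param scale,n_bands filterbank configuration (default ERB / 256).
#' @param latent_sweep latent widths to try (default `seq(5, 175, by = 5)`).
#' @param split a `vf_splitplan` (default [default_split_plan()]).
#' @param k number of tracks to keep (default 5).
#' @param seed,epochs,lr training configuration.
#' @param window_length,hop track windowing (defaults 1000 / 200).
#' @return list with `selection` (the `vf_selection`), `input_dim_full`,
#'   `input_dim_selected`, `sweep` (data.frame: width, unsupervised and
#'   supervised overall accuracy), `best` (row of `sweep` with the best
#'   supervised accuracy), `reports` (per width).
#' @export
run_whole_sequence_experiment <- function(cohort, scale = "erb", n_bands = 256,
                                          latent_sweep = seq(5, 175, by = 5),
                                          split = NULL, k = 5, seed = 0L,
                                          epochs = 100, lr = 3e-3,
                                          window_length = 1000, hop = 200) {
  plan <- if (is.null(split)) default_split_plan(cohort) else split
  tracks <- lapply(cohort, whole_sequence_tracks, scale = scale,
                   n_bands = n_bands, window_length = window_length, hop = hop)
  ids <- vapply(tracks, `[[`, "", "subject_id")
  labels <- vapply(tracks, `[[`, "", "label")
  names(tracks) <- ids
  is_train <- ids %in% plan$train_subjects
  n_feat <- length(AUDIO_FEATURE_NAMES)

  # JMI over pooled training windows: rows = windows, columns = features
  pool <- do.call(rbind, lapply(tracks[is_train], function(tr) t(tr$tracks)))
  colnames(pool) <- AUDIO_FEATURE_NAMES
  pool_labels <- rep(labels[is_train],
                     each = ncol(tracks[[1]]$tracks))
  sel <- jmi_select(pool, pool_labels, k = k)

  # per-feature z-scoring with training statistics, then concatenation
  mu <- colMeans(pool); sd <- apply(pool, 2, stats::sd)
  sd[sd == 0] <- 1
  concat_z <- function(tr, features) {
    z <- (tr$tracks - mu) / sd
    as.numeric(t(z[features, , drop = FALSE]))
  }
  X_full <- do.call(rbind, lapply(tracks, concat_z, features = seq_len(n_feat)))
  X_sel <- do.call(rbind, lapply(tracks, concat_z, features = sel$selected_ids))
  classes <- sort(unique(labels))
  Xtr <- X_sel[is_train, , drop = FALSE]; Xte <- X_sel[!is_train, , drop = FALSE]
  ytr <- labels[is_train]; yte <- labels[!is_train]

  sweep_rows <- list(); reports <- list()
  for (w in latent_sweep) {
    spec_u <- ae_spec(c(w, ncol(Xtr)), ncol(Xtr), latent_index = 1,
                      seed = derive_seed(seed, paste0("ws-unsup-", w)))
    ae <- train_autoencoder(init_autoencoder(spec_u), Xtr, epochs = epochs, lr = lr)
    head <- train_softmax_head(encode(ae, Xtr), ytr, classes)
    rep_u <- accuracy_table(predict_labels(head, encode(ae, Xte)), yte, classes)
    spec_s <- ae_spec(w, ncol(Xtr), latent_index = 1,
                      seed = derive_seed(seed, paste0("ws-sup-", w)))
    sup <- fine_tune_supervised(spec_s, Xtr, ytr, classes,
                                epochs_pre = epochs, epochs_ft = epochs, lr = lr)
    rep_s <- accuracy_table(predict_labels(sup, Xte), yte, classes)
    sweep_rows[[length(sweep_rows) + 1]] <-
      data.frame(latent_width = w,
                 unsupervised_accuracy = rep_u$overall_accuracy,
                 supervised_accuracy = rep_s$overall_accuracy)
    reports[[as.character(w)]] <- list(unsupervised = rep_u, supervised = rep_s)
  }
  sweep_df <- do.call(rbind, sweep_rows)
  list(selection = sel,
       input_dim_full = ncol(X_full),
       input_dim_selected = ncol(X_sel),
       sweep = sweep_df,
       best = sweep_df[which.max(sweep_df$supervised_accuracy), ],
       reports = reports)
}

#' Export a latent embedding to CSV
#'
#' @param embedding a `vf_embedding` (3-D codes for the plotting layout).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_latent <- function(embedding, path) {
  d <- ncol(embedding$codes)
  df <- as.data.frame(embedding$codes)
  names(df) <- paste0("code", seq_len(d))
  df$label <- if (is.null(embedding$labels)) NA else embedding$labels
  df$subject_id <- if (is.null(embedding$subject_ids)) NA else embedding$subject_ids
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
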