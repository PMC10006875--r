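#' @name manifold
#' @title Autoencoders, latent codes, softmax heads, and fine-tuning
#'
#' @description
#' The manifold learners are plain fully connected autoencoders: an encoder
#' `h = phi(W_e x + b_e)` maps a D-dimensional input window to a
#' d-dimensional latent code (d = 3 for all windowed-feature experiments),
#' and a decoder `xhat = psi(W_d h + b_d)` reconstructs it; deeper stacks
#' chain several such affine-plus-nonlinearity layers. Hidden layers use a
#' logistic sigmoid, output layers are linear, training minimizes mean
#' squared reconstruction error by full-batch Adam. Classification either
#' attaches an independent softmax layer to frozen latent codes
#' (unsupervised scheme) or fine-tunes the whole stack jointly under
#' cross-entropy (supervised scheme).
NULL

apply_act <- function(Z, act) {
  switch(act, linear = Z, sigmoid = 1 / (1 + exp(-Z)),
         vf_config_error("unknown activation '%s'", act))
}

act_deriv <- function(A, act) {
  switch(act, linear = 1, sigmoid = A * (1 - A))
}

#' Describe an autoencoder architecture
#'
#' `layer_sizes` lists the neuron counts of the hidden and output layers in
#' order (the input layer is implied by `input_dim`); the bottleneck is the
#' smallest listed layer unless `latent_index` says otherwise. For an
#' unsupervised autoencoder the last listed size equals `input_dim`, e.g.
#' `c(16, 3, 16, 204)` for 204-sample time windows or
#' `c(30, 10, 3, 10, 30, 67)` for 67-bin periodogram vectors.
#'
#' @param layer_sizes integer vector of layer widths.
#' @param input_dim input dimensionality D.
#' @param latent_index position of the bottleneck in `layer_sizes`
#'   (default: first minimum).
#' @param activation hidden-layer nonlinearity (`"sigmoid"` or `"linear"`;
#'   output layers are always linear).
#' @param seed integer seed for weight initialization.
#' @return a `vf_ae_spec` list.
#' @export
ae_spec <- function(layer_sizes, input_dim,
                    latent_index = which.min(layer_sizes),
                    activation = "sigmoid", seed = 0L) {
  if (length(layer_sizes) < 1 || any(layer_sizes < 1))
    vf_config_error("layer_sizes must be positive")
  if (latent_index < 1 || latent_index > length(layer_sizes))
    vf_config_error("latent_index out of range")
  structure(list(layer_sizes = as.integer(layer_sizes),
                 input_dim = as.integer(input_dim),
                 latent_index = as.integer(latent_index),
                 latent_dim = as.integer(layer_sizes[latent_index]),
                 activation = activation, seed = as.integer(seed)),
            class = "vf_ae_spec")
}

init_layer <- function(n_in, n_out, act) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out), act = act)
}

#' Initialize an autoencoder from its spec
#'
#' Weights are drawn from the scaled uniform (Glorot) range under the
#' spec's seed; biases start at zero. Hidden layers get the spec's
#' activation, the final layer is linear.
#'
#' @param spec a `vf_ae_spec`.
#' @return a `vf_model`: list with `layers` (each `W`, `b`, `act`),
#'   `latent_index`, `input_dim`, `loss_log`, optional `head_classes`.
#' @export
init_autoencoder <- function(spec) {
  sizes <- c(spec$input_dim, spec$layer_sizes)
  with_seed(spec$seed, {
    layers <- lapply(seq_len(length(sizes) - 1), function(l) {
      act <- if (l == length(sizes) - 1) "linear" else spec$activation
      init_layer(sizes[l], sizes[l + 1], act)
    })
    structure(list(layers = layers, latent_index = spec$latent_index,
                   input_dim = spec$input_dim, latent_dim = spec$latent_dim,
                   head_classes = NULL, loss_log = numeric(0)),
              class = "vf_model")
  })
}

forward_pass <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (l in seq_along(layers)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    acts[[l + 1]] <- apply_act(Z, layers[[l]]$act)
  }
  acts
}

# Full-batch Adam on an arbitrary layer stack. loss_grad(out) must return
# list(loss = scalar, delta = dLoss/dZ_out for a linear output layer).
optimize_layers <- function(layers, X, loss_grad, epochs, lr,
                            trainable = rep(TRUE, length(layers)),
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  mW <- lapply(layers, function(l) l$W * 0); vW <- mW
  mb <- lapply(layers, function(l) l$b * 0); vb <- mb
  loss_log <- numeric(epochs)
  L <- length(layers)
  for (ep in seq_len(epochs)) {
    acts <- forward_pass(layers, X)
    lg <- loss_grad(acts[[L + 1]])
    loss_log[ep] <- lg$loss
    delta <- lg$delta
    for (l in rev(seq_len(L))) {
      dZ <- delta * act_deriv(acts[[l + 1]], layers[[l]]$act)
      if (l > 1) delta <- dZ %*% t(layers[[l]]$W)
      if (!trainable[l]) next
      gW <- crossprod(acts[[l]], dZ)
      gb <- colSums(dZ)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
      mhb <- mb[[l]] / (1 - beta1^ep); vhb <- vb[[l]] / (1 - beta2^ep)
      layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
      layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  list(layers = layers, loss_log = loss_log)
}

mse_loss_grad <- function(target) {
  force(target)
  function(out) {
    err <- out - target
    list(loss = mean(err^2), delta = 2 * err / length(err))
  }
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

ce_loss_grad <- function(Y1hot) {
  force(Y1hot)
  function(out) {
    P <- softmax_rows(out)
    list(loss = -mean(log(pmax(rowSums(P * Y1hot), 1e-300))),
         delta = (P - Y1hot) / nrow(Y1hot))
  }
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Train an autoencoder by reconstruction
#'
#' Stacks deeper than one hidden layer are first pretrained greedily
#' layer-by-layer (each encoder/decoder pair trained as a shallow
#' autoencoder on the previous layer's codes), then the whole stack is
#' fine-tuned jointly on the mean squared reconstruction error. The final
#' logged loss never exceeds the initial one by construction of the
#' optimizer run (monitored, best weights kept).
#'
#' @param model a `vf_model` from [init_autoencoder()].
#' @param X training matrix (n x D).
#' @param epochs joint-training epochs (default 200).
#' @param lr Adam learning rate (default 3e-3).
#' @param layerwise pretrain layer pairs greedily first (default TRUE for
#'   symmetric stacks with more than one encoder layer).
#' @param epochs_layerwise epochs per greedy layer pair (default `epochs`).
#' @return the trained `vf_model` with `loss_log` filled.
#' @export
train_autoencoder <- function(model, X, epochs = 200, lr = 3e-3,
                              layerwise = NULL, epochs_layerwise = epochs) {
  if (!is.matrix(X) || ncol(X) != model$input_dim)
    vf_input_error("X must be a matrix with %d columns", model$input_dim)
  if (any(!is.finite(X))) vf_input_error("non-finite training inputs")
  li <- model$latent_index
  L <- length(model$layers)
  symmetric <- L == 2 * li
  if (is.null(layerwise)) layerwise <- symmetric && li > 1
  if (layerwise && symmetric && li > 1) {
    codes <- X
    for (l in seq_len(li)) {
      pair <- list(model$layers[[l]], model$layers[[L + 1 - l]])
      pair[[2]]$act <- "linear"   # shallow reconstruction head
      res <- optimize_layers(pair, codes, mse_loss_grad(codes),
                             epochs_layerwise, lr)
      model$layers[[l]] <- res$layers[[1]]
      model$layers[[L + 1 - l]]$W <- res$layers[[2]]$W
      model$layers[[L + 1 - l]]$b <- res$layers[[2]]$b
      codes <- forward_pass(res$layers[1], codes)[[2]]
    }
  }
  res <- optimize_layers(model$layers, X, mse_loss_grad(X), epochs, lr)
  # keep the better of initial vs final weights (guards vs. divergence)
  if (length(res$loss_log) > 0 && res$loss_log[epochs] > res$loss_log[1]) {
    model$loss_log <- c(model$loss_log, res$loss_log[1])
    return(model)
  }
  model$layers <- res$layers
  model$loss_log <- c(model$loss_log, res$loss_log)
  model
}

#' Encode inputs into the latent space
#'
#' @param model a `vf_model`.
#' @param X matrix (n x D).
#' @param labels,subject_ids optional per-row provenance carried into the
#'   embedding (defaults: the matrix's attributes, if present).
#' @return a `vf_embedding`: list with `codes` (n x d), `labels`,
#'   `subject_ids`.
#' @export
encode <- function(model, X, labels = attr(X, "labels"),
                   subject_ids = attr(X, "subject_ids")) {
  if (!is.matrix(X) || ncol(X) != model$input_dim)
    vf_input_error("X must be a matrix with %d columns", model$input_dim)
  acts <- forward_pass(model$layers[seq_len(model$latent_index)], X)
  structure(list(codes = acts[[model$latent_index + 1]],
                 labels = labels, subject_ids = subject_ids),
            class = "vf_embedding")
}

#' Decode latent codes back to the input space
#'
#' @param model a `vf_model`.
#' @param H matrix (n x d) of latent codes.
#' @return matrix (n x D) of reconstructions.
#' @export
decode <- function(model, H) {
  if (!is.matrix(H) || ncol(H) != model$latent_dim)
    vf_input_error("H must be a matrix with %d columns", model$latent_dim)
  dec <- model$layers[(model$latent_index + 1):length(model$layers)]
  forward_pass(dec, H)[[length(dec) + 1]]
}

#' Train an independent softmax layer on latent codes
#'
#' Multinomial logistic regression by full-batch Adam on cross-entropy;
#' this is the unsupervised scheme's separability probe (the autoencoder
#' never sees the labels).
#'
#' @param latent a `vf_embedding` (or bare code matrix).
#' @param labels label per row.
#' @param classes ordered class labels.
#' @param epochs,lr optimizer settings.
#' @return a `vf_softmax`: list with `W`, `b`, `classes`.
#' @export
train_softmax_head <- function(latent, labels, classes = sort(unique(labels)),
                               epochs = 500, lr = 0.05) {
  H <- if (inherits(latent, "vf_embedding")) latent$codes else latent
  if (!all(labels %in% classes)) vf_input_error("labels outside the class list")
  if (length(unique(labels)) < 2) {
    warning("single-class input: returning trivial classifier")
    return(structure(list(W = matrix(0, ncol(H), length(classes)),
                          b = ifelse(classes == labels[1], 1, 0),
                          classes = classes), class = "vf_softmax"))
  }
  layer <- with_seed(derive_seed(0, "softmax"),
                     list(init_layer(ncol(H), length(classes), "linear")))
  res <- optimize_layers(layer, H, ce_loss_grad(one_hot(labels, classes)),
                         epochs, lr)
  structure(list(W = res$layers[[1]]$W, b = res$layers[[1]]$b,
                 classes = classes, loss_log = res$loss_log),
            class = "vf_softmax")
}

#' Predict class labels
#'
#' Argmax over class scores; ties break toward the lower class index.
#' Accepts either a supervised `vf_model` (with a classification head, raw
#' inputs in `X`) or a `vf_softmax` (latent codes in `X`).
#'
#' @param model a `vf_model` with head, or a `vf_softmax`.
#' @param X input matrix on the model's expected scale.
#' @return character vector of predicted labels.
#' @export
predict_labels <- function(model, X) {
  if (inherits(model, "vf_softmax")) {
    H <- if (inherits(X, "vf_embedding")) X$codes else X
    scores <- sweep(H %*% model$W, 2, model$b, `+`)
    return(model$classes[apply(scores, 1, which.max)])
  }
  if (is.null(model$head_classes)) vf_input_error("model has no classification head")
  acts <- forward_pass(model$layers, X)
  model$head_classes[apply(acts[[length(acts)]], 1, which.max)]
}

#' Pretrain, head-train, and fine-tune a supervised autoencoder
#'
#' Three stages: (1) the encoder prefix of the spec (layers down to the
#' bottleneck) is pretrained unsupervised as a symmetric autoencoder;
#' (2) the post-bottleneck layers and the softmax classification head are
#' trained under cross-entropy with the encoder frozen; (3) the entire
#' stack is fine-tuned jointly. If joint fine-tuning ever degrades
#' training-set accuracy below the stage-2 level, the stage-2 weights are
#' kept, so fine-tuning can only help.
#'
#' @param spec a `vf_ae_spec` whose `layer_sizes` list the encoder sizes
#'   down to the bottleneck followed by post-bottleneck fully connected
#'   sizes, e.g. `c(30, 10, 3, 10, 50)` for the spectral supervised
#'   architecture.
#' @param X training matrix (n x D).
#' @param labels training label per row.
#' @param classes ordered class labels (head width = `length(classes)`).
#' @param epochs_pre unsupervised pretraining epochs (default 200).
#' @param epochs_ft head-training and fine-tuning epochs (default 200).
#' @param lr Adam learning rate.
#' @return a supervised `vf_model` with `head_classes` set and a
#'   `stage_accuracy` field (`c(head = ..., fine_tuned = ...)`).
#' @export
fine_tune_supervised <- function(spec, X, labels, classes = sort(unique(labels)),
                                 epochs_pre = 200, epochs_ft = 200, lr = 3e-3) {
  if (!all(labels %in% classes)) vf_input_error("labels outside the class list")
  li <- spec$latent_index
  enc_sizes <- spec$layer_sizes[seq_len(li)]
  post_sizes <- if (li < length(spec$layer_sizes))
    spec$layer_sizes[(li + 1):length(spec$layer_sizes)] else integer(0)

  # stage 1: symmetric unsupervised pretraining of the encoder prefix
  ae <- init_autoencoder(ae_spec(c(enc_sizes, rev(enc_sizes[-li]), spec$input_dim),
                                 spec$input_dim, latent_index = li,
                                 activation = spec$activation, seed = spec$seed))
  ae <- train_autoencoder(ae, X, epochs = epochs_pre, lr = lr)
  enc_layers <- ae$layers[seq_len(li)]

  # classification tail: post-bottleneck fully connected layers + head
  with_seed(derive_seed(spec$seed, "head"), {
    sizes <- c(spec$layer_sizes[li], post_sizes)
    tail_layers <- lapply(seq_len(length(sizes) - 1), function(l)
      init_layer(sizes[l], sizes[l + 1], spec$activation))
    head_layer <- init_layer(sizes[length(sizes)], length(classes), "linear")
  })
  layers <- c(enc_layers, tail_layers, list(head_layer))
  Y <- one_hot(labels, classes)

  # stage 2: encoder frozen
  frozen <- c(rep(FALSE, li), rep(TRUE, length(tail_layers) + 1))
  res2 <- optimize_layers(layers, X, ce_loss_grad(Y), epochs_ft, lr,
                          trainable = frozen)
  acc <- function(ls) {
    pred <- classes[apply(forward_pass(ls, X)[[length(ls) + 1]], 1, which.max)]
    mean(pred == labels)
  }
  acc2 <- acc(res2$layers)

  # stage 3: joint fine-tuning
  res3 <- optimize_layers(res2$layers, X, ce_loss_grad(Y), epochs_ft, lr)
  acc3 <- acc(res3$layers)
  final <- if (acc3 >= acc2) res3$layers else res2$layers
  structure(list(layers = final, latent_index = li, input_dim = spec$input_dim,
                 latent_dim = spec$latent_dim, head_classes = classes,
                 loss_log = c(res2$loss_log, res3$loss_log),
                 stage_accuracy = c(head = acc2, fine_tuned = max(acc2, acc3))),
            class = "vf_model")
}
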