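# Greedy layer-wise autoencoder pretraining and supervised fine-tuning.

# the output layer's Gaussian is a per-unit transfer function on the
# affine net input (unit j scores 1 when its net input is 0)
output_act <- function(config) {
  if (config$output_activation == "gaussian") "gaussian_unit" else "linear"
}

# mini-batch gradient-descent epochs with a per-batch step-halving descent
# safeguard; with track = TRUE the best-so-far epoch checkpoint is kept and
# convergence/settling against cfg$convergence is reported
sgd_epochs <- function(net, x, target, cfg, epochs, batch_size, track = FALSE) {
  n <- nrow(x)
  trace <- numeric(0)
  converged <- FALSE
  settled <- FALSE
  prev <- Inf
  epochs_run <- 0L
  best <- list(net = net, mse = epoch_mse(net, x, target))
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (s in seq(1, n, by = batch_size)) {
      rows <- idx[s:min(s + batch_size - 1, n)]
      xb <- x[rows, , drop = FALSE]
      tb <- target[rows, , drop = FALSE]
      bp <- backprop_gradients(net, xb, tb)
      # halve the step while it would increase the batch loss (the nominal
      # rate is kept for well-scaled batches)
      alpha <- cfg$learning_rate
      for (try in 1:8) {
        cand <- update_weights(net, bp$grads, alpha)
        if (epoch_mse(cand, xb, tb) <= bp$loss) { net <- cand; break }
        alpha <- alpha / 2
      }
    }
    cur <- epoch_mse(net, x, target)
    epochs_run <- ep
    trace[ep] <- cur
    if (cur < best$mse) best <- list(net = net, mse = cur)
    if (cur <= cfg$convergence) { converged <- TRUE; break }
    if (abs(prev - cur) < cfg$convergence) { settled <- TRUE; break }
    prev <- cur
  }
  if (track && best$mse < (if (epochs_run) trace[epochs_run] else Inf)) {
    net <- best$net
  }
  list(net = net, trace = trace, converged = converged, settled = settled,
       epochs_run = epochs_run)
}

# Train one layer as the encoder of a single-hidden-layer autoencoder with a
# linear decoder, by mini-batch gradient descent on the mean squared
# reconstruction loss. The best-so-far parameters (full-data loss) are kept,
# so the returned layer's final loss never exceeds its initial loss.
pretrain_layer <- function(layer, h, epochs, lr, batch_size) {
  n <- nrow(h)
  m <- ncol(h)
  k <- length(layer$b)
  batch_size <- min(batch_size, n)
  # start the linear decoder at its least-squares optimum given the initial
  # encoder (the classical RBF pseudo-inverse solution); gradient descent
  # then refines encoder and decoder jointly
  a0 <- layer_activation(layer, h %*% layer$W +
                           matrix(layer$b, n, k, byrow = TRUE))
  design <- cbind(a0, 1)
  gram <- crossprod(design) + diag(1e-8, k + 1)
  coefs <- solve(gram, crossprod(design, h))
  D <- coefs[seq_len(k), , drop = FALSE]
  cbias <- as.numeric(coefs[k + 1, ])

  encode <- function() {
    z <- h %*% layer$W + matrix(layer$b, n, k, byrow = TRUE)
    list(z = z, a = layer_activation(layer, z))
  }
  recon_loss <- function() {
    e <- encode()
    xhat <- e$a %*% D + matrix(cbias, n, m, byrow = TRUE)
    mean(rowSums((h - xhat)^2))
  }

  batch_loss <- function(layer, D, cbias, hb) {
    z <- hb %*% layer$W + matrix(layer$b, nrow(hb), k, byrow = TRUE)
    a <- layer_activation(layer, z)
    xhat <- a %*% D + matrix(cbias, nrow(hb), m, byrow = TRUE)
    mean(rowSums((hb - xhat)^2))
  }

  init <- list(W = layer$W, b = layer$b)
  trace <- numeric(0)
  best <- list(W = layer$W, b = layer$b, loss = recon_loss())
  trace[1] <- best$loss
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      rows <- idx[s:min(s + batch_size - 1, n)]
      hb <- h[rows, , drop = FALSE]
      nb <- length(rows)
      z <- hb %*% layer$W + matrix(layer$b, nb, k, byrow = TRUE)
      a <- layer_activation(layer, z)
      xhat <- a %*% D + matrix(cbias, nb, m, byrow = TRUE)
      loss0 <- mean(rowSums((hb - xhat)^2))
      r <- 2 * (xhat - hb) / nb            # d(mean recon loss)/d xhat
      if (any(!is.finite(r))) tn_stop("training_error", "divergent reconstruction loss")
      gD <- crossprod(a, r)
      gc_ <- colSums(r)
      da <- r %*% t(D)
      dz <- layer_grad_z(layer, z, a, da)
      gW <- crossprod(hb, dz)
      gb <- colSums(dz)
      # descent safeguard: halve the step while the batch loss would grow
      alpha <- lr
      for (try in 1:8) {
        cand_layer <- layer
        cand_D <- D - alpha * gD
        cand_c <- cbias - alpha * gc_
        if (!isFALSE(layer$train_map)) {
          cand_layer$W <- layer$W - alpha * gW
          cand_layer$b <- layer$b - alpha * gb
        }
        if (batch_loss(cand_layer, cand_D, cand_c, hb) <= loss0) {
          layer <- cand_layer; D <- cand_D; cbias <- cand_c
          break
        }
        alpha <- alpha / 2
      }
    }
    cur <- recon_loss()
    if (!is.finite(cur)) tn_stop("training_error", "divergent reconstruction loss")
    trace[ep + 1] <- cur
    if (cur < best$loss) best <- list(W = layer$W, b = layer$b, loss = cur)
  }
  layer$W <- best$W
  layer$b <- best$b
  # a pretrained encoder that collapses every input to one point carries no
  # information forward; fall back to the initialization in that case
  # (unless the inputs themselves were constant)
  enc <- layer_activation(layer, h %*% layer$W +
                            matrix(layer$b, n, k, byrow = TRUE))
  input_spread <- max(apply(h, 2, stats::sd))
  if (max(apply(enc, 2, stats::sd)) < 1e-8 && input_spread > 1e-8) {
    layer$W <- init$W
    layer$b <- init$b
    best$loss <- trace[1]
  }
  list(layer = layer, trace = trace, best_loss = best$loss)
}

#' Greedy layer-wise autoencoder pretraining
#'
#' Pretrains each hidden layer of an initialized network in order: the
#' layer is trained as the encoder of a single-hidden-layer autoencoder
#' (linear decoder, mean squared reconstruction loss) on the previous
#' layer's encoded outputs, then frozen, and its encodings propagate to the
#' next layer. The parameters kept for each layer are its best-so-far
#' checkpoint, so every layer's final reconstruction loss is at most its
#' initial loss.
#'
#' @param net An initialized `deep_rbfnn` (see [init_deep_rbfnn()]).
#' @param x Training inputs, matrix with `input_dim` columns.
#' @param epochs Pretraining epochs per layer (default: the config's
#'   `pretrain_epochs`).
#' @return The network with pretrained hidden layers; per-layer loss
#'   traces are stored in `$pretrain` (a list of numeric vectors, the
#'   first entry of each being the initial loss).
#' @export
pretrain_autoencoder <- function(net, x, epochs = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0) tn_stop("argument_error", "pretraining data is empty")
  cfg <- net$config
  epochs <- epochs %||% cfg$pretrain_epochs
  h <- x
  n_hidden <- length(cfg$hidden_layers)
  traces <- vector("list", n_hidden)
  for (l in seq_len(n_hidden)) {
    res <- pretrain_layer(net$layers[[l]], h, epochs, cfg$learning_rate,
                          cfg$batch_size)
    net$layers[[l]] <- res$layer
    traces[[l]] <- res$trace
    z <- h %*% res$layer$W + matrix(res$layer$b, nrow(h),
                                    length(res$layer$b), byrow = TRUE)
    h <- layer_activation(res$layer, z)
  }
  net$pretrain <- traces
  net
}

#' Initialize an unfitted deep RBF network
#'
#' Builds the layer stack for the given data: per layer, k-means centers on
#' that layer's input encodings (all upfront under `"single-shot"` scope),
#' widths by the configured rule, seeded uniform weights in
#' `[-1/sqrt(fan-in), 1/sqrt(fan-in)]` and zero biases. All layers are
#' built from the initial (un-pretrained) forward pass; [deep_rbfnn()]
#' instead interleaves construction with pretraining under the default
#' `"per-layer"` k-means scope.
#'
#' @param config An [rbf_config()].
#' @param x Training inputs (matrix, `input_dim` columns).
#' @return An unfitted `deep_rbfnn` object with all layers built from the
#'   initial (un-pretrained) forward pass.
#' @export
init_deep_rbfnn <- function(config, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  withr::with_seed(config$seed, {
    layers <- build_layers_eager(config, x)
  })
  structure(list(config = config, layers = layers,
                 classes = c("non_DM", "DM"), fitted = FALSE,
                 pretrain = NULL, report = NULL),
            class = "deep_rbfnn")
}

# build every layer from encodings under the current (initial) weights
build_layers_eager <- function(config, x) {
  sizes <- c(config$hidden_layers, config$output_dim)
  layers <- vector("list", length(sizes))
  h <- x
  for (l in seq_along(sizes)) {
    act <- if (l == length(sizes)) output_act(config) else "gaussian"
    map <- if (l == length(sizes)) "trained" else config$input_map
    layers[[l]] <- new_layer(h, sizes[l], config$width_rule, act, map)
    z <- h %*% layers[[l]]$W + matrix(layers[[l]]$b, nrow(h), sizes[l], byrow = TRUE)
    h <- layer_activation(layers[[l]], z)
  }
  layers
}

#' Fit a deep RBF network classifier
#'
#' The full training pipeline: (1) per-layer k-means center placement,
#' (2) width assignment by the configured rule, (3) greedy layer-wise
#' autoencoder pretraining, and (4) supervised fine-tuning by mini-batch
#' gradient descent on the one-hot squared-error loss, with gradients
#' averaged within each batch and the data reshuffled every epoch. Under
#' the default `"per-layer"` k-means scope each hidden layer's centers are
#' computed on its *pretrained* input encodings, interleaving steps (1)-(3)
#' layer by layer. Training stops when the epoch MSE reaches the
#' convergence criterion (`converged`), when the epoch-over-epoch
#' improvement falls below it (`settled`), or at `max_epochs`.
#'
#' The whole procedure is deterministic given `(config, x, y, config$seed)`.
#'
#' @param x Numeric input matrix (rows = samples, `input_dim` columns),
#'   e.g. from [encode_records()].
#' @param y Class labels: a factor or character vector with exactly two
#'   distinct values. The *first* factor level is treated as the negative
#'   class (`non_DM` before `DM` for schema labels); prediction ties break
#'   toward it.
#' @param config An [rbf_config()].
#' @return A fitted `deep_rbfnn` object; `$report` holds `epochs_run`,
#'   `final_train_mse`, `converged`, `settled` and the per-epoch `mse`
#'   trace.
#' @seealso [predict.deep_rbfnn()], [save_model()]
#' @export
deep_rbfnn <- function(x, y, config = rbf_config()) {
  if (is.null(dim(x))) x <- matrix(x, ncol = config$input_dim)
  if (!is.factor(y)) {
    lev <- unique(as.character(y))
    lev <- if (setequal(lev, c("non_DM", "DM"))) c("non_DM", "DM") else sort(lev)
    y <- factor(as.character(y), levels = lev)
  }
  if (nlevels(y) != 2 || length(unique(as.character(y))) < 2) {
    tn_stop("fit_error", "training labels must contain exactly 2 classes")
  }
  if (length(y) != nrow(x)) tn_stop("contract_error", "x and y lengths differ")
  if (anyNA(y)) tn_stop("fit_error", "missing labels in training data")
  cfg <- config
  n <- nrow(x)
  batch_size <- min(cfg$batch_size, n)
  target <- matrix(0, n, 2)
  target[cbind(seq_len(n), as.integer(y))] <- 1

  # loss of the best constant predictor (the collapse attractor of a deep
  # Gaussian stack); an attempt that cannot beat it triggers a seeded
  # restart
  const_out <- colMeans(target)
  baseline <- mean(rowSums(sweep(target, 2, const_out)^2)) / 2

  best_attempt <- NULL
  for (attempt in 0:3) {
    attempt_seed <- if (attempt == 0) cfg$seed else derive_seed(cfg$seed, attempt)
    fitted <- fit_once(cfg, x, y, target, batch_size, attempt_seed)
    if (is.null(best_attempt) ||
        fitted$report$final_train_mse < best_attempt$report$final_train_mse) {
      best_attempt <- fitted
    }
    if (best_attempt$report$final_train_mse < baseline - 1e-6) break
  }
  net <- best_attempt$net
  net$fitted <- TRUE
  net$report <- c(best_attempt$report, list(restarts = attempt))
  net
}

fit_once <- function(cfg, x, y, target, batch_size, seed) {
  n <- nrow(x)
  withr::with_seed(seed, {
    # interleaved per-layer init + pretraining (or eager init, single-shot)
    if (cfg$kmeans_scope == "single-shot") {
      layers <- build_layers_eager(cfg, x)
      net <- structure(list(config = cfg, layers = layers,
                            classes = levels(y), fitted = FALSE),
                       class = "deep_rbfnn")
      net <- pretrain_autoencoder(net, x)
    } else {
      h <- x
      layers <- list()
      traces <- list()
      for (l in seq_along(cfg$hidden_layers)) {
        layer <- new_layer(h, cfg$hidden_layers[l], cfg$width_rule, "gaussian",
                           cfg$input_map)
        res <- pretrain_layer(layer, h, cfg$pretrain_epochs,
                              cfg$learning_rate, batch_size)
        layers[[l]] <- res$layer
        traces[[l]] <- res$trace
        z <- h %*% res$layer$W + matrix(res$layer$b, nrow(h),
                                        cfg$hidden_layers[l], byrow = TRUE)
        h <- layer_activation(res$layer, z)
      }
      # the output affine map (the hidden-to-output weights) always trains
      layers[[length(layers) + 1]] <- new_layer(h, cfg$output_dim,
                                                cfg$width_rule,
                                                output_act(cfg), "trained")
      net <- structure(list(config = cfg, layers = layers,
                            classes = levels(y), fitted = FALSE,
                            pretrain = traces),
                       class = "deep_rbfnn")
    }

    # supervised warm-up: only the output layer trains on the frozen
    # pretrained features (stacked-autoencoder practice; gives the joint
    # phase an informative top layer to backpropagate from)
    if (cfg$warmup_epochs > 0) {
      frozen <- vapply(net$layers, function(l) isFALSE(l$train_map), TRUE)
      L <- length(net$layers)
      for (l in seq_len(L - 1)) net$layers[[l]]$train_map <- FALSE
      net <- sgd_epochs(net, x, target, cfg, cfg$warmup_epochs, batch_size)$net
      for (l in seq_len(L - 1)) net$layers[[l]]$train_map <- !frozen[l]
    }

    # joint fine-tuning of every layer, keeping the best epoch checkpoint
    tuned <- sgd_epochs(net, x, target, cfg, cfg$max_epochs, batch_size,
                        track = TRUE)
    net <- tuned$net
    mse_trace <- tuned$trace
    converged <- tuned$converged
    settled <- tuned$settled
    epochs_run <- tuned$epochs_run
  })

  list(net = net,
       report = list(epochs_run = epochs_run,
                     final_train_mse = epoch_mse(net, x, target),
                     converged = converged, settled = settled,
                     mse = mse_trace))
}

#' Predict classes and per-class scores
#'
#' Scores are the output-layer activations (one column per class); the
#' predicted class is the argmax, with exact ties broken toward the
#' negative (first) class — `non_DM` for schema labels. Scores are exposed
#' for ROC analysis via [roc_curve()].
#'
#' @param object A fitted `deep_rbfnn`.
#' @param newdata Numeric matrix (or single vector) with `input_dim`
#'   columns.
#' @param type `"class"` (default) for predicted labels, `"score"` for the
#'   score matrix.
#' @param ... Unused.
#' @return A factor of predicted classes, or a numeric score matrix with
#'   one named column per class.
#' @export
predict.deep_rbfnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$fitted)) tn_stop("state_error", "network has not been fitted")
  scores <- forward_pass(object, newdata)$output
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  pos <- scores[, 2] > scores[, 1] # ties -> negative class
  factor(ifelse(pos, object$classes[2], object$classes[1]),
         levels = object$classes)
}
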