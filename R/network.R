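#' Configure a deep RBF network
#'
#' Collects the architecture and training hyperparameters of the deep
#' radial basis function classifier. The defaults are the reference
#' configuration: 8 inputs, seven hidden layers of 3-5-7-5-3-4-3 Gaussian
#' units, 2 output units, learning rate 0.2, mean-square-error convergence
#' criterion 1e-6 and mini-batches of 40 samples.
#'
#' @param input_dim Number of input coordinates (8 for encoded tongue
#'   records; set higher for dense feature vectors from an external
#'   convolutional backend).
#' @param hidden_layers Hidden layer sizes, in order.
#' @param output_dim Number of output units (2: non-DM, DM).
#' @param learning_rate Gradient-descent step size.
#' @param convergence Epoch mean-square-error threshold; training stops
#'   when the epoch MSE falls below it (`converged`) or when the
#'   epoch-over-epoch improvement does (`settled`).
#' @param batch_size Mini-batch size (shrunk to the training size when
#'   larger).
#' @param max_epochs Hard cap on fine-tuning epochs (default 150, about
#'   twice the epoch count at which the reference configuration converges).
#' @param pretrain_epochs Autoencoder pretraining epochs per layer.
#' @param warmup_epochs Supervised warm-up epochs in which only the output
#'   layer trains on the frozen pretrained features before joint
#'   fine-tuning (standard stacked-autoencoder practice; stabilizes the
#'   deep Gaussian stack).
#' @param width_rule `"nearest-center"` — each unit's width is the mean
#'   distance to its two nearest sibling centers; or `"cluster-spread"` —
#'   the RMS radius of the unit's k-means cluster.
#' @param kmeans_scope `"per-layer"` (centers recomputed on each layer's
#'   pretrained input encodings) or `"single-shot"` (all centers fixed
#'   upfront from the initial forward pass).
#' @param output_activation `"gaussian"` (reference behaviour) or
#'   `"linear"` (diagnostic mode: a plain affine output map).
#' @param input_map `"trained"` — each layer's affine net-input map is
#'   learned (seeded uniform init in `[-1/sqrt(fan-in), 1/sqrt(fan-in)]`);
#'   or `"identity"` — the map is frozen at the identity, giving a
#'   classical RBF stack whose distances are taken in each layer's raw
#'   input space.
#' @param seed Integer seed; `(config, data, seed)` fully determine the
#'   fitted model.
#' @return An `rbf_config` list.
#' @export
rbf_config <- function(input_dim = 8L,
                       hidden_layers = c(3L, 5L, 7L, 5L, 3L, 4L, 3L),
                       output_dim = 2L,
                       learning_rate = 0.2,
                       convergence = 1e-6,
                       batch_size = 40L,
                       max_epochs = 150L,
                       pretrain_epochs = 30L,
                       warmup_epochs = 30L,
                       width_rule = c("nearest-center", "cluster-spread"),
                       kmeans_scope = c("per-layer", "single-shot"),
                       output_activation = c("gaussian", "linear"),
                       input_map = c("trained", "identity"),
                       seed = 1L) {
  if (!is_count(input_dim) || input_dim < 1) tn_stop("config_error", "input_dim must be >= 1")
  if (!all(vapply(hidden_layers, is_count, TRUE)) || any(hidden_layers < 1)) {
    tn_stop("config_error", "hidden layer sizes must be counts >= 1")
  }
  if (!is_count(output_dim) || output_dim < 1) tn_stop("config_error", "output_dim must be >= 1")
  if (learning_rate <= 0) tn_stop("config_error", "learning_rate must be > 0")
  if (convergence <= 0) tn_stop("config_error", "convergence must be > 0")
  if (!is_count(batch_size) || batch_size < 1) tn_stop("config_error", "batch_size must be >= 1")
  structure(list(
    input_dim = as.integer(input_dim),
    hidden_layers = as.integer(hidden_layers),
    output_dim = as.integer(output_dim),
    learning_rate = learning_rate,
    convergence = convergence,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    pretrain_epochs = as.integer(pretrain_epochs),
    warmup_epochs = as.integer(warmup_epochs),
    width_rule = match.arg(width_rule),
    kmeans_scope = match.arg(kmeans_scope),
    output_activation = match.arg(output_activation),
    input_map = match.arg(input_map),
    seed = as.integer(seed)
  ), class = "rbf_config")
}

#' Gaussian radial basis activation
#'
#' `phi(d2, sigma) = exp(-d2 / (2 sigma^2))` for squared distance `d2` and
#' width `sigma`. Returns values in (0, 1\], strictly decreasing in `d2`,
#' equal to 1 at the center and `exp(-1)` at `d2 = 2 sigma^2`.
#'
#' @param d2 Nonnegative squared distance(s).
#' @param sigma Positive width(s), recycled against `d2`.
#' @return Numeric vector of activations.
#' @export
gaussian_phi <- function(d2, sigma) {
  if (any(!is.finite(d2)) || any(d2 < 0)) {
    tn_stop("argument_error", "squared distances must be finite and nonnegative")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    tn_stop("argument_error", "width sigma must be positive")
  }
  exp(-d2 / (2 * sigma^2))
}

#' Seeded k-means clustering (k-means++ start, Lloyd iterations)
#'
#' Initializes centers by the k-means++ rule under the given seed, then
#' runs Lloyd's algorithm until the cluster assignment reaches a fixpoint
#' or `max_iter` iterations. The within-cluster sum of squares is
#' non-increasing across iterations; an emptied cluster is reseeded to the
#' point farthest from its center. Used to place each layer's radial
#' centers.
#'
#' @param x Numeric matrix, one observation per row.
#' @param k Number of centers; must not exceed the number of distinct rows.
#' @param seed Integer seed.
#' @param max_iter Lloyd iteration cap (default 300).
#' @return List with `centers` (k x ncol(x)), `assignments` (length
#'   nrow(x)), `wcss` (within-cluster sum of squares) and `iterations`.
#' @export
kmeans_centers <- function(x, k, seed = 1L, max_iter = 300L) {
  x <- as.matrix(x)
  if (nrow(x) == 0) tn_stop("argument_error", "empty data")
  n_distinct <- nrow(unique(x))
  if (!is_count(k) || k < 1) tn_stop("argument_error", "k must be a positive count")
  if (k > n_distinct) {
    tn_stop("argument_error", "k = %d exceeds the %d distinct points", k, n_distinct)
  }
  withr::with_seed(seed, kmeans_impl(x, as.integer(k), as.integer(max_iter)))
}

sq_dist_to <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

kmeans_impl <- function(x, k, max_iter) {
  n <- nrow(x)
  # k-means++ seeding
  centers <- x[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- pmax(apply(sq_dist_to(x, centers), 1, min), 0)
    if (sum(d2) <= 0) { # all remaining mass on existing centers
      pick <- which(!duplicated(rbind(centers, x))[-seq_len(nrow(centers))])[1]
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers <- rbind(centers, x[pick, , drop = FALSE])
  }
  assign_prev <- rep(0L, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- sq_dist_to(x, centers)
    assign_cur <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      idx <- which(assign_cur == j)
      if (length(idx) == 0) { # reseed an emptied cluster deterministically
        far <- which.max(apply(d2, 1, min))
        centers[j, ] <- x[far, ]
        assign_cur[far] <- j
      } else {
        centers[j, ] <- colMeans(x[idx, , drop = FALSE])
      }
    }
    if (identical(assign_cur, assign_prev) || iter >= max_iter) break
    assign_prev <- assign_cur
  }
  d2 <- sq_dist_to(x, centers)
  assign_cur <- max.col(-d2, ties.method = "first")
  wcss <- sum(d2[cbind(seq_len(n), assign_cur)])
  list(centers = unname(centers), assignments = assign_cur,
       wcss = max(wcss, 0), iterations = iter)
}

# ---- layer construction ----------------------------------------------------

# A layer maps m inputs to k radial units. The trainable affine map acts
# input-side of the distance to the centers: net input z = x W + b (k-dim),
# activation of unit j is phi(||z - r_j||^2, sigma_j) with the k centers
# r_j placed by k-means on the layer's mapped input encodings. With the
# identity map (W = I, untrained) this reduces to a classical RBF layer
# whose distances are taken in the raw input space of the layer.
new_layer <- function(input_data, k, width_rule, activation = "gaussian",
                      input_map = "trained") {
  m <- ncol(input_data)
  if (input_map == "identity") {
    W <- diag(1, m, k)
    b <- numeric(k)
  } else {
    lim <- 1 / sqrt(m)
    W <- matrix(stats::runif(m * k, -lim, lim), nrow = m, ncol = k)
    b <- numeric(k)
  }
  z <- input_data %*% W + matrix(b, nrow(input_data), k, byrow = TRUE)
  layer <- list(W = W, b = b, centers = NULL, sigma = NULL,
                activation = activation,
                train_map = !identical(input_map, "identity"))
  if (activation == "gaussian_unit") {
    # per-unit Gaussian transfer on the affine net input: a = exp(-z^2/2);
    # used at the output layer, where the two units score the two classes
    layer$sigma <- rep(1, k)
  } else if (activation == "gaussian") {
    uz <- unique(as.matrix(z))
    if (nrow(uz) >= k) {
      km <- kmeans_impl(as.matrix(z), k, 300L)
      centers <- km$centers
      assignments <- km$assignments
    } else {
      # degenerate encodings (fewer distinct points than units, e.g. a
      # collapsed upstream layer): spread centers deterministically around
      # the distinct points so later fine-tuning can still revive the layer
      eps <- 1e-3 * (1 + mean(abs(uz)))
      base <- uz[rep_len(seq_len(nrow(uz)), k), , drop = FALSE]
      shift <- matrix(0, k, ncol(uz))
      shift[cbind(seq_len(k), rep_len(seq_len(ncol(uz)), k))] <-
        eps * seq_len(k)
      centers <- base + shift
      assignments <- max.col(-sq_dist_to(as.matrix(z), centers),
                             ties.method = "first")
    }
    layer$centers <- centers
    layer$sigma <- layer_widths(centers, z, assignments, width_rule)
  }
  layer
}

# width heuristics in the layer's net-input space
layer_widths <- function(centers, z, assignments, width_rule) {
  k <- nrow(centers)
  nearest <- vapply(seq_len(k), function(j) {
    if (k == 1) {
      return(sqrt(max(mean(sq_dist_to(z, centers)[, 1]), 0)))
    }
    d <- sort(sqrt(pmax(sq_dist_to(centers[-j, , drop = FALSE],
                                   centers[j, , drop = FALSE]), 0)))
    mean(d[seq_len(min(2, length(d)))])
  }, 0)
  sigma <- nearest
  if (width_rule == "cluster-spread") {
    d2 <- sq_dist_to(z, centers)
    for (j in seq_len(k)) {
      idx <- which(assignments == j)
      if (length(idx) >= 2) sigma[j] <- sqrt(mean(pmax(d2[idx, j], 0)))
    }
  }
  # floor widths at a fraction of the layer's overall center spread:
  # near-duplicate centers would otherwise produce near-zero widths whose
  # 1/sigma^2 activation derivatives destabilize the gradient chain
  spread <- if (k >= 2) {
    sqrt(mean(pmax(sq_dist_to(centers, centers), 0))) # RMS pairwise distance
  } else {
    sigma[1]
  }
  pmax(sigma, 0.3 * spread, 1e-3)
}

layer_activation <- function(layer, z) {
  switch(layer$activation,
    linear = z,
    gaussian_unit = exp(-sweep(z^2, 2, 2 * layer$sigma^2, "/")),
    {
      d2 <- pmax(sq_dist_to(z, layer$centers), 0)
      sweep(-d2, 2, 2 * layer$sigma^2, "/") |> exp()
    })
}

# dE/dz from dE/da: chain through the activation derivative; for the
# radial units da_j/dz = -a_j (z - r_j) / sigma_j^2
layer_grad_z <- function(layer, z, a, d_a) {
  switch(layer$activation,
    linear = d_a,
    gaussian_unit = d_a * (-sweep(z, 2, layer$sigma^2, "/") * a),
    {
      coef <- sweep(d_a * a, 2, layer$sigma^2, "/")
      coef %*% layer$centers - z * rowSums(coef)
    })
}

#' Forward pass through a deep RBF network
#'
#' Propagates inputs through every layer: per layer the affine net input
#' `z = x W + b` followed by the Gaussian radial activation relative to the
#' layer's centers (the output layer uses the configured output
#' activation). All intermediate net inputs and activations are returned
#' for gradient computation. With the Gaussian output, scores lie in
#' (0, 1\].
#'
#' @param net A fitted or initialized `deep_rbfnn` object.
#' @param x Numeric matrix (rows = samples) or a single numeric vector,
#'   with `input_dim` columns.
#' @return List with `z` and `a` (per-layer lists of net-input and
#'   activation matrices) and `output` (the last activation matrix).
#' @export
forward_pass <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$config$input_dim) {
    tn_stop("contract_error", "input has %d columns, expected %d",
            ncol(x), net$config$input_dim)
  }
  h <- x
  zs <- vector("list", length(net$layers))
  as <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    layer <- net$layers[[l]]
    z <- h %*% layer$W + matrix(layer$b, nrow(h), length(layer$b), byrow = TRUE)
    a <- layer_activation(layer, z)
    if (any(!is.finite(a))) tn_stop("numeric_error", "non-finite activation in layer %d", l)
    zs[[l]] <- z; as[[l]] <- a
    h <- a
  }
  list(z = zs, a = as, output = h)
}

#' Backpropagated gradients of the squared-error loss
#'
#' Computes analytic gradients of `E = 1/2 sum_k (y_target - y_predicted)^2`
#' (averaged over the rows of `x`) with respect to every layer's weights
#' and biases, chaining the Gaussian activation derivative through the
#' deep stack: at the output, `delta_k = -(y_target - y_predicted) f'(y_ink)`
#' and `dE/dv_jk = delta_k z_j`; one layer down,
#' `delta_j = sum_k delta_k v_jk f'(z_inj)` and `dE/dw_ij = delta_j x_i`.
#'
#' @param net A `deep_rbfnn` object.
#' @param x Input matrix (rows = samples).
#' @param y_target Target matrix, same rows as `x`, `output_dim` columns
#'   (one-hot for classification).
#' @param forward Optional precomputed [forward_pass()] result.
#' @return List with `grads` (per layer: `W`, `b`), `loss` (mean per-sample
#'   E) and `output`.
#' @export
backprop_gradients <- function(net, x, y_target, forward = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y_target))) y_target <- matrix(y_target, nrow = 1)
  fw <- forward %||% forward_pass(net, x)
  n <- nrow(x)
  L <- length(net$layers)
  grads <- vector("list", L)
  resid <- fw$output - y_target                       # -(t - o) = dE/d output
  d_a <- resid
  for (l in rev(seq_len(L))) {
    delta <- layer_grad_z(net$layers[[l]], fw$z[[l]], fw$a[[l]], d_a)
    if (any(!is.finite(delta))) {
      tn_stop("numeric_error", "non-finite gradient in layer %d", l)
    }
    h_prev <- if (l == 1) x else fw$a[[l - 1]]
    grads[[l]] <- list(W = crossprod(h_prev, delta) / n,
                       b = colMeans(delta))
    if (l > 1) d_a <- delta %*% t(net$layers[[l]]$W)
  }
  list(grads = grads, loss = mean(rowSums(resid^2)) / 2, output = fw$output)
}

#' Gradient-descent weight update
#'
#' Applies the descent rule `w(t+1) = w(t) - alpha dE/dw` to every layer's
#' weights and biases. Zero gradients or `alpha = 0` leave the network
#' unchanged.
#'
#' @param net A `deep_rbfnn` object.
#' @param grads Gradient list from [backprop_gradients()].
#' @param alpha Learning rate (>= 0).
#' @return The updated network.
#' @export
update_weights <- function(net, grads, alpha) {
  if (alpha < 0) tn_stop("argument_error", "alpha must be nonnegative")
  if (!is.null(grads$grads)) grads <- grads$grads
  for (l in seq_along(net$layers)) {
    if (isFALSE(net$layers[[l]]$train_map)) next # frozen identity map
    net$layers[[l]]$W <- net$layers[[l]]$W - alpha * grads[[l]]$W
    net$layers[[l]]$b <- net$layers[[l]]$b - alpha * grads[[l]]$b
  }
  net
}

# mean per-sample squared-error loss over a dataset
epoch_mse <- function(net, x, y_target) {
  out <- forward_pass(net, x)$output
  mean(rowSums((out - y_target)^2)) / 2
}

# ---- serialization ---------------------------------------------------------

MODEL_SCHEMA_VERSION <- "1.0"

#' Save / load a deep RBF network as JSON
#'
#' Serializes the full model — configuration, per-layer centers, widths,
#' weights and biases, class labels, pretraining traces and the training
#' report — as a single versioned JSON document at full floating-point
#' precision, and restores it losslessly.
#'
#' @param net A `deep_rbfnn` object.
#' @param path Output (input) file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `deep_rbfnn` object.
#' @rdname model_io
#' @export
save_model <- function(net, path) {
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    config = unclass(net$config),
    classes = net$classes,
    fitted = isTRUE(net$fitted),
    layers = lapply(net$layers, function(l) list(
      W = l$W, b = l$b, centers = l$centers, sigma = l$sigma,
      activation = l$activation, train_map = l$train_map
    )),
    pretrain = net$pretrain,
    report = net$report
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname model_io
#' @export
load_model <- function(path) {
  if (!file.exists(path)) tn_stop("data_error", "no such file: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version)) tn_stop("data_error", "not a model file: %s", path)
  cfg <- doc$config
  config <- rbf_config(
    input_dim = cfg$input_dim, hidden_layers = cfg$hidden_layers,
    output_dim = cfg$output_dim, learning_rate = cfg$learning_rate,
    convergence = cfg$convergence, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, pretrain_epochs = cfg$pretrain_epochs,
    warmup_epochs = cfg$warmup_epochs %||% 30L,
    width_rule = cfg$width_rule, kmeans_scope = cfg$kmeans_scope,
    output_activation = cfg$output_activation,
    input_map = cfg$input_map %||% "trained", seed = cfg$seed
  )
  layers <- lapply(seq_len(nrow_layers(doc$layers)), function(i) {
    l <- layer_slice(doc$layers, i)
    list(W = as.matrix(l$W), b = as.numeric(l$b),
         centers = if (length(l$centers)) as.matrix(l$centers) else NULL,
         sigma = if (length(l$sigma)) as.numeric(l$sigma) else NULL,
         activation = l$activation, train_map = isTRUE(l$train_map))
  })
  structure(list(config = config, layers = layers, classes = doc$classes,
                 fitted = isTRUE(doc$fitted), pretrain = doc$pretrain,
                 report = doc$report),
            class = "deep_rbfnn")
}

# jsonlite may simplify the layer list to a data.frame; normalize access
nrow_layers <- function(layers) if (is.data.frame(layers)) nrow(layers) else length(layers)
layer_slice <- function(layers, i) {
  if (is.data.frame(layers)) {
    list(W = layers$W[[i]], b = layers$b[[i]], centers = layers$centers[[i]],
         sigma = layers$sigma[[i]], activation = layers$activation[[i]],
         train_map = layers$train_map[[i]])
  } else layers[[i]]
}

#' @export
print.deep_rbfnn <- function(x, ...) {
  cfg <- x$config
  cat("Deep RBF network classifier\n")
  cat(sprintf("  architecture: %d -> %s -> %d (%s output)\n", cfg$input_dim,
              paste(cfg$hidden_layers, collapse = "-"), cfg$output_dim,
              cfg$output_activation))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  if (isTRUE(x$fitted)) {
    cat(sprintf("  fitted: %d epoch(s), final train MSE %.3g%s\n",
                x$report$epochs_run, x$report$final_train_mse,
                if (isTRUE(x$report$converged)) " (converged)"
                else if (isTRUE(x$report$settled)) " (settled)" else ""))
  } else {
    cat("  not fitted\n")
  }
  invisible(x)
}
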