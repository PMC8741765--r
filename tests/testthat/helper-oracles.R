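# Independent oracles and small fixture builders used across the suite.

# straight-line re-computation of the forward pass, one sample and one
# unit at a time, without the package's matrix layer abstraction
oracle_forward <- function(net, x) {
  h <- as.numeric(x)
  for (layer in net$layers) {
    k <- length(layer$b)
    z <- numeric(k)
    for (j in seq_len(k)) {
      z[j] <- sum(h * layer$W[, j]) + layer$b[j]
    }
    a <- numeric(k)
    for (j in seq_len(k)) {
      a[j] <- switch(layer$activation,
        linear = z[j],
        gaussian_unit = exp(-z[j]^2 / (2 * layer$sigma[j]^2)),
        exp(-sum((z - layer$centers[j, ])^2) / (2 * layer$sigma[j]^2)))
    }
    h <- a
  }
  h
}

# central finite differences of the mean per-sample squared-error loss
oracle_fd_gradients <- function(net, x, y_target, eps = 1e-5) {
  loss_of <- function(n2) {
    out <- forward_pass(n2, x)$output
    mean(rowSums((out - y_target)^2)) / 2
  }
  lapply(seq_along(net$layers), function(l) {
    gW <- net$layers[[l]]$W * 0
    for (i in seq_along(gW)) {
      np <- net; np$layers[[l]]$W[i] <- np$layers[[l]]$W[i] + eps
      nm <- net; nm$layers[[l]]$W[i] <- nm$layers[[l]]$W[i] - eps
      gW[i] <- (loss_of(np) - loss_of(nm)) / (2 * eps)
    }
    gb <- net$layers[[l]]$b * 0
    for (i in seq_along(gb)) {
      np <- net; np$layers[[l]]$b[i] <- np$layers[[l]]$b[i] + eps
      nm <- net; nm$layers[[l]]$b[i] <- nm$layers[[l]]$b[i] - eps
      gb[i] <- (loss_of(np) - loss_of(nm)) / (2 * eps)
    }
    list(W = gW, b = gb)
  })
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}

# worst relative disagreement between analytic and finite-difference
# gradients over every parameter of the network; the denominator floor
# keeps finite-difference roundoff on near-zero gradients from counting
gradient_check <- function(net, x, y_target) {
  an <- backprop_gradients(net, x, y_target)$grads
  fd <- oracle_fd_gradients(net, x, y_target)
  worst <- 0
  for (l in seq_along(an)) {
    worst <- max(worst,
                 max_rel_err(an[[l]]$W, fd[[l]]$W, 1e-4),
                 max_rel_err(an[[l]]$b, fd[[l]]$b, 1e-4))
  }
  worst
}

# random small network via the package's own initializer
random_small_net <- function(seed, input_dim = 2, hidden = c(3),
                             output_activation = "gaussian") {
  cfg <- rbf_config(input_dim = input_dim, hidden_layers = hidden,
                    output_activation = output_activation, seed = seed)
  x <- withr::with_seed(seed + 5000, matrix(stats::runif(12 * input_dim), 12))
  list(net = init_deep_rbfnn(cfg, x), x = x)
}

# O(n^2) pairwise AUC oracle (Mann-Whitney identity)
oracle_auc <- function(scores, labels, positive = "DM") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# brute-force confusion tally
oracle_confusion <- function(pred, lab, positive = "DM") {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == positive && lab[i] == positive) tp <- tp + 1L
    else if (pred[i] == positive) fp <- fp + 1L
    else if (lab[i] == positive) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# one valid record with every feature at its clinically unremarkable
# reference category
reference_record <- function() {
  data.frame(tongue_body = "medium", tongue_color = "mild_red",
             red_spots = FALSE, black_spots = FALSE, fissures = FALSE,
             petechiae = FALSE, teeth_markings = FALSE, fur_color = "white",
             saliva = "normal", fur_thickness = "thin", label = "non_DM",
             stringsAsFactors = FALSE)
}

# small labeled cohort of r records cycling through the vocabulary
mixed_records <- function(n, seed = 1) {
  schema <- tongue_schema()
  withr::with_seed(seed, data.frame(
    tongue_body = sample(schema$levels$tongue_body, n, replace = TRUE),
    tongue_color = sample(schema$levels$tongue_color, n, replace = TRUE),
    red_spots = sample(c(TRUE, FALSE), n, replace = TRUE),
    black_spots = sample(c(TRUE, FALSE), n, replace = TRUE),
    fissures = sample(c(TRUE, FALSE), n, replace = TRUE),
    petechiae = sample(c(TRUE, FALSE), n, replace = TRUE),
    teeth_markings = sample(c(TRUE, FALSE), n, replace = TRUE),
    fur_color = sample(c("white", "black", "yellow"), n, replace = TRUE),
    saliva = sample(schema$levels$saliva, n, replace = TRUE),
    fur_thickness = sample(c("thin", "thick"), n, replace = TRUE),
    label = sample(c("DM", "non_DM"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# two well-separated 8-d Gaussian blobs, one per class
blob_data <- function(n_per_class = 60, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per_class * 8, 0, 0.5), n_per_class),
               matrix(stats::rnorm(n_per_class * 8, sep, 0.5), n_per_class))
  })
  list(x = x, y = rep(c("non_DM", "DM"), each = n_per_class))
}

# tiny fast network configuration for pipeline-level tests
tiny_config <- function(seed = 1, ...) {
  rbf_config(hidden_layers = c(4L), max_epochs = 40L, pretrain_epochs = 5L,
             warmup_epochs = 10L, seed = seed, ...)
}
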