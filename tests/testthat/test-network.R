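# Radial layers: k-means centers, Gaussian activation, forward pass,
# analytic gradients, weight updates, serialization.

test_that("k-means recovers centroid identities and tight blobs", {
  x <- matrix(runif(40), 20, 2)
  km1 <- kmeans_centers(x, 1, seed = 1)
  expect_equal(km1$centers[1, ], colMeans(x), tolerance = 1e-12)

  means <- rbind(c(0, 0), c(10, 0), c(0, 10))
  blobs <- withr::with_seed(4, {
    do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(60, 0, 0.01), 30, 2), 2, means[i, ], "+")
    }))
  })
  km3 <- kmeans_centers(blobs, 3, seed = 2)
  worst <- max(apply(means, 1, function(m) {
    min(sqrt(rowSums(sweep(km3$centers, 2, m)^2)))
  }))
  expect_lt(worst, 0.05)

  # one point per cluster: centers are the points, zero dispersion
  pts <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  kmn <- kmeans_centers(pts, 3, seed = 3)
  expect_equal(kmn$wcss, 0)
  expect_equal(pts[order(pts[, 1]), ], kmn$centers[order(kmn$centers[, 1]), ],
               ignore_attr = TRUE)
})

test_that("k-means solutions are competitive with the stats::kmeans oracle", {
  x <- withr::with_seed(11, matrix(rnorm(300), 100, 3))
  km <- kmeans_centers(x, 4, seed = 1)
  oracle <- withr::with_seed(1, stats::kmeans(x, 4, nstart = 10,
                                              iter.max = 300))
  expect_lt(km$wcss, oracle$tot.withinss * 1.10)
  expect_length(km$assignments, 100)
})

test_that("k-means rejects degenerate inputs", {
  expect_error(kmeans_centers(matrix(numeric(0), 0, 2), 1),
               class = "tonguenet_argument_error")
  x <- matrix(1, 4, 2)
  expect_error(kmeans_centers(x, 2), class = "tonguenet_argument_error")
  expect_error(kmeans_centers(x, 0), class = "tonguenet_argument_error")
})

test_that("gaussian_phi matches its closed form and is monotone", {
  expect_equal(gaussian_phi(0, 2), 1)
  expect_equal(gaussian_phi(2 * 1.5^2, 1.5), exp(-1))
  withr::with_seed(9, {
    for (i in 1:20) {
      sigma <- runif(1, 0.1, 3)
      d2 <- sort(runif(10, 0, 10))
      phi <- gaussian_phi(d2, sigma)
      expect_equal(phi, exp(-d2 / (2 * sigma^2)))
      expect_true(all(diff(phi) < 0))
      expect_true(all(phi > 0 & phi <= 1))
    }
  })
  expect_error(gaussian_phi(1, 0), class = "tonguenet_argument_error")
  expect_error(gaussian_phi(-1, 1), class = "tonguenet_argument_error")
})

test_that("forward pass agrees with the straight-line oracle", {
  for (seed in 1:5) {
    rs <- random_small_net(seed, input_dim = 3, hidden = c(4, 2))
    x <- rs$x[1, ]
    expect_equal(as.numeric(forward_pass(rs$net, x)$output),
                 oracle_forward(rs$net, x), tolerance = 1e-12)
  }
})

test_that("batch forward equals per-sample forwards and scores stay in (0,1]", {
  rs <- random_small_net(3, input_dim = 4, hidden = c(3, 3))
  batch <- forward_pass(rs$net, rs$x)$output
  for (i in seq_len(nrow(rs$x))) {
    expect_equal(batch[i, ], as.numeric(forward_pass(rs$net, rs$x[i, ])$output))
  }
  expect_true(all(batch > 0 & batch <= 1))
  expect_error(forward_pass(rs$net, matrix(1, 2, 7)),
               class = "tonguenet_contract_error")
})

test_that("analytic gradients match central finite differences", {
  worst <- 0
  for (seed in 1:30) {
    rs <- random_small_net(seed, input_dim = 2, hidden = c(3))
    x <- rs$x[1:4, ]
    y <- withr::with_seed(seed + 900, matrix(runif(8), 4, 2))
    worst <- max(worst, gradient_check(rs$net, x, y))
  }
  expect_lt(worst, 1e-6)
})

test_that("a perfect prediction has exactly zero gradients", {
  rs <- random_small_net(8, input_dim = 2, hidden = c(3))
  out <- forward_pass(rs$net, rs$x)$output
  bp <- backprop_gradients(rs$net, rs$x, out)
  expect_equal(bp$loss, 0)
  for (g in bp$grads) {
    expect_true(all(g$W == 0))
    expect_true(all(g$b == 0))
  }
})

test_that("doubling the residual doubles gradients for a linear output", {
  rs <- random_small_net(2, input_dim = 2, hidden = c(3),
                         output_activation = "linear")
  out <- forward_pass(rs$net, rs$x)$output
  g1 <- backprop_gradients(rs$net, rs$x, out - 0.1)$grads
  g2 <- backprop_gradients(rs$net, rs$x, out - 0.2)$grads
  for (l in seq_along(g1)) {
    expect_equal(2 * g1[[l]]$W, g2[[l]]$W, tolerance = 1e-12)
    expect_equal(2 * g1[[l]]$b, g2[[l]]$b, tolerance = 1e-12)
  }
})

test_that("weight updates follow the descent rule and respect alpha = 0", {
  rs <- random_small_net(4)
  bp <- backprop_gradients(rs$net, rs$x,
                           matrix(0.5, nrow(rs$x), 2))
  same <- update_weights(rs$net, bp$grads, 0)
  expect_identical(same$layers, rs$net$layers)
  zero <- lapply(bp$grads, function(g) list(W = g$W * 0, b = g$b * 0))
  expect_identical(update_weights(rs$net, zero, 0.3)$layers, rs$net$layers)

  # scalar quadratic toy: E = 1/2 (t - w x)^2, hand-derived step
  toy <- list(config = rbf_config(input_dim = 1, hidden_layers = 1L,
                                  output_dim = 1),
              layers = list(list(W = matrix(2), b = 0, centers = NULL,
                                 sigma = NULL, activation = "linear",
                                 train_map = TRUE)),
              classes = c("a", "b"), fitted = TRUE)
  class(toy) <- "deep_rbfnn"
  bp <- backprop_gradients(toy, matrix(3), matrix(1))   # o = 6, t = 1
  expect_equal(bp$grads[[1]]$W[1], (6 - 1) * 3)          # dE/dw = (o-t) x
  upd <- update_weights(toy, bp$grads, 0.01)
  expect_equal(upd$layers[[1]]$W[1], 2 - 0.01 * 15)
})

test_that("width rules give positive widths tied to center geometry", {
  x <- withr::with_seed(5, matrix(runif(200), 100, 2))
  for (rule in c("nearest-center", "cluster-spread")) {
    cfg <- rbf_config(input_dim = 2, hidden_layers = c(5), width_rule = rule,
                      seed = 2)
    net <- init_deep_rbfnn(cfg, x)
    expect_true(all(net$layers[[1]]$sigma > 0))
  }
})

test_that("model JSON round trip is lossless", {
  bd <- blob_data(20, seed = 6)
  fit <- deep_rbfnn(bd$x, bd$y, tiny_config(seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_equal(back$layers, fit$layers, tolerance = 1e-12)
  expect_equal(back$classes, fit$classes)
  x_new <- withr::with_seed(1, matrix(rnorm(80, 3, 2), 10, 8))
  expect_equal(predict(back, x_new, type = "score"),
               predict(fit, x_new, type = "score"), tolerance = 1e-10)
  expect_error(load_model("no-such-file.json"), class = "tonguenet_data_error")
})
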