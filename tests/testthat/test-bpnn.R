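toy_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_input = 3L, n_hidden = 4L, n_output = 2L, learning_rate = 0.1,
         momentum = 0, max_epochs = 10L),
    list(...))
  do.call(network_config, args)
}

test_that("initialization is seeded, shaped, and in [-0.5, 0.5]", {
  cfg <- network_config(seed = 99L)
  s1 <- init_state(cfg); s2 <- init_state(cfg)
  expect_identical(s1, s2)
  expect_equal(dim(s1$W_ih), c(401L, 45L))  # bias row appended
  expect_equal(dim(s1$W_ho), c(46L, 2L))
  expect_true(all(abs(s1$W_ih) <= 0.5) && all(abs(s1$W_ho) <= 0.5))
  expect_true(all(s1$prev_delta_ih == 0) && all(s1$prev_delta_ho == 0))
  s3 <- init_state(network_config(seed = 100L))
  expect_false(identical(s1$W_ih, s3$W_ih))
})

test_that("forward pass matches hand-evaluated sigmoids", {
  # all-zero weights: every neuron sees potential 0, sigma(0) = 0.5
  cfg <- toy_cfg(seed = 1L)
  st <- init_state(cfg)
  st$W_ih[] <- 0; st$W_ho[] <- 0
  out <- nn_forward(st, c(0.3, 0.9, 0.1))
  expect_equal(out$output, c(0.5, 0.5))

  # 1-1-1 net, w = 1, b = 0, v = 1, c = 0, input 0:
  # hidden = sigma(0) = 0.5, output = sigma(0.5) = 0.62245933...
  st1 <- list(W_ih = matrix(c(1, 0), 2, 1), W_ho = matrix(c(1, 0), 2, 1),
              prev_delta_ih = matrix(0, 2, 1), prev_delta_ho = matrix(0, 2, 1))
  class(st1) <- "network_state"
  out1 <- nn_forward(st1, 0)
  expect_equal(out1$hidden, 0.5)
  expect_equal(out1$output, 1 / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(out1$output, 0.622459, tolerance = 1e-6)

  # sigmoid outputs are strictly inside (0, 1)
  set.seed(8)
  for (i in 1:10) {
    st <- init_state(toy_cfg(seed = i))
    o <- nn_forward(st, runif(3, -5, 5))$output
    expect_true(all(o > 0 & o < 1))
  }
  expect_error(nn_forward(st, c(1, 2)), class = "amypet_shape_error")
})

test_that("a zero-error pattern is a fixed point of the update", {
  cfg <- toy_cfg(seed = 5L, momentum = 0.9)
  st <- init_state(cfg)
  x <- c(0.2, 0.7, 0.4)
  target <- nn_forward(st, x)$output  # error is exactly zero
  st2 <- backprop_step(st, x, target, cfg)
  expect_equal(st2$W_ih, st$W_ih)
  expect_equal(st2$W_ho, st$W_ho)
})

test_that("analytic gradient matches central differences (momentum 0)", {
  set.seed(123)
  worst <- 0
  for (rep in 1:50) {
    cfg <- network_config(n_input = 3L, n_hidden = 4L, n_output = 2L,
                          learning_rate = 1, momentum = 0, seed = rep)
    st <- init_state(cfg)
    x <- runif(3, -1, 1)
    target <- as.numeric(sample(c(0, 1), 2, replace = TRUE))
    st2 <- backprop_step(st, x, target, cfg)
    # with eta = 1 and alpha = 0 the update IS the negative loss gradient
    ana <- list(W_ih = -(st2$W_ih - st$W_ih), W_ho = -(st2$W_ho - st$W_ho))
    num <- oracle_numeric_grad(st, x, target)
    denom <- max(abs(unlist(num)), 1e-8)
    rel <- max(abs(unlist(ana) - unlist(num))) / denom
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("momentum re-applies the previous update", {
  cfg <- toy_cfg(seed = 2L, momentum = 0.9)
  st0 <- init_state(cfg)
  x <- c(0.5, -0.2, 0.8); target <- c(1, 0)
  st1 <- backprop_step(st0, x, target, cfg)
  d1_ih <- st1$W_ih - st0$W_ih
  expect_equal(st1$prev_delta_ih, d1_ih)  # buffer stores dW(t)

  st2 <- backprop_step(st1, x, target, cfg)
  # second update = fresh gradient term + 0.9 * first update
  cfg0 <- toy_cfg(seed = 2L, momentum = 0)
  st1_clean <- st1
  st1_clean$prev_delta_ih[] <- 0; st1_clean$prev_delta_ho[] <- 0
  grad_only <- backprop_step(st1_clean, x, target, cfg0)
  expect_equal(st2$W_ih - st1$W_ih,
               (grad_only$W_ih - st1$W_ih) + 0.9 * d1_ih, tolerance = 1e-12)
  expect_equal(st2$W_ho - st1$W_ho,
               (grad_only$W_ho - st1$W_ho) + 0.9 * (st1$W_ho - st0$W_ho),
               tolerance = 1e-12)
})

test_that("one small-step epoch decreases single-pattern squared error", {
  set.seed(31)
  for (rep in 1:10) {
    cfg <- network_config(n_input = 3L, n_hidden = 4L, n_output = 2L,
                          learning_rate = 0.01, momentum = 0, seed = rep)
    st <- init_state(cfg)
    x <- runif(3, -1, 1); target <- c(1, 0)
    before <- oracle_loss(st, x, target)
    after <- oracle_loss(backprop_step(st, x, target, cfg), x, target)
    expect_lt(after, before)
  }
})

test_that("the fast training loop equals sequential single steps", {
  cfg <- network_config(n_input = 5L, n_hidden = 3L, n_output = 2L,
                        learning_rate = 0.2, momentum = 0.9, seed = 7L)
  st <- init_state(cfg)
  set.seed(77)
  X <- matrix(runif(20 * 5), 20, 5)
  T <- cbind(rep(c(1, 0), 10), rep(c(0, 1), 10))
  fast <- amypet:::.cpp_train(st$W_ih, st$W_ho, st$prev_delta_ih,
                              st$prev_delta_ho, X, T, cfg$learning_rate,
                              cfg$momentum, 1e-12, 3L, 0L, TRUE, FALSE)
  slow <- st
  for (e in 1:3) for (p in 1:20)
    slow <- backprop_step(slow, X[p, ], T[p, ], cfg)
  expect_equal(fast$W_ih, slow$W_ih, tolerance = 1e-13)
  expect_equal(fast$W_ho, slow$W_ho, tolerance = 1e-13)
  expect_equal(fast$prev_delta_ih, slow$prev_delta_ih, tolerance = 1e-13)
})

test_that("training separates two Gaussian blobs and reproduces exactly", {
  # separation 10 sigma: linearly separable with a wide margin
  set.seed(202)
  n <- 20
  X <- rbind(cbind(rnorm(n, 0, 1), rnorm(n, 0, 1)),
             cbind(rnorm(n, 10, 1), rnorm(n, 10, 1)))
  labels <- rep(c("NC", "AD"), each = n)
  cfg <- network_config(n_input = 2L, n_hidden = 8L, n_output = 2L,
                        learning_rate = 0.05, momentum = 0.9,
                        min_rms = 0.003, max_epochs = 5000L, seed = 42L)
  fit <- nn_train(X, labels, cfg, classes = c("NC", "AD"))
  expect_true(fit$converged)
  expect_lte(fit$final_rms, 0.003)
  expect_identical(fit$converged, fit$final_rms <= cfg$min_rms)
  pred <- nn_predict(fit, X)
  expect_equal(mean(c("NC", "AD")[pred + 1] == labels), 1)  # 100% training

  fit2 <- nn_train(X, labels, cfg, classes = c("NC", "AD"))
  expect_identical(fit$rms_history, fit2$rms_history)
  expect_identical(fit$state$W_ih, fit2$state$W_ih)
})

test_that("train validates its inputs", {
  cfg <- toy_cfg()
  expect_error(nn_train(matrix(numeric(0), 0, 3), character(0), cfg),
               class = "amypet_validation_error")
  expect_error(nn_train(matrix(1, 2, 3), c("NC", "NC"), cfg,
                        classes = c("NC", "AD")),
               class = "amypet_validation_error")
  expect_error(nn_train(matrix(1, 2, 2), c("NC", "AD"), cfg),
               class = "amypet_shape_error")
})

test_that("prediction is argmax with ties toward the lower index", {
  st <- list(W_ih = matrix(0, 3, 4), W_ho = matrix(0, 5, 2),
             prev_delta_ih = matrix(0, 3, 4), prev_delta_ho = matrix(0, 5, 2))
  class(st) <- "network_state"
  # zero weights: outputs are (0.5, 0.5) for any input -> class 0
  expect_equal(nn_predict(st, matrix(runif(6, -9, 9), 3, 2)), rep(0L, 3))
  # bias makes output 2 win
  st$W_ho[5, 2] <- 1
  expect_equal(nn_predict(st, c(0, 0)), 1L)
  expect_error(nn_predict(st, c(1, 2, 3)), class = "amypet_shape_error")
})

test_that("ReLU is hidden-layer only; outputs stay in (0,1)", {
  cfg <- network_config(n_input = 3L, n_hidden = 6L, n_output = 2L,
                        learning_rate = 0.05, momentum = 0.5,
                        activation = "relu", max_epochs = 50L, seed = 9L)
  st <- init_state(cfg)
  out <- nn_forward(st, c(2, -3, 1), activation = "relu")
  expect_true(all(out$hidden >= 0))        # ReLU is unbounded above, >= 0
  expect_true(all(out$output > 0 & out$output < 1))  # sigmoid output layer
  X <- rbind(c(0, 0, 0), c(1, 1, 1))
  fit <- nn_train(X, c("NC", "AD"), cfg, classes = c("NC", "AD"))
  expect_true(all(is.finite(fit$rms_history)))
})

test_that("models survive a JSON save/load round trip exactly", {
  cfg <- network_config(n_input = 2L, n_hidden = 3L, n_output = 2L,
                        learning_rate = 0.05, max_epochs = 20L, seed = 3L)
  X <- rbind(c(0, 0), c(1, 1), c(0.1, 0), c(0.9, 1))
  fit <- nn_train(X, c("NC", "AD", "NC", "AD"), cfg, classes = c("NC", "AD"))
  f <- tempfile(fileext = ".json")
  save_model(fit, f)
  back <- load_model(f)
  # decimal JSON costs at most a couple of ULPs on a weight
  expect_equal(back$state$W_ih, unname(fit$state$W_ih), tolerance = 1e-14)
  expect_equal(back$state$W_ho, unname(fit$state$W_ho), tolerance = 1e-14)
  expect_identical(back$classes, fit$classes)
  expect_equal(nn_predict(back, X), nn_predict(fit, X))
})
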