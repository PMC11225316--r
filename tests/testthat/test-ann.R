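makeToyNet <- function(weights, config) {
  duospec:::newTrainedNet(config, weights,
    list(in_min = rep(-1, config$n_inputs),
         in_max = rep(1, config$n_inputs),
         out_min = rep(-1, config$n_outputs),
         out_max = rep(1, config$n_outputs)),
    data.frame(), "lm", 0L, NA_real_, 0L)
}

test_that("weight initialization is seeded and shape-correct", {
  cfg <- netConfig(5, c(2L, 2L))
  w1 <- initWeights(cfg, 7)
  w2 <- initWeights(cfg, 7)
  w3 <- initWeights(cfg, 8)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
  expect_equal(dim(w1[[1]]$W), c(2L, 5L))
  expect_equal(dim(w1[[2]]$W), c(2L, 2L))
  expect_equal(dim(w1[[3]]$W), c(2L, 2L))
  expect_length(w1[[3]]$b, 2L)
})

test_that("the forward pass matches its closed forms", {
  cfg <- netConfig(3, 2L)
  wts <- initWeights(cfg, 1)
  # zero weights: output equals the output biases for every sample
  wz <- lapply(wts, function(l) list(W = l$W * 0, b = l$b * 0))
  wz[[2]]$b <- c(0.3, -0.2)
  net <- makeToyNet(wz, cfg)
  out <- annForward(net, matrix(rnorm(12), 4, 3))
  expect_equal(out, matrix(rep(c(0.3, -0.2), each = 4), 4, 2))
  # tanh linear regime approximates the underlying linear map (biases
  # zeroed so the operating point sits at the origin)
  wl <- wts
  wl[[1]]$b <- rep(0, 2)
  net2 <- makeToyNet(wl, cfg)
  X <- matrix(rnorm(30), 10, 3) * 1e-3
  lin <- t(wl[[2]]$W %*% (wl[[1]]$W %*% t(X) + wl[[1]]$b) + wl[[2]]$b)
  expect_equal(annForward(net2, X), lin, tolerance = 1e-4)
  # batch forward equals row-by-row forward
  rowwise <- t(vapply(seq_len(10), function(i)
    annForward(net2, X[i, , drop = FALSE])[1, ], numeric(2)))
  expect_equal(annForward(net2, X), rowwise)
})

test_that("the backprop Jacobian matches central finite differences", {
  for (hidden in list(2L, c(2L, 2L))) {
    cfg <- netConfig(5, hidden)
    wts <- initWeights(cfg, 3)
    set.seed(4)
    Xs <- matrix(runif(4 * 5, -1, 1), 4, 5)
    jr <- duospec:::netJacobian(wts, cfg, Xs)
    theta <- duospec:::flattenWeights(wts)
    h <- 1e-6
    fd <- vapply(seq_along(theta), function(k) {
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      yp <- duospec:::forwardScaled(duospec:::unflattenWeights(tp, cfg), Xs)
      ym <- duospec:::forwardScaled(duospec:::unflattenWeights(tm, cfg), Xs)
      as.vector((yp[[length(yp)]] - ym[[length(ym)]])) / (2 * h)
    }, numeric(4 * 2))
    # as.vector of the outputs x samples matrix stacks sample-major,
    # output-minor: the same ordering as the Jacobian rows
    expect_equal(jr$J, fd, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("damping interpolates between gradient descent and Gauss-Newton", {
  cfg <- netConfig(2, 1L)
  wts <- initWeights(cfg, 2)
  set.seed(9)
  Xs <- matrix(runif(10 * 2, -1, 1), 10, 2)
  Ys <- matrix(runif(10 * 2, -1, 1), 10, 2)
  jr <- duospec:::netJacobian(wts, cfg, Xs)
  e <- as.vector(t(jr$yhat - Ys))
  g <- crossprod(jr$J, e)
  JtJ <- crossprod(jr$J)
  P <- length(g)
  cosang <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  step_big <- solve(JtJ + diag(1e8, P), -g)
  expect_gt(cosang(step_big, -g), 1 - 1e-6)
  step_small <- solve(JtJ + diag(1e-12, P), -g)
  gn <- solve(JtJ, -g)
  expect_equal(as.numeric(step_small), as.numeric(gn), tolerance = 1e-4)
})

test_that("LM training solves a linear problem and is reproducible", {
  set.seed(5)
  X <- matrix(runif(20 * 3, -1, 1), 20, 3)
  M <- matrix(c(0.5, -1, 2, 1, 0.3, -0.7), 3, 2)
  Y <- X %*% M
  cfg <- netConfig(3, 2L)
  net <- trainLm(X, Y, cfg, lmParams(seed = 1, max_epochs = 1000,
                                     grad_tol = 1e-12))
  pred <- annForward(net, X)
  expect_lt(sqrt(mean((pred - Y)^2)), 1e-4)
  net2 <- trainLm(X, Y, cfg, lmParams(seed = 1, max_epochs = 1000,
                                      grad_tol = 1e-12))
  expect_identical(net@history, net2@history)
  expect_identical(net@weights, net2@weights)
  # accepted-step rule keeps the training error non-increasing
  expect_true(all(diff(net@history$train_sse) <= 1e-12))
})

test_that("a one-sample set warns and stops without crashing", {
  X <- matrix(c(0.1, 0.5, -0.2), 1, 3)
  Y <- matrix(c(1, 2), 1, 2)
  w <- capture_warnings(
    net <- trainLm(X, Y, netConfig(3, 2L), lmParams(seed = 1)))
  expect_true(any(grepl("degenerate scaling", w)))
  expect_true(any(grepl("rank-deficient", w)))
  expect_s4_class(net, "TrainedNet")
})

test_that("Bayesian regularization learns a noiseless linear map", {
  set.seed(6)
  X <- matrix(runif(20 * 3, -1, 1), 20, 3)
  Y <- X %*% matrix(c(0.5, -1, 2, 1, 0.3, -0.7), 3, 2)
  net <- trainBr(X, Y, netConfig(3, 2L), brParams(seed = 2, max_epochs = 300))
  expect_lt(sqrt(mean((annForward(net, X) - Y)^2)), 1e-3)
  # effective parameters near what a 3 -> 2 linear map needs (8), far
  # below the 14 available
  expect_gt(net@gamma, 3)
  expect_lt(net@gamma, 14)
  net2 <- trainBr(X, Y, netConfig(3, 2L), brParams(seed = 2, max_epochs = 300))
  expect_identical(net@weights, net2@weights)
})

test_that("regularization shrinks weights relative to plain LM under noise", {
  set.seed(12)
  X <- matrix(runif(30 * 3, -1, 1), 30, 3)
  Y <- X %*% matrix(c(0.5, -1, 2, 1, 0.3, -0.7), 3, 2) +
    matrix(rnorm(60, 0, 0.5), 30, 2)
  cfg <- netConfig(3, 2L)
  nb <- trainBr(X, Y, cfg, brParams(seed = 3, max_epochs = 150))
  nl <- trainLm(X, Y, cfg, lmParams(seed = 3, max_epochs = 150))
  ew <- function(n) sum(duospec:::flattenWeights(n@weights)^2)
  expect_lt(ew(nb), ew(nl))
})
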