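#' Feed-forward network configuration
#'
#' TANSIG (hyperbolic tangent) hidden layers, PURELIN (identity) output
#' layer; one or two hidden layers. Both components are predicted jointly
#' by one two-output net.
#'
#' @param n_inputs number of input features (75 for the standard
#'   279.0-316.0 nm, 0.5 nm absorbance window)
#' @param hidden integer vector of hidden-layer neuron counts (length 1-2)
#' @param n_outputs number of outputs (default 2)
#' @return a config list
#' @export
netConfig <- function(n_inputs, hidden = 2L, n_outputs = 2L) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1L || length(hidden) > 2L)
    stop("1 or 2 hidden layers supported")
  if (any(hidden < 1L)) stop("hidden neuron counts must be >= 1")
  list(n_inputs = as.integer(n_inputs), hidden = hidden,
       n_outputs = as.integer(n_outputs),
       sizes = c(as.integer(n_inputs), hidden, as.integer(n_outputs)))
}

#' Levenberg-Marquardt training parameters
#'
#' @param mu0 initial damping
#' @param mu_inc,mu_dec damping adaptation factors
#' @param mu_max damping ceiling (training stops above it)
#' @param max_epochs epoch cap
#' @param grad_tol gradient infinity-norm stopping threshold
#' @param patience consecutive validation-error increases tolerated
#' @param seed RNG seed for weight initialization
#' @export
lmParams <- function(mu0 = 1e-3, mu_inc = 10, mu_dec = 0.1, mu_max = 1e10,
                     max_epochs = 1000L, grad_tol = 1e-7, patience = 6L,
                     seed = 1L) {
  list(mu0 = mu0, mu_inc = mu_inc, mu_dec = mu_dec, mu_max = mu_max,
       max_epochs = as.integer(max_epochs), grad_tol = grad_tol,
       patience = as.integer(patience), seed = as.integer(seed))
}

#' Bayesian-regularization training parameters
#'
#' @param alpha0,beta0 initial hyperparameters of the regularized objective
#'   F = beta ED + alpha EW
#' @param max_epochs epoch cap
#' @param grad_tol gradient infinity-norm stopping threshold
#' @param mu0,mu_inc,mu_dec,mu_max inner Levenberg-Marquardt damping
#' @param seed RNG seed for weight initialization
#' @export
brParams <- function(alpha0 = 0, beta0 = 1, max_epochs = 1000L,
                     grad_tol = 1e-7, mu0 = 1e-3, mu_inc = 10,
                     mu_dec = 0.1, mu_max = 1e10, seed = 1L) {
  list(alpha0 = alpha0, beta0 = beta0, max_epochs = as.integer(max_epochs),
       grad_tol = grad_tol, mu0 = mu0, mu_inc = mu_inc, mu_dec = mu_dec,
       mu_max = mu_max, seed = as.integer(seed))
}

#' Seeded weight initialization
#'
#' Nguyen-Widrow initialization for hidden layers (normalized random
#' directions scaled to 0.7 H^(1/fan_in), evenly spread biases), small
#' uniform weights for the output layer.
#'
#' @param config a \code{\link{netConfig}}
#' @param seed integer seed
#' @return list of layers, each list(W, b)
#' @export
initWeights <- function(config, seed = 1L) {
  withSeed(seed, {
    sizes <- config$sizes
    nl <- length(sizes) - 1L
    lapply(seq_len(nl), function(l) {
      fan_in <- sizes[l]; n <- sizes[l + 1L]
      if (l < nl) {
        W <- matrix(stats::runif(n * fan_in, -1, 1), n, fan_in)
        W <- W / pmax(sqrt(rowSums(W^2)), 1e-12)
        beta <- 0.7 * n^(1 / fan_in)
        W <- beta * W
        b <- if (n == 1L) 0 else beta * seq(-1, 1, length.out = n) *
          sign(W[, 1])
        list(W = W, b = as.numeric(b))
      } else {
        list(W = matrix(stats::runif(n * fan_in, -0.1, 0.1), n, fan_in),
             b = stats::runif(n, -0.1, 0.1))
      }
    })
  })
}

#' Min-max scaling of features and targets to [-1, 1]
#' @keywords internal
minmaxParams <- function(X, Y) {
  rng <- function(M, what) {
    mn <- apply(M, 2, min); mx <- apply(M, 2, max)
    if (any(mx - mn <= 0)) {
      if (nrow(M) == 1L) {
        # a single sample cannot define a range; widen symmetrically so a
        # degenerate set still runs (the trainer warns rank-deficient)
        warning("degenerate scaling: single-sample ", what,
                " given unit range")
        pad <- pmax(abs(mn), 1)
        mn <- mn - pad; mx <- mx + pad
      } else stop("constant ", what, " rejected: no spread to scale")
    }
    list(min = mn, max = mx)
  }
  i <- rng(X, "input feature"); o <- rng(Y, "target")
  list(in_min = i$min, in_max = i$max, out_min = o$min, out_max = o$max)
}

scaleMat <- function(M, mn, mx) {
  sweep(sweep(M, 2, mn), 2, (mx - mn) / 2, "/") - 1
}

unscaleMat <- function(M, mn, mx) {
  sweep(sweep(M + 1, 2, (mx - mn) / 2, "*"), 2, mn, "+")
}

flattenWeights <- function(wts) {
  unlist(lapply(wts, function(l) c(as.vector(l$W), l$b)))
}

unflattenWeights <- function(theta, config) {
  sizes <- config$sizes
  out <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (l in seq_along(out)) {
    nw <- sizes[l + 1L] * sizes[l]
    W <- matrix(theta[pos + seq_len(nw)], sizes[l + 1L], sizes[l])
    pos <- pos + nw
    b <- theta[pos + seq_len(sizes[l + 1L])]
    pos <- pos + sizes[l + 1L]
    out[[l]] <- list(W = W, b = b)
  }
  out
}

# forward pass on scaled inputs; returns activations per layer
forwardScaled <- function(wts, Xs) {
  acts <- vector("list", length(wts) + 1L)
  acts[[1]] <- t(Xs)                       # features x samples
  for (l in seq_along(wts)) {
    z <- wts[[l]]$W %*% acts[[l]] + wts[[l]]$b
    acts[[l + 1L]] <- if (l < length(wts)) tanh(z) else z
  }
  acts
}

#' Forward pass of a trained net
#'
#' Scales raw inputs to [-1, 1], runs the TANSIG/PURELIN net, and unscales
#' the outputs back to concentration units.
#'
#' @param net a \linkS4class{TrainedNet}
#' @param X samples x n_inputs matrix of raw inputs
#' @return samples x n_outputs matrix of predictions (ug/ml)
#' @export
annForward <- function(net, X) {
  X <- matrix(X, ncol = net@config$n_inputs)
  s <- net@scaling
  Xs <- scaleMat(X, s$in_min, s$in_max)
  acts <- forwardScaled(net@weights, Xs)
  Ys <- t(acts[[length(acts)]])
  unscaleMat(Ys, s$out_min, s$out_max)
}

# Jacobian of the stacked scaled errors wrt the flat parameter vector, by
# per-sample backpropagation; rows ordered sample-major, output-minor.
netJacobian <- function(wts, config, Xs) {
  sizes <- config$sizes
  nl <- length(wts)
  n <- nrow(Xs)
  no <- config$n_outputs
  P <- sum(vapply(seq_len(nl), function(l)
    sizes[l + 1L] * sizes[l] + sizes[l + 1L], numeric(1)))
  acts <- forwardScaled(wts, Xs)
  J <- matrix(0, n * no, P)
  offs <- cumsum(c(0, vapply(seq_len(nl), function(l)
    sizes[l + 1L] * sizes[l] + sizes[l + 1L], numeric(1))))
  for (i in seq_len(n)) {
    a <- lapply(acts, function(A) A[, i])
    for (o in seq_len(no)) {
      delta <- vector("list", nl)
      d <- numeric(no); d[o] <- 1
      delta[[nl]] <- d
      if (nl > 1L)
        for (l in (nl - 1L):1L)
          delta[[l]] <- as.numeric(crossprod(wts[[l + 1L]]$W, delta[[l + 1L]])) *
            (1 - a[[l + 1L]]^2)
      row <- (i - 1L) * no + o
      for (l in seq_len(nl)) {
        gW <- outer(delta[[l]], a[[l]])
        J[row, (offs[l] + 1L):offs[l + 1L]] <- c(as.vector(gW), delta[[l]])
      }
    }
  }
  list(J = J, yhat = t(acts[[length(acts)]]))
}

stackErrors <- function(yhat, Ys) as.vector(t(yhat - Ys))

newTrainedNet <- function(config, wts, scaling, history, algorithm,
                          epochs, gamma, seed) {
  new("TrainedNet", config = config, weights = wts, scaling = scaling,
      history = history, algorithm = algorithm,
      epochs_run = as.integer(epochs), gamma = gamma,
      seed = as.integer(seed))
}

setMethod("show", "TrainedNet", function(object) {
  cat(sprintf(
    "TrainedNet (%s): %d-[%s]-%d TANSIG/PURELIN, %d epochs%s\n",
    object@algorithm, object@config$n_inputs,
    paste(object@config$hidden, collapse = ","), object@config$n_outputs,
    object@epochs_run,
    if (!is.na(object@gamma)) sprintf(", gamma = %.2f", object@gamma) else ""))
})

#' Levenberg-Marquardt backpropagation training
#'
#' Iterates the damped Gauss-Newton update
#' dw = (J'J + mu I)^-1 J'e with multiplicative damping adaptation: an
#' epoch's step is accepted (and mu divided) only if the training SSE
#' decreases, otherwise mu is multiplied and the step retried. Stops on the
#' epoch cap, the gradient threshold, the damping ceiling, or
#' \code{patience} consecutive validation-error increases; the returned
#' weights are those with the best validation error (final weights when no
#' validation set is given).
#'
#' @param X samples x n_inputs raw input matrix
#' @param Y samples x n_outputs raw target matrix
#' @param config a \code{\link{netConfig}}
#' @param params an \code{\link{lmParams}}
#' @param split list(train=, val=, test=) of row index vectors; val may be
#'   empty
#' @return a \linkS4class{TrainedNet}
#' @export
trainLm <- function(X, Y, config, params = lmParams(),
                    split = list(train = seq_len(nrow(X)),
                                 val = integer(0), test = integer(0))) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  scaling <- minmaxParams(X, Y)
  Xs <- scaleMat(X, scaling$in_min, scaling$in_max)
  Ys <- scaleMat(Y, scaling$out_min, scaling$out_max)
  tr <- split$train; va <- split$val
  wts <- initWeights(config, params$seed)
  theta <- flattenWeights(wts)
  P <- length(theta)
  if (length(tr) * config$n_outputs < P)
    warning("rank-deficient problem: fewer training errors (",
            length(tr) * config$n_outputs, ") than parameters (", P, ")")
  sse <- function(w, idx) {
    a <- forwardScaled(w, Xs[idx, , drop = FALSE])
    sum((t(a[[length(a)]]) - Ys[idx, , drop = FALSE])^2)
  }
  mu <- params$mu0
  train_sse <- sse(wts, tr)
  best_val <- Inf; best_wts <- wts; val_up <- 0L
  hist <- vector("list", params$max_epochs)
  epoch <- 0L
  while (epoch < params$max_epochs) {
    epoch <- epoch + 1L
    jr <- netJacobian(wts, config, Xs[tr, , drop = FALSE])
    e <- stackErrors(jr$yhat, Ys[tr, , drop = FALSE])
    g <- crossprod(jr$J, e)
    if (max(abs(2 * g)) < params$grad_tol) { epoch <- epoch - 1L; break }
    JtJ <- crossprod(jr$J)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(
        solve(JtJ + diag(mu, P), -g),
        error = function(err)
          stop("singular normal matrix at the damping floor; raise mu0"))
      cand <- unflattenWeights(theta + as.numeric(step), config)
      cand_sse <- sse(cand, tr)
      if (cand_sse < train_sse) {
        wts <- cand; theta <- theta + as.numeric(step)
        train_sse <- cand_sse
        mu <- max(mu * params$mu_dec, 1e-20)
        accepted <- TRUE
      } else {
        mu <- mu * params$mu_inc
        if (mu > params$mu_max) break
      }
    }
    val_sse <- if (length(va)) sse(wts, va) else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, train_sse = train_sse,
                                val_sse = val_sse, mu = mu)
    if (length(va)) {
      if (val_sse < best_val) {
        best_val <- val_sse; best_wts <- wts; val_up <- 0L
      } else val_up <- val_up + 1L
      if (val_up >= params$patience) break
    }
    if (!accepted) break                    # mu exceeded mu_max
  }
  final <- if (length(va)) best_wts else wts
  newTrainedNet(config, final, scaling,
                do.call(rbind, hist[seq_len(epoch)]), "lm", epoch,
                NA_real_, params$seed)
}

#' Bayesian-regularization backpropagation training
#'
#' Minimizes F = beta ED + alpha EW (ED the sum of squared scaled errors,
#' EW the sum of squared weights and biases) by damped Gauss-Newton inner
#' steps, re-estimating the hyperparameters after every epoch by the
#' evidence-framework updates: gamma = N - 2 alpha tr(H^-1),
#' alpha = gamma / (2 EW), beta = (n - gamma) / (2 ED), with
#' H = 2 beta J'J + 2 alpha I. No validation set is used.
#'
#' @param X samples x n_inputs raw input matrix
#' @param Y samples x n_outputs raw target matrix
#' @param config a \code{\link{netConfig}}
#' @param params a \code{\link{brParams}}
#' @return a \linkS4class{TrainedNet} with the effective number of
#'   parameters in \code{gamma}
#' @export
trainBr <- function(X, Y, config, params = brParams()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  scaling <- minmaxParams(X, Y)
  Xs <- scaleMat(X, scaling$in_min, scaling$in_max)
  Ys <- scaleMat(Y, scaling$out_min, scaling$out_max)
  wts <- initWeights(config, params$seed)
  theta <- flattenWeights(wts)
  P <- length(theta)
  nerr <- nrow(Xs) * config$n_outputs
  alpha <- params$alpha0; beta <- params$beta0
  ed <- function(w) {
    a <- forwardScaled(w, Xs)
    sum((t(a[[length(a)]]) - Ys)^2)
  }
  ED <- ed(wts); EW <- sum(theta^2)
  mu <- params$mu0
  gamma <- NA_real_
  hist <- vector("list", params$max_epochs)
  epoch <- 0L
  while (epoch < params$max_epochs) {
    epoch <- epoch + 1L
    jr <- netJacobian(wts, config, Xs)
    e <- stackErrors(jr$yhat, Ys)
    g <- 2 * beta * crossprod(jr$J, e) + 2 * alpha * theta
    if (max(abs(g)) < params$grad_tol) { epoch <- epoch - 1L; break }
    H <- 2 * beta * crossprod(jr$J) + diag(2 * alpha, P)
    Fcur <- beta * ED + alpha * EW
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(solve(H + diag(mu, P), -g),
                       error = function(err)
                         stop("singular regularized normal matrix; raise mu0"))
      cand_theta <- theta + as.numeric(step)
      cand <- unflattenWeights(cand_theta, config)
      cand_ED <- ed(cand); cand_EW <- sum(cand_theta^2)
      if (beta * cand_ED + alpha * cand_EW < Fcur) {
        wts <- cand; theta <- cand_theta; ED <- cand_ED; EW <- cand_EW
        mu <- max(mu * params$mu_dec, 1e-20)
        accepted <- TRUE
      } else {
        mu <- mu * params$mu_inc
        if (mu > params$mu_max) break
      }
    }
    # evidence-framework hyperparameter re-estimation (Foresee-Hagan)
    jr2 <- netJacobian(wts, config, Xs)
    H2 <- 2 * beta * crossprod(jr2$J) + diag(2 * max(alpha, 1e-12), P)
    trHinv <- sum(diag(solve(H2)))
    gamma <- P - 2 * alpha * trHinv
    gamma <- min(max(gamma, 1e-6), P)
    alpha <- gamma / (2 * max(EW, 1e-12))
    beta <- (nerr - gamma) / (2 * max(ED, 1e-12))
    if (beta <= 0) beta <- 1e-6
    hist[[epoch]] <- data.frame(epoch = epoch, train_sse = ED,
                                ew = EW, alpha = alpha, beta = beta,
                                gamma = gamma, mu = mu)
    if (!accepted) break
  }
  newTrainedNet(config, wts, scaling,
                do.call(rbind, hist[seq_len(epoch)]), "br", epoch, gamma,
                params$seed)
}

#' Evaluate a trained net on a test set
#'
#' @param net a \linkS4class{TrainedNet}
#' @param X_test samples x n_inputs raw inputs
#' @param Y_test samples x n_outputs true concentrations
#' @return list with per-output \code{\link{predictionMetrics}} and the
#'   pooled MSEP over all outputs
#' @export
evaluateNet <- function(net, X_test, Y_test) {
  Y_test <- as.matrix(Y_test)
  pred <- annForward(net, as.matrix(X_test))
  per <- lapply(seq_len(ncol(Y_test)), function(j)
    predictionMetrics(Y_test[, j], pred[, j]))
  names(per) <- colnames(Y_test)
  list(per_output = per, predictions = pred,
       pooled_msep = msep(as.vector(Y_test), as.vector(pred)))
}

#' Compare training algorithms and architectures on synthetic mixtures
#'
#' Trains every architecture with both algorithms on synthetic spectra of
#' the 32-mixture training design and evaluates each net on independently
#' generated spectra of the 10-mixture test design, one row per
#' seed/algorithm/architecture with MSEP, RRMSEP, BCMSEP and mean recovery
#' per component. The Levenberg-Marquardt nets use a seeded random
#' 30/6/6 train/validation/test split of the pooled 42 mixtures; the
#' Bayesian nets train on all 32 training mixtures with no validation.
#'
#' @param architectures list of hidden-layer vectors
#' @param seeds integer vector of seeds (one run per seed)
#' @param noise a \code{\link{noiseModel}} template (its seed is offset per
#'   run)
#' @param components list of the two \code{\link{componentModel}}s
#' @param max_epochs epoch cap passed to both trainers
#' @return data.frame of evaluation metrics
#' @export
compareAlgorithms <- function(architectures = list(1L, 2L, c(2L, 2L)),
                              seeds = 1:5, noise = noiseModel(),
                              components = list(ciLikeModel(), orLikeModel()),
                              max_epochs = 1000L) {
  rows <- list()
  for (seed in seeds) {
    d <- annDataset(seed, noise, components)
    for (arch in architectures) {
      cfg <- netConfig(ncol(d$X_train), arch)
      for (alg in c("br", "lm")) {
        net <- if (alg == "br")
          trainBr(d$X_train, d$Y_train, cfg,
                  brParams(max_epochs = max_epochs, seed = seed))
        else {
          pool_X <- rbind(d$X_train, d$X_test)
          pool_Y <- rbind(d$Y_train, d$Y_test)
          idx <- withSeed(seed + 500L, sample(nrow(pool_X)))
          trainLm(pool_X, pool_Y, cfg,
                  lmParams(max_epochs = max_epochs, seed = seed),
                  split = list(train = idx[1:30], val = idx[31:36],
                               test = idx[37:42]))
        }
        ev <- evaluateNet(net, d$X_eval, d$Y_eval)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, algorithm = alg,
          architecture = paste(arch, collapse = "x"),
          msep_ci = ev$per_output[[1]]$msep,
          msep_or = ev$per_output[[2]]$msep,
          rrmsep_ci = ev$per_output[[1]]$rrmsep,
          rrmsep_or = ev$per_output[[2]]$rrmsep,
          bcmsep_ci = ev$per_output[[1]]$bcmsep,
          bcmsep_or = ev$per_output[[2]]$bcmsep,
          pooled_msep = ev$pooled_msep,
          mean_recovery_ci = ev$per_output[[1]]$mean_recovery,
          mean_recovery_or = ev$per_output[[2]]$mean_recovery)
      }
    }
  }
  do.call(rbind, rows)
}

#' Synthetic train/test absorbance matrices for neural calibration
#'
#' Generates full-resolution scans of the 32-mixture training design and
#' the 10-mixture test design (plus an independent evaluation replicate of
#' the test design), resamples them to the 75-point neural-input grid, and
#' returns sample-major matrices.
#'
#' @param seed integer seed offsetting the noise streams
#' @param noise a \code{\link{noiseModel}} template
#' @param components list of the two \code{\link{componentModel}}s
#' @return list: X_train, Y_train, X_test, Y_test, X_eval, Y_eval
#' @export
annDataset <- function(seed = 1L, noise = noiseModel(),
                       components = list(ciLikeModel(), orLikeModel())) {
  sg <- scanGrid(); ag <- annGrid()
  mk <- function(design, off) {
    nm <- noiseModel(noise$additive_sd, noise$baseline_amp,
                     noise$seed + seed + off)
    set <- makeMixtureSet(components, design, nm, sg)
    X <- t(vapply(seq_len(nSpectra(set)), function(i)
      resample(getSpectrum(set, i), ag)@absorbance, numeric(ag@n_points)))
    list(X = X, Y = set@concentrations)
  }
  tr <- mk(referenceTrainingDesign(), 0L)
  te <- mk(referenceTestDesign(), 1000L)
  ev <- mk(referenceTestDesign(), 2000L)
  list(X_train = tr$X, Y_train = tr$Y, X_test = te$X, Y_test = te$Y,
       X_eval = ev$X, Y_eval = ev$Y)
}
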