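# Minimal fully-connected network machinery with exact reverse-mode
# gradients, written against base matrix ops. Layout convention: data
# matrices are (batch x features); a dense layer stores W (in x out) and
# bias b (out). Hidden blocks are dense -> batch norm -> ReLU; output
# blocks are dense with an optional sigmoid and never batch-normalized.
# Gradient correctness is pinned by a finite-difference test.

new_dense <- function(n_in, n_out) {
  # He-style initialization, suited to ReLU hidden units
  list(
    type = "dense",
    W = matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
    b = numeric(n_out)
  )
}

new_batchnorm <- function(n) {
  list(
    type = "batchnorm",
    gamma = rep(1, n), beta = numeric(n),
    running_mean = numeric(n), running_var = rep(1, n),
    momentum = 0.1, eps = 1e-5
  )
}

new_activation <- function(kind) list(type = "activation", kind = kind)

#' Build a feed-forward network
#'
#' Hidden layers are affine + batch normalization + ReLU. The output layer is
#' affine only for encoder outputs and predictor heads (`"linear"`) or affine
#' + logistic squashing for decoder outputs (`"sigmoid"`), and is never batch
#' normalized.
#'
#' @param sizes Integer vector of layer widths, input first, output last.
#' @param output Output activation, `"linear"` or `"sigmoid"`.
#' @param batchnorm Batch-normalize hidden layers (default `TRUE`).
#' @return An `msvae_net` object (list of blocks).
#' @keywords internal
build_network <- function(sizes, output = c("linear", "sigmoid"), batchnorm = TRUE) {
  output <- match.arg(output)
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  blocks <- list()
  n_hidden <- length(sizes) - 2L
  for (i in seq_len(n_hidden)) {
    blocks <- c(blocks, list(new_dense(sizes[i], sizes[i + 1L])))
    if (batchnorm) blocks <- c(blocks, list(new_batchnorm(sizes[i + 1L])))
    blocks <- c(blocks, list(new_activation("relu")))
  }
  blocks <- c(blocks, list(new_dense(sizes[length(sizes) - 1L], sizes[length(sizes)])))
  if (output == "sigmoid") blocks <- c(blocks, list(new_activation("sigmoid")))
  structure(list(blocks = blocks, sizes = sizes, output = output), class = "msvae_net")
}

# Forward pass. Returns list(out, caches, net) -- net is returned because
# training mode updates batch-norm running statistics.
net_forward <- function(net, X, training = FALSE) {
  X <- as.matrix(X)
  caches <- vector("list", length(net$blocks))
  for (i in seq_along(net$blocks)) {
    blk <- net$blocks[[i]]
    if (blk$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- X %*% blk$W + matrix(blk$b, nrow(X), length(blk$b), byrow = TRUE)
    } else if (blk$type == "batchnorm") {
      if (training) {
        mu <- colMeans(X)
        centered <- sweep(X, 2L, mu)
        v <- colMeans(centered^2)
        invstd <- 1 / sqrt(v + blk$eps)
        xhat <- sweep(centered, 2L, invstd, `*`)
        blk$running_mean <- (1 - blk$momentum) * blk$running_mean + blk$momentum * mu
        blk$running_var <- (1 - blk$momentum) * blk$running_var + blk$momentum * v
        net$blocks[[i]] <- blk
      } else {
        invstd <- 1 / sqrt(blk$running_var + blk$eps)
        xhat <- sweep(sweep(X, 2L, blk$running_mean), 2L, invstd, `*`)
      }
      caches[[i]] <- list(xhat = xhat, invstd = invstd)
      X <- sweep(sweep(xhat, 2L, blk$gamma, `*`), 2L, blk$beta, `+`)
    } else { # activation
      if (blk$kind == "relu") {
        caches[[i]] <- list(mask = X > 0)
        X <- X * caches[[i]]$mask
      } else { # sigmoid
        X <- 1 / (1 + exp(-X))
        caches[[i]] <- list(s = X)
      }
    }
  }
  list(out = X, caches = caches, net = net)
}

# Reverse pass: dOut is the gradient of the scalar loss w.r.t. the network
# output. Returns list(grads, dX); grads[[i]] matches blocks[[i]].
net_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$blocks))
  dX <- dOut
  for (i in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[i]]
    cache <- caches[[i]]
    if (blk$type == "dense") {
      grads[[i]] <- list(W = crossprod(cache$X, dX), b = colSums(dX))
      dX <- tcrossprod(dX, blk$W)
    } else if (blk$type == "batchnorm") {
      m <- nrow(dX)
      dgamma <- colSums(dX * cache$xhat)
      dbeta <- colSums(dX)
      dxhat <- sweep(dX, 2L, blk$gamma, `*`)
      # gradient through the batch statistics (biased variance)
      t1 <- sweep(dxhat, 2L, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
      dX <- sweep(t1 - t2, 2L, cache$invstd, `*`)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (blk$kind == "relu") {
      dX <- dX * cache$mask
    } else {
      dX <- dX * cache$s * (1 - cache$s)
    }
  }
  list(grads = grads, dX = dX)
}

## ---------------------------------------------------------------------------
## Parameter bookkeeping (flat views used by the optimizer and by tests)

net_param_names <- function(net) {
  out <- list()
  for (i in seq_along(net$blocks)) {
    blk <- net$blocks[[i]]
    if (blk$type == "dense") out[[length(out) + 1L]] <- list(block = i, names = c("W", "b"))
    if (blk$type == "batchnorm") out[[length(out) + 1L]] <- list(block = i, names = c("gamma", "beta"))
  }
  out
}

net_get_params <- function(net) {
  unlist(lapply(net_param_names(net), function(p) {
    unlist(lapply(p$names, function(nm) as.numeric(net$blocks[[p$block]][[nm]])))
  }))
}

net_set_params <- function(net, theta) {
  pos <- 1L
  for (p in net_param_names(net)) {
    for (nm in p$names) {
      cur <- net$blocks[[p$block]][[nm]]
      k <- length(cur)
      val <- theta[pos:(pos + k - 1L)]
      net$blocks[[p$block]][[nm]] <- if (is.matrix(cur)) {
        matrix(val, nrow(cur), ncol(cur))
      } else {
        val
      }
      pos <- pos + k
    }
  }
  stopifnot(pos - 1L == length(theta))
  net
}

grads_to_vector <- function(net, grads) {
  unlist(lapply(net_param_names(net), function(p) {
    unlist(lapply(p$names, function(nm) as.numeric(grads[[p$block]][[nm]])))
  }))
}

## ---------------------------------------------------------------------------
## Adam (adaptive-moment stochastic gradient)

adam_init <- function(n_params) {
  list(m = numeric(n_params), v = numeric(n_params), t = 0L)
}

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
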