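# Seeded stochastic-gradient training with the adaptive-moment (Adam)
# optimizer, an optional inverse-frequency weighted random sampler, and a
# per-epoch loss history.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size.
#' @param sampler `"uniform"` (shuffled epochs) or `"weighted_by_class"`
#'   (per-sample weights proportional to inverse class frequency, so each
#'   batch holds a similar number of instances from each class).
#' @param class_balance_factor Name of the factor column whose classes the
#'   weighted sampler balances (informational; the labels themselves are
#'   passed to [fit_vae()]/[joint_train()]).
#' @param seed Integer seed covering initialization order, the sampler, and
#'   the reparameterization noise.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 20L, batch_size = 64L,
                         sampler = c("uniform", "weighted_by_class"),
                         class_balance_factor = NULL, seed = 1L) {
  sampler <- match.arg(sampler)
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(
    list(
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), sampler = sampler,
      class_balance_factor = class_balance_factor, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

# Draw the epoch's batch index list. Weighted sampling draws with replacement
# with probability proportional to inverse class frequency.
epoch_batches <- function(n, cfg, labels = NULL) {
  idx <- if (cfg$sampler == "weighted_by_class") {
    if (is.null(labels)) {
      abort("sampler = 'weighted_by_class' requires class labels", class = "msvae_config_error")
    }
    freq <- table(labels)
    w <- as.numeric(1 / freq[as.character(labels)])
    sample.int(n, n, replace = TRUE, prob = w)
  } else {
    sample.int(n, n)
  }
  split(idx, ceiling(seq_along(idx) / cfg$batch_size))
}

apply_grads <- function(net, grads, opt, lr) {
  theta <- net_get_params(net)
  g <- grads_to_vector(net, grads)
  upd <- adam_step(opt, theta, g, lr)
  list(net = net_set_params(net, upd$theta), opt = upd$state)
}

#' Train a BetaVAE or JointVAE
#'
#' Stochastic-gradient optimization with Adam; all randomness (sampler order,
#' reparameterization noise, Gumbel draws) flows from `cfg$seed`. Training
#' aborts with the accumulated history attached if the loss turns non-finite.
#'
#' @param model A [betavae()] or [jointvae()].
#' @param vectors Numeric matrix of preprocessed spectrum vectors (rows =
#'   spectra).
#' @param cfg A [train_config()].
#' @param labels Optional class labels (one per row) for the weighted sampler.
#' @return The trained model, with the per-epoch loss history tibble in
#'   `$history`.
#' @export
fit_vae <- function(model, vectors, cfg = train_config(), labels = NULL) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != model$input_dim) {
    abort("vector width does not match the model input", class = "msvae_shape_error")
  }
  n <- nrow(vectors)
  joint <- inherits(model, "jointvae")
  withr::with_seed(cfg$seed, {
    enc_opt <- adam_init(length(net_get_params(model$encoder)))
    dec_opt <- adam_init(length(net_get_params(model$decoder)))
    history <- list()
    step <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      batches <- epoch_batches(n, cfg, labels)
      sums <- NULL
      for (b in batches) {
        X <- vectors[b, , drop = FALSE]
        res <- if (joint) jointvae_step(model, X, step) else betavae_step(model, X)
        if (!is.finite(res$losses$total)) {
          model$history <- dplyr::bind_rows(history)
          abort("training diverged (non-finite loss)",
            class = "msvae_numerical_error", body = c(i = sprintf("at epoch %d", epoch))
          )
        }
        model$encoder <- res$encoder
        model$decoder <- res$decoder
        eu <- apply_grads(model$encoder, res$enc_grads, enc_opt, cfg$learning_rate)
        du <- apply_grads(model$decoder, res$dec_grads, dec_opt, cfg$learning_rate)
        model$encoder <- eu$net
        enc_opt <- eu$opt
        model$decoder <- du$net
        dec_opt <- du$opt
        step <- step + 1L
        l <- unlist(res$losses)
        sums <- if (is.null(sums)) l else sums + l
      }
      history[[epoch]] <- tibble(epoch = epoch, !!!as.list(sums / length(batches)))
    }
    model$history <- dplyr::bind_rows(history)
  })
  model$trained_epochs <- model$trained_epochs + cfg$epochs
  class(model$history) <- c("msvae_history", class(model$history))
  model
}

## ---------------------------------------------------------------------------
## Supervised heads

# Cross-entropy over softmax logits; targets are integer class indices (1-based).
# Returns loss and gradient w.r.t. logits (mean over batch).
softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  picked <- p[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  d <- p
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  list(loss = loss, d_logits = d / n)
}

mse_head <- function(pred, y) {
  n <- length(y)
  d <- 2 * (pred - y) / n
  list(loss = mean((pred - y)^2), d_logits = matrix(d, ncol = 1L))
}

head_loss_grad <- function(out, y, task) {
  if (task == "classify") softmax_xent(out, y) else mse_head(as.numeric(out), y)
}

#' Jointly train a VAE with a downstream factor predictor
#'
#' One optimization of the summed loss: the VAE objective plus the head
#' objective (cross-entropy for classification, mean squared error for
#' regression). The head consumes the posterior-mean latent code concatenated
#' with the supplied non-target factor columns, and its gradient flows back
#' into the encoder through the mean path.
#'
#' @inheritParams fit_vae
#' @param target Target vector: a factor/character vector for
#'   `task = "classify"`, numeric for `task = "regress"`.
#' @param side_features Numeric matrix of the non-target factor columns
#'   concatenated to the latent code (may be `NULL`).
#' @param task `"classify"` or `"regress"`.
#' @param head_hidden Hidden widths of the predictor head.
#' @return A list with `model` (trained VAE), `head` (trained predictor net
#'   with `task`, `levels`), and `history` (per-epoch losses including the
#'   summed total).
#' @export
joint_train <- function(model, vectors, target, side_features = NULL,
                        task = c("classify", "regress"), head_hidden = c(16),
                        cfg = train_config(), labels = NULL) {
  task <- match.arg(task)
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (anyNA(target)) abort("target factor must be fully observed", class = "msvae_config_error")
  if (task == "classify") {
    lev <- sort(unique(as.character(target)))
    if (length(lev) < 2L) {
      abort("classification needs at least 2 target classes", class = "msvae_config_error")
    }
    y <- match(as.character(target), lev)
    out_dim <- length(lev)
  } else {
    lev <- NULL
    y <- as.numeric(target)
    out_dim <- 1L
  }
  side_std <- NULL
  if (!is.null(side_features)) {
    side_features <- as.matrix(side_features)
    side_std <- standardizer(side_features)
    side_features <- apply_standardizer(side_features, side_std)
  }
  head_in <- model$latent_dim + (if (is.null(side_features)) 0L else ncol(side_features))
  # the head standardizes only its side-feature block; the latent block is
  # already on unit scale
  head_std <- list(
    center = c(numeric(model$latent_dim), side_std$center),
    scale = c(rep(1, model$latent_dim), side_std$scale)
  )

  withr::with_seed(cfg$seed, {
    head <- build_network(c(head_in, head_hidden, out_dim), output = "linear")
    enc_opt <- adam_init(length(net_get_params(model$encoder)))
    dec_opt <- adam_init(length(net_get_params(model$decoder)))
    head_opt <- adam_init(length(net_get_params(head)))
    history <- list()
    for (epoch in seq_len(cfg$epochs)) {
      batches <- epoch_batches(n, cfg, labels %||% (if (task == "classify") target))
      sums <- NULL
      for (b in batches) {
        X <- vectors[b, , drop = FALSE]
        res <- betavae_step(model, X)
        model$encoder <- res$encoder
        model$decoder <- res$decoder

        # head forward/backward on the posterior mean of this batch
        ef <- net_forward(model$encoder, X, training = TRUE)
        parts <- split_encoder_output(model, ef$out)
        hin <- cbind(parts$mean, side_features[b, , drop = FALSE])
        hf <- net_forward(head, hin, training = TRUE)
        hl <- head_loss_grad(hf$out, y[b], task)
        bh <- net_backward(head, hf$caches, hl$d_logits)
        d_hin <- bh$dX
        d_mu <- d_hin[, seq_len(model$latent_dim), drop = FALSE]
        be <- net_backward(
          model$encoder, ef$caches,
          cbind(d_mu, matrix(0, nrow(X), model$latent_dim))
        )
        head <- hf$net
        model$encoder <- ef$net

        enc_grads <- Map(function(a, b) {
          if (is.null(a)) NULL else Map(`+`, a, b)
        }, res$enc_grads, be$grads)
        eu <- apply_grads(model$encoder, enc_grads, enc_opt, cfg$learning_rate)
        du <- apply_grads(model$decoder, res$dec_grads, dec_opt, cfg$learning_rate)
        hu <- apply_grads(head, bh$grads, head_opt, cfg$learning_rate)
        model$encoder <- eu$net
        enc_opt <- eu$opt
        model$decoder <- du$net
        dec_opt <- du$opt
        head <- hu$net
        head_opt <- hu$opt

        l <- c(unlist(res$losses), head = hl$loss)
        l["summed_total"] <- l["total"] + hl$loss
        sums <- if (is.null(sums)) l else sums + l
      }
      history[[epoch]] <- tibble(epoch = epoch, !!!as.list(sums / length(batches)))
    }
    history <- dplyr::bind_rows(history)
  })
  model$trained_epochs <- model$trained_epochs + cfg$epochs
  class(history) <- c("msvae_history", class(history))
  list(
    model = model,
    head = structure(list(net = head, task = task, levels = lev, std = head_std),
      class = "msvae_predictor"
    ),
    history = history
  )
}

# column-wise z-scoring; constant columns are left unscaled
standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2L, std$center), 2L, std$scale, `/`)
}

# Supervised training of a standalone feed-forward predictor (used by
# fit_predictor in the factor-inference module). Inputs are z-scored on the
# training set so factor columns on instrument scales (hundreds of Da) do not
# swamp binary codes.
train_head <- function(X, y, task, hidden, cfg, levels = NULL) {
  X <- as.matrix(X)
  std <- standardizer(X)
  X <- apply_standardizer(X, std)
  out_dim <- if (task == "classify") length(levels) else 1L
  withr::with_seed(cfg$seed, {
    net <- build_network(c(ncol(X), hidden, out_dim), output = "linear")
    opt <- adam_init(length(net_get_params(net)))
    for (epoch in seq_len(cfg$epochs)) {
      batches <- epoch_batches(nrow(X), cfg, if (task == "classify") y)
      for (b in batches) {
        f <- net_forward(net, X[b, , drop = FALSE], training = TRUE)
        hl <- head_loss_grad(f$out, y[b], task)
        bk <- net_backward(f$net, f$caches, hl$d_logits)
        upd <- apply_grads(f$net, bk$grads, opt, cfg$learning_rate)
        net <- upd$net
        opt <- upd$opt
      }
    }
  })
  structure(list(net = net, task = task, levels = levels, std = std),
    class = "msvae_predictor"
  )
}

#' Predict from a trained factor predictor
#'
#' @param object An `msvae_predictor` (from [fit_predictor()] or
#'   [joint_train()]).
#' @param newdata Numeric input matrix.
#' @param type `"response"` (class labels / numeric values) or `"prob"`
#'   (class probabilities, classification only).
#' @param ... Unused.
#' @export
predict.msvae_predictor <- function(object, newdata, type = c("response", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$std)) newdata <- apply_standardizer(newdata, object$std)
  out <- net_forward(object$net, newdata, training = FALSE)$out
  if (object$task == "regress") {
    return(as.numeric(out))
  }
  p <- softmax_rows(out)
  colnames(p) <- object$levels
  if (type == "prob") {
    return(p)
  }
  object$levels[max.col(p, ties.method = "first")]
}
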