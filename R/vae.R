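# BetaVAE and JointVAE over spectrum vectors. Encoder approximates the
# posterior q(z|x) (diagonal Gaussian, plus categorical blocks for JointVAE),
# decoder approximates the likelihood p(x|z) with a sigmoid output so every
# reconstructed cell lies in (0, 1). The reconstruction term is the squared
# Euclidean error over the 2N cells (summed per sample, averaged over the
# batch; m/z and intensity cells weighted equally), i.e. the Gaussian
# negative log-likelihood up to constants, so beta = 1 is the plain ELBO.

#' Construct a BetaVAE model
#'
#' @param input_dim Width of the spectrum vector (2 x max_num_peaks).
#' @param latent_dim Size of the continuous latent code.
#' @param beta KL-divergence weight; `beta = 1` recovers the plain VAE.
#' @param hidden Integer vector of encoder hidden-layer widths;
#'   `integer(0)` gives the depth-0 model (a single affine map).
#' @param decoder_hidden Decoder hidden widths; by default the decoder
#'   mirrors the encoder (symmetric architecture).
#' @param seed Seed for parameter initialization.
#' @return A `betavae` model object.
#' @export
betavae <- function(input_dim, latent_dim, beta = 1, hidden = c(64),
                    decoder_hidden = rev(hidden), seed = 1L) {
  stopifnot(beta > 0, latent_dim >= 1, input_dim >= 2)
  withr::with_seed(as.integer(seed), {
    encoder <- build_network(c(input_dim, hidden, 2L * latent_dim), output = "linear")
    decoder <- build_network(c(latent_dim, decoder_hidden, input_dim), output = "sigmoid")
  })
  structure(
    list(
      encoder = encoder, decoder = decoder,
      input_dim = as.integer(input_dim), latent_dim = as.integer(latent_dim),
      beta = beta, hidden = hidden, decoder_hidden = decoder_hidden,
      trained_epochs = 0L
    ),
    class = c("betavae", "msvae_model")
  )
}

#' Construct a JointVAE model
#'
#' Continuous and categorical latent blocks whose KL terms are driven toward
#' linearly growing capacity targets; categorical sampling uses the
#' Gumbel-softmax continuous relaxation during training and one-hot argmax at
#' evaluation time.
#'
#' @inheritParams betavae
#' @param cont_latent_dim Continuous latent size (may be 0 if discrete blocks
#'   exist).
#' @param disc_category_sizes Integer vector, one entry per categorical block
#'   giving its number of categories (may be empty).
#' @param cont_gamma,disc_gamma Capacity-loss weights.
#' @param cont_max_capacity,disc_max_capacity Final capacity targets (nats).
#' @param capacity_steps Training steps over which capacities ramp 0 -> max.
#' @param gumbel_temperature Relaxation temperature.
#' @return A `jointvae` model object.
#' @export
jointvae <- function(input_dim, cont_latent_dim, disc_category_sizes = integer(),
                     cont_gamma = 30, disc_gamma = 30,
                     cont_max_capacity = 5, disc_max_capacity = 5,
                     capacity_steps = 1000L, gumbel_temperature = 0.67,
                     hidden = c(64), decoder_hidden = rev(hidden), seed = 1L) {
  disc_category_sizes <- as.integer(disc_category_sizes)
  if (cont_latent_dim < 1 && !length(disc_category_sizes)) {
    abort("at least one of the continuous/discrete blocks must be non-empty")
  }
  stopifnot(
    cont_max_capacity >= 0, disc_max_capacity >= 0,
    gumbel_temperature > 0, all(disc_category_sizes >= 2)
  )
  n_disc <- sum(disc_category_sizes)
  withr::with_seed(as.integer(seed), {
    encoder <- build_network(c(input_dim, hidden, 2L * cont_latent_dim + n_disc),
      output = "linear"
    )
    decoder <- build_network(c(cont_latent_dim + n_disc, decoder_hidden, input_dim),
      output = "sigmoid"
    )
  })
  structure(
    list(
      encoder = encoder, decoder = decoder,
      input_dim = as.integer(input_dim),
      latent_dim = as.integer(cont_latent_dim),
      disc_category_sizes = disc_category_sizes,
      cont_gamma = cont_gamma, disc_gamma = disc_gamma,
      cont_max_capacity = cont_max_capacity, disc_max_capacity = disc_max_capacity,
      capacity_steps = as.integer(capacity_steps),
      gumbel_temperature = gumbel_temperature,
      hidden = hidden, decoder_hidden = decoder_hidden,
      trained_epochs = 0L
    ),
    class = c("jointvae", "msvae_model")
  )
}

split_encoder_output <- function(model, h) {
  L <- model$latent_dim
  out <- list(
    mean = h[, seq_len(L), drop = FALSE],
    log_variance = h[, L + seq_len(L), drop = FALSE]
  )
  if (inherits(model, "jointvae") && length(model$disc_category_sizes)) {
    pos <- 2L * L
    out$disc_logits <- lapply(model$disc_category_sizes, function(k) {
      block <- h[, pos + seq_len(k), drop = FALSE]
      pos <<- pos + k
      block
    })
  }
  out
}

softmax_rows <- function(X) {
  e <- exp(X - apply(X, 1L, max))
  e / rowSums(e)
}

#' Encode spectrum vectors to latent codes
#'
#' Runs the encoder in evaluation mode (batch normalization uses running
#' statistics), so the posterior mean path is deterministic -- correlation
#' analyses use this path.
#'
#' @param model A `betavae` or `jointvae`.
#' @param x Numeric matrix of spectrum vectors (or a single vector).
#' @param sample Draw a reparameterized sample (`sample` field); sampling uses
#'   the current RNG state.
#' @return A list with `mean`, `log_variance`, `sample`, and for JointVAE
#'   `discrete_probs` (per-block probability matrices, rows summing to 1).
#' @export
encode <- function(model, x, sample = FALSE) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != model$input_dim) abort("input width does not match the model", class = "msvae_shape_error")
  h <- net_forward(model$encoder, x, training = FALSE)$out
  parts <- split_encoder_output(model, h)
  code <- list(mean = parts$mean, log_variance = parts$log_variance)
  if (sample) {
    eps <- matrix(rnorm(length(parts$mean)), nrow(parts$mean))
    code$sample <- parts$mean + exp(0.5 * parts$log_variance) * eps
  } else {
    code$sample <- parts$mean
  }
  if (!is.null(parts$disc_logits)) {
    code$discrete_probs <- lapply(parts$disc_logits, softmax_rows)
    # straight-through evaluation: one-hot argmax per block
    onehot <- lapply(code$discrete_probs, function(p) {
      oh <- matrix(0, nrow(p), ncol(p))
      oh[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))] <- 1
      oh
    })
    code$sample <- cbind(code$sample, do.call(cbind, onehot))
  }
  code
}

#' Decode latent vectors to spectrum vectors
#'
#' @param model A `betavae` or `jointvae`.
#' @param z Numeric matrix of latent vectors (continuous code, with one-hot
#'   discrete blocks appended for JointVAE), or a single vector.
#' @return Matrix of decoded spectrum vectors with all cells in (0, 1).
#' @export
decode <- function(model, z) {
  z <- if (is.null(dim(z))) matrix(z, nrow = 1L) else as.matrix(z)
  expected <- model$latent_dim + sum(model$disc_category_sizes %||% 0L)
  if (ncol(z) != expected) abort("latent width does not match the model", class = "msvae_shape_error")
  net_forward(model$decoder, z, training = FALSE)$out
}

## ---------------------------------------------------------------------------
## Losses

gaussian_kl <- function(mean, log_variance) {
  # KL( N(mu, sigma^2) || N(0, I) ), summed over dimensions, averaged over rows
  mean(0.5 * rowSums(mean^2 + exp(log_variance) - 1 - log_variance))
}

categorical_kl <- function(probs) {
  # KL( q || uniform ) per block = log K - H(q), averaged over rows
  k <- ncol(probs)
  p <- pmax(probs, 1e-12)
  mean(rowSums(p * log(p * k)))
}

#' BetaVAE loss
#'
#' `total = reconstruction + beta * kl`, with the reconstruction term the
#' squared Euclidean error over cells (summed per sample, averaged over the
#' batch) and the KL term the closed-form divergence of the diagonal-Gaussian
#' posterior from the standard-normal prior (summed over latent dimensions,
#' averaged over the batch). At `beta = 1` this is the negative ELBO under a
#' unit-variance Gaussian reconstruction likelihood, up to constants.
#'
#' @param x,x_hat Input and reconstructed vectors (matrices or vectors of
#'   equal shape).
#' @param code Latent code list with `mean` and `log_variance` (see
#'   [encode()]).
#' @param beta KL weight.
#' @return Named list: `total`, `reconstruction`, `kl`.
#' @export
betavae_loss <- function(x, x_hat, code, beta) {
  x <- rbind(x)
  x_hat <- rbind(x_hat)
  if (!all(dim(x) == dim(x_hat))) abort("x and x_hat shapes differ", class = "msvae_shape_error")
  recon <- mean(rowSums((x_hat - x)^2))
  kl <- gaussian_kl(rbind(code$mean), rbind(code$log_variance))
  total <- recon + beta * kl
  if (!is.finite(total)) {
    abort(sprintf("non-finite loss (reconstruction %g, kl %g)", recon, kl),
      class = "msvae_numerical_error"
    )
  }
  list(total = total, reconstruction = recon, kl = kl)
}

#' Capacity schedule for JointVAE
#'
#' Linear ramp from 0 at step 0 to the maximum capacities at
#' `capacity_steps`, constant thereafter.
#'
#' @param step Non-negative training step.
#' @param model A `jointvae` (or any list with `cont_max_capacity`,
#'   `disc_max_capacity`, `capacity_steps`).
#' @return Named numeric vector `c(cont = ..., disc = ...)`.
#' @export
capacity_schedule <- function(step, model) {
  stopifnot(step >= 0)
  frac <- if (model$capacity_steps <= 0L) 1 else min(step / model$capacity_steps, 1)
  c(cont = frac * model$cont_max_capacity, disc = frac * model$disc_max_capacity)
}

#' JointVAE loss
#'
#' `total = reconstruction + cont_gamma * |KL_cont - C_cont(step)| +
#' disc_gamma * |KL_disc - C_disc(step)|`; the discrete KL is measured against
#' the uniform categorical prior and capacities grow linearly with the step.
#'
#' @inheritParams betavae_loss
#' @param model A [jointvae()] model.
#' @param step Training step (drives the capacity schedule).
#' @return Named list: `total`, `reconstruction`, `kl_cont`, `kl_disc`,
#'   `capacity_cont`, `capacity_disc`.
#' @export
jointvae_loss <- function(x, x_hat, code, model, step = 0L) {
  x <- rbind(x)
  x_hat <- rbind(x_hat)
  if (!all(dim(x) == dim(x_hat))) abort("x and x_hat shapes differ", class = "msvae_shape_error")
  recon <- mean(rowSums((x_hat - x)^2))
  kl_cont <- if (model$latent_dim > 0L) {
    gaussian_kl(rbind(code$mean), rbind(code$log_variance))
  } else {
    0
  }
  kl_disc <- if (length(code$discrete_probs %||% list())) {
    sum(vapply(code$discrete_probs, function(p) categorical_kl(rbind(p)), numeric(1)))
  } else {
    0
  }
  cap <- capacity_schedule(step, model)
  total <- recon + model$cont_gamma * abs(kl_cont - cap[["cont"]]) +
    model$disc_gamma * abs(kl_disc - cap[["disc"]])
  if (!is.finite(total)) {
    abort(sprintf(
      "non-finite loss (reconstruction %g, kl_cont %g, kl_disc %g)",
      recon, kl_cont, kl_disc
    ), class = "msvae_numerical_error")
  }
  list(
    total = total, reconstruction = recon, kl_cont = kl_cont, kl_disc = kl_disc,
    capacity_cont = cap[["cont"]], capacity_disc = cap[["disc"]]
  )
}

## ---------------------------------------------------------------------------
## Single training steps (loss + exact gradients). Used by fit_vae();
## separated out so the finite-difference gradient test can call them.

# BetaVAE: returns losses, gradients for encoder/decoder, and nets with
# updated batch-norm running statistics.
betavae_step <- function(model, X, eps = NULL) {
  n <- nrow(X)
  D <- ncol(X)
  L <- model$latent_dim
  ef <- net_forward(model$encoder, X, training = TRUE)
  parts <- split_encoder_output(model, ef$out)
  mu <- parts$mean
  lv <- parts$log_variance
  if (is.null(eps)) eps <- matrix(rnorm(n * L), n, L)
  z <- mu + exp(0.5 * lv) * eps
  df <- net_forward(model$decoder, z, training = TRUE)
  x_hat <- df$out

  recon <- mean(rowSums((x_hat - X)^2))
  kl <- gaussian_kl(mu, lv)
  total <- recon + model$beta * kl

  d_xhat <- 2 * (x_hat - X) / n
  bdec <- net_backward(model$decoder, df$caches, d_xhat)
  dz <- bdec$dX
  d_mu <- dz + model$beta * mu / n
  d_lv <- dz * eps * 0.5 * exp(0.5 * lv) + model$beta * 0.5 * (exp(lv) - 1) / n
  benc <- net_backward(model$encoder, ef$caches, cbind(d_mu, d_lv))

  list(
    losses = list(total = total, reconstruction = recon, kl = kl),
    enc_grads = benc$grads, dec_grads = bdec$grads,
    encoder = ef$net, decoder = df$net
  )
}

# JointVAE: as betavae_step, with Gumbel-softmax discrete blocks and
# capacity-target losses.
jointvae_step <- function(model, X, step, eps = NULL, gumbel = NULL) {
  n <- nrow(X)
  D <- ncol(X)
  L <- model$latent_dim
  sizes <- model$disc_category_sizes
  tau <- model$gumbel_temperature

  ef <- net_forward(model$encoder, X, training = TRUE)
  parts <- split_encoder_output(model, ef$out)
  mu <- parts$mean
  lv <- parts$log_variance
  if (is.null(eps)) eps <- matrix(rnorm(n * L), n, max(L, 1L))
  z_cont <- if (L > 0L) mu + exp(0.5 * lv) * eps else NULL

  alphas <- lapply(parts$disc_logits %||% list(), softmax_rows)
  if (is.null(gumbel) && length(sizes)) {
    gumbel <- lapply(sizes, function(k) {
      -log(-log(matrix(runif(n * k), n, k)))
    })
  }
  ys <- Map(function(logits, g) softmax_rows((logits + g) / tau),
    parts$disc_logits %||% list(), gumbel %||% list()
  )
  z <- do.call(cbind, c(list(z_cont), ys))
  df <- net_forward(model$decoder, z, training = TRUE)
  x_hat <- df$out

  recon <- mean(rowSums((x_hat - X)^2))
  kl_cont <- if (L > 0L) gaussian_kl(mu, lv) else 0
  kl_disc <- if (length(alphas)) sum(vapply(alphas, categorical_kl, numeric(1))) else 0
  cap <- capacity_schedule(step, model)
  total <- recon + model$cont_gamma * abs(kl_cont - cap[["cont"]]) +
    model$disc_gamma * abs(kl_disc - cap[["disc"]])

  d_xhat <- 2 * (x_hat - X) / n
  bdec <- net_backward(model$decoder, df$caches, d_xhat)
  dz <- bdec$dX

  s_cont <- model$cont_gamma * sign(kl_cont - cap[["cont"]])
  s_disc <- model$disc_gamma * sign(kl_disc - cap[["disc"]])
  d_enc_parts <- list()
  if (L > 0L) {
    dzc <- dz[, seq_len(L), drop = FALSE]
    d_mu <- dzc + s_cont * mu / n
    d_lv <- dzc * eps * 0.5 * exp(0.5 * lv) + s_cont * 0.5 * (exp(lv) - 1) / n
    d_enc_parts <- list(d_mu, d_lv)
  }
  pos <- L
  for (b in seq_along(sizes)) {
    k <- sizes[b]
    dy <- dz[, pos + seq_len(k), drop = FALSE]
    pos <- pos + k
    y <- ys[[b]]
    # softmax Jacobian through the relaxation, then the KL path through alpha
    d_logits <- y * (dy - rowSums(dy * y)) / tau
    a <- pmax(alphas[[b]], 1e-12)
    loga <- log(a)
    d_logits <- d_logits + s_disc * a * (loga - rowSums(a * loga)) / n
    d_enc_parts[[length(d_enc_parts) + 1L]] <- d_logits
  }
  benc <- net_backward(model$encoder, ef$caches, do.call(cbind, d_enc_parts))

  list(
    losses = list(
      total = total, reconstruction = recon, kl_cont = kl_cont,
      kl_disc = kl_disc, capacity_cont = cap[["cont"]], capacity_disc = cap[["disc"]]
    ),
    enc_grads = benc$grads, dec_grads = bdec$grads,
    encoder = ef$net, decoder = df$net
  )
}

#' @export
print.msvae_model <- function(x, ...) {
  kind <- if (inherits(x, "jointvae")) "JointVAE" else "BetaVAE"
  cat(sprintf(
    "<%s> input %d, latent %d%s, encoder %s, trained %d epochs\n",
    kind, x$input_dim, x$latent_dim,
    if (length(x$disc_category_sizes %||% integer())) {
      sprintf(" + discrete (%s)", paste(x$disc_category_sizes, collapse = ","))
    } else {
      ""
    },
    paste(x$encoder$sizes, collapse = "-"), x$trained_epochs
  ))
  invisible(x)
}
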