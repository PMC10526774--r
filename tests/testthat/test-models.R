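# Network construction, VAE losses, gradients, and training behavior.

test_that("decoder outputs are always squashed into (0,1) and shapes are contractual", {
  m <- betavae(input_dim = 8, latent_dim = 2, beta = 0.5, hidden = c(6), seed = 1)
  z <- matrix(rnorm(20 * 2, sd = 5), 20, 2)
  out <- decode(m, z)
  expect_equal(dim(out), c(20L, 8L))
  expect_true(all(out > 0 & out < 1))
  expect_true(all(decode(m, numeric(2)) > 0 & decode(m, numeric(2)) < 1))
  expect_error(decode(m, matrix(0, 1, 3)), class = "msvae_shape_error")
  expect_error(encode(m, numeric(5)), class = "msvae_shape_error")
})

test_that("the depth-0 model is a single affine map and forward passes are deterministic", {
  m <- betavae(input_dim = 6, latent_dim = 2, hidden = integer(), seed = 2)
  expect_length(m$encoder$blocks, 1)
  expect_equal(m$encoder$blocks[[1]]$type, "dense")
  x <- matrix(runif(12), 2, 6)
  c1 <- encode(m, x)
  c2 <- encode(m, x)
  expect_identical(c1$mean, c2$mean)
  # the affine identity holds exactly
  W <- m$encoder$blocks[[1]]$W
  b <- m$encoder$blocks[[1]]$b
  expect_equal(cbind(c1$mean, c1$log_variance),
    x %*% W + matrix(b, 2, 4, byrow = TRUE),
    tolerance = 1e-12
  )
})

test_that("betavae_loss matches its closed forms", {
  x <- c(0.2, 0.4, 0.6, 0.8)
  code0 <- list(mean = matrix(0, 1, 2), log_variance = matrix(0, 1, 2))
  l0 <- betavae_loss(x, x, code0, beta = 1)
  expect_equal(l0$reconstruction, 0)
  expect_equal(l0$kl, 0)
  expect_equal(l0$total, 0)

  # unit variance, mean mu, 1-D: KL = mu^2 / 2
  mu <- 1.7
  code1 <- list(mean = matrix(mu, 1, 1), log_variance = matrix(0, 1, 1))
  expect_equal(betavae_loss(x, x, code1, beta = 2)$kl, mu^2 / 2)
  expect_equal(betavae_loss(x, x, code1, beta = 2)$total, 2 * mu^2 / 2)

  # additivity of the terms on a nontrivial case
  xh <- x + 0.1
  l <- betavae_loss(x, xh, code1, beta = 0.3)
  expect_equal(l$total, l$reconstruction + 0.3 * l$kl)
  expect_gte(l$kl, 0)
  expect_gte(l$reconstruction, 0)
  expect_error(betavae_loss(x, xh[1:3], code1, 1), class = "msvae_shape_error")
})

test_that("jointvae_loss handles the categorical KL closed forms and capacities", {
  m <- jointvae(4, cont_latent_dim = 1, disc_category_sizes = 3,
                cont_gamma = 1, disc_gamma = 1, cont_max_capacity = 2,
                disc_max_capacity = 1, capacity_steps = 10, seed = 1)
  x <- runif(4)
  code_u <- list(
    mean = matrix(0, 1, 1), log_variance = matrix(0, 1, 1),
    discrete_probs = list(matrix(1 / 3, 1, 3))
  )
  l <- jointvae_loss(x, x, code_u, m, step = 0)
  expect_equal(l$kl_disc, 0)
  expect_equal(l$kl_cont, 0)
  # step 0, zero capacity, matched KL: the capacity terms vanish
  expect_equal(l$total, 0)

  # deterministic one-hot block: KL = log 3
  code_d <- code_u
  code_d$discrete_probs <- list(matrix(c(1, 0, 0), 1, 3))
  expect_equal(jointvae_loss(x, x, code_d, m, step = 0)$kl_disc, log(3), tolerance = 1e-9)
})

test_that("capacity_schedule ramps linearly from zero to the maxima", {
  m <- jointvae(4, 1, 3, cont_max_capacity = 6, disc_max_capacity = 2,
                capacity_steps = 100, seed = 1)
  expect_equal(capacity_schedule(0, m), c(cont = 0, disc = 0))
  expect_equal(capacity_schedule(50, m), c(cont = 3, disc = 1))
  expect_equal(capacity_schedule(100, m), c(cont = 6, disc = 2))
  expect_equal(capacity_schedule(5000, m), c(cont = 6, disc = 2))
  steps <- vapply(0:120, function(s) capacity_schedule(s, m)[["cont"]], numeric(1))
  expect_true(all(diff(steps) >= 0))
})

test_that("analytic gradients agree with finite differences on a 4-cell toy input", {
  set.seed(42)
  X <- matrix(runif(3 * 4), 3, 4)
  h <- 1e-6

  m <- betavae(4, latent_dim = 2, beta = 0.7, hidden = c(5), seed = 9)
  eps <- matrix(rnorm(3 * 2), 3, 2)
  res <- msvae:::betavae_step(m, X, eps = eps)
  analytic <- c(
    msvae:::grads_to_vector(m$encoder, res$enc_grads),
    msvae:::grads_to_vector(m$decoder, res$dec_grads)
  )
  n_enc <- length(msvae:::net_get_params(m$encoder))
  loss_at <- function(theta) {
    m2 <- m
    m2$encoder <- msvae:::net_set_params(m$encoder, theta[seq_len(n_enc)])
    m2$decoder <- msvae:::net_set_params(m$decoder, theta[-seq_len(n_enc)])
    msvae:::betavae_step(m2, X, eps = eps)$losses$total
  }
  theta0 <- c(msvae:::net_get_params(m$encoder), msvae:::net_get_params(m$decoder))
  numeric_grad <- vapply(seq_along(theta0), function(i) {
    tp <- theta0
    tp[i] <- tp[i] + h
    tm <- theta0
    tm[i] <- tm[i] - h
    (loss_at(tp) - loss_at(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(analytic - numeric_grad)), 1e-4)

  mj <- jointvae(4, cont_latent_dim = 2, disc_category_sizes = 3, cont_gamma = 2,
                 disc_gamma = 3, cont_max_capacity = 1, disc_max_capacity = 0.5,
                 capacity_steps = 10, hidden = c(5), seed = 9)
  epsj <- matrix(rnorm(3 * 2), 3, 2)
  gum <- list(-log(-log(matrix(runif(9), 3, 3))))
  resj <- msvae:::jointvae_step(mj, X, step = 4, eps = epsj, gumbel = gum)
  analytic_j <- c(
    msvae:::grads_to_vector(mj$encoder, resj$enc_grads),
    msvae:::grads_to_vector(mj$decoder, resj$dec_grads)
  )
  n_enc_j <- length(msvae:::net_get_params(mj$encoder))
  loss_j <- function(theta) {
    m2 <- mj
    m2$encoder <- msvae:::net_set_params(mj$encoder, theta[seq_len(n_enc_j)])
    m2$decoder <- msvae:::net_set_params(mj$decoder, theta[-seq_len(n_enc_j)])
    msvae:::jointvae_step(m2, X, step = 4, eps = epsj, gumbel = gum)$losses$total
  }
  t0 <- c(msvae:::net_get_params(mj$encoder), msvae:::net_get_params(mj$decoder))
  numeric_j <- vapply(seq_along(t0), function(i) {
    tp <- t0
    tp[i] <- tp[i] + h
    tm <- t0
    tm[i] <- tm[i] - h
    (loss_j(tp) - loss_j(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(analytic_j - numeric_j)), 1e-4)
})

test_that("a wide model memorizes a single repeated spectrum (overfit sanity)", {
  set.seed(2)
  x <- runif(20)
  X <- matrix(rep(x, 50), 50, byrow = TRUE)
  m <- betavae(20, latent_dim = 3, beta = 0.01, hidden = c(64), seed = 3)
  m <- fit_vae(m, X, train_config(epochs = 200, learning_rate = 0.01, seed = 5))
  # reconstruction is summed squared error over 20 cells
  expect_lt(tail(m$history$reconstruction, 1), 1e-3 * 20)
  expect_lt(mean((decode(m, encode(m, x)$mean) - x)^2), 1e-3)
})

test_that("training histories are fully reproducible under a seed", {
  setup <- small_training_setup(n_compounds = 20)
  m0 <- betavae(ncol(setup$prep$vectors), latent_dim = 2, beta = 0.1, hidden = c(16), seed = 7)
  cfg <- train_config(epochs = 3, seed = 99)
  h1 <- fit_vae(m0, setup$prep$vectors, cfg)$history
  h2 <- fit_vae(m0, setup$prep$vectors, cfg)$history
  expect_identical(h1, h2)
  expect_named(h1, c("epoch", "total", "reconstruction", "kl"))
})

test_that("the weighted sampler balances a 9:1 binary factor at the batch level", {
  labels <- rep(c("major", "minor"), c(180, 20))
  cfg <- train_config(batch_size = 50, sampler = "weighted_by_class", seed = 3)
  shares <- withr::with_seed(17, {
    vapply(1:100, function(i) {
      batches <- msvae:::epoch_batches(200, cfg, labels)
      mean(labels[batches[[1]]] == "minor")
    }, numeric(1))
  })
  expect_lt(abs(mean(shares) - 0.5), 0.1)
})

test_that("jointvae training runs and its capacities rise along the schedule", {
  setup <- small_training_setup(n_compounds = 20)
  m <- jointvae(ncol(setup$prep$vectors), cont_latent_dim = 2,
                disc_category_sizes = 2, cont_gamma = 5, disc_gamma = 5,
                cont_max_capacity = 3, disc_max_capacity = 0.5,
                capacity_steps = 20, hidden = c(16), seed = 7)
  m <- fit_vae(m, setup$prep$vectors, train_config(epochs = 4, seed = 1))
  h <- m$history
  expect_true(all(diff(h$capacity_cont) >= 0))
  expect_true(all(is.finite(h$total)))
  code <- encode(m, setup$prep$vectors[1:5, ])
  expect_length(code$discrete_probs, 1)
  expect_equal(unname(rowSums(code$discrete_probs[[1]])), rep(1, 5), tolerance = 1e-9)
  # one-hot evaluation sample appended to the continuous block
  expect_equal(ncol(code$sample), 2 + 2)
})

test_that("joint training adds the head objective and learns a decodable factor", {
  setup <- small_training_setup(n_compounds = 50, seed = 19)
  prep <- setup$prep
  target <- ifelse(prep$factors[, "ionization_mode"] == 1, "positive", "negative")
  # the head sees the latent code plus the remaining factors; ionization mode
  # is decodable by construction from precursor type / precursor m/z vs mass
  side <- prep$factors[, c("precursor_type", "precursor_mz", "total_exact_mass")]
  m <- betavae(ncol(prep$vectors), latent_dim = 3, beta = 0.05, hidden = c(48), seed = 7)
  jt <- joint_train(m, prep$vectors, target,
    side_features = side, task = "classify",
    cfg = train_config(epochs = 25, learning_rate = 3e-3, seed = 13)
  )
  # the logged summed loss is exactly the VAE total plus the head loss
  expect_equal(jt$history$summed_total, jt$history$total + jt$history$head,
    tolerance = 1e-12
  )
  # ionization mode is decodable by construction: held-out accuracy is high
  idx <- msvae:::holdout_split(target, "classify", seed = 21)
  test_idx <- setdiff(seq_along(target), idx)
  z <- encode(jt$model, prep$vectors[test_idx, ])$mean
  pred <- predict(jt$head, cbind(z, side[test_idx, , drop = FALSE]))
  bacc <- msvae:::classification_metrics(
    target[test_idx], pred, sort(unique(target))
  )$balanced_accuracy
  expect_gt(bacc, 0.9)
  # degenerate single-class target refuses
  expect_error(
    joint_train(m, prep$vectors, rep("positive", nrow(prep$vectors)), task = "classify"),
    class = "msvae_config_error"
  )
})

test_that("raising beta degrades reconstruction cosine (trade-off trend)", {
  setup <- small_training_setup(n_compounds = 40, seed = 23)
  betas <- c(0.01, 0.1, 0.5, 1, 2)
  mean_cos <- vapply(betas, function(b) {
    cos_by_seed <- vapply(1:3, function(s) {
      m <- betavae(ncol(setup$prep$vectors), latent_dim = 3, beta = b,
                   hidden = c(32), seed = s)
      m <- fit_vae(m, setup$prep$vectors,
                   train_config(epochs = 8, learning_rate = 3e-3, seed = 100 + s))
      mean(reconstruction_report(m, setup$prep$vectors)$per_sample$cos_sim)
    }, numeric(1))
    mean(cos_by_seed)
  }, numeric(1))
  expect_lte(cor(betas, mean_cos, method = "spearman"), 0)
})
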