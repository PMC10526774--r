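# Task inputs, predictor metrics, permutation feature importance, and
# factor cross-correlation.

test_that("build_task_inputs assembles spectrum- and latent-mode matrices", {
  setup <- small_training_setup(n_compounds = 15, seed = 3)
  prep <- setup$prep
  inp <- build_task_inputs(prep$vectors, prep$factors, "ionization_mode")
  n_side <- ncol(prep$factors) - 1L
  expect_equal(ncol(inp$x), ncol(prep$vectors) + n_side)
  expect_named(inp$groups[1], "spectrum")
  expect_length(inp$groups, n_side + 1L)

  m <- betavae(ncol(prep$vectors), latent_dim = 3, hidden = c(8), seed = 1)
  lat <- build_task_inputs(prep$vectors, prep$factors, "ionization_mode",
    input_mode = "latent", model = m
  )
  expect_equal(ncol(lat$x), 3L + n_side)
  expect_lt(ncol(lat$x), ncol(inp$x))
  expect_error(
    build_task_inputs(prep$vectors, prep$factors, "ionization_mode",
      input_mode = "latent"
    ),
    class = "msvae_config_error"
  )
  expect_error(
    build_task_inputs(prep$vectors, prep$factors, "ionization_mode",
      included_factors = "ionization_mode"
    ),
    class = "msvae_config_error"
  )
  # determinism
  inp2 <- build_task_inputs(prep$vectors, prep$factors, "ionization_mode")
  expect_identical(inp$x, inp2$x)
})

test_that("rows with missing included factors are dropped, not imputed", {
  setup <- small_training_setup(n_compounds = 10, seed = 5)
  f <- setup$prep$factors
  f[3, "collision_energy"] <- NA
  inp <- build_task_inputs(setup$prep$vectors, f, "ionization_mode")
  expect_equal(inp$n_dropped, 1L)
  expect_false(3L %in% inp$kept)
})

test_that("a leaked target column yields perfect balanced accuracy", {
  set.seed(21)
  y <- rep(c("a", "b"), each = 50)
  x <- cbind(leak = as.numeric(y == "a"), noise = rnorm(100))
  fit <- fit_predictor(x, y, "classify", hidden = c(8),
                       cfg = train_config(epochs = 150, learning_rate = 1e-2, seed = 2))
  expect_equal(fit$metrics$balanced_accuracy, 1)
})

test_that("regression on a nearly noise-free linear law reaches r2 near 1", {
  set.seed(22)
  x <- matrix(runif(300), 300, 1)
  y <- 2 * x[, 1] + rnorm(300, sd = 1e-3)
  fit <- fit_predictor(x, y, "regress", hidden = c(16),
                       cfg = train_config(epochs = 60, learning_rate = 3e-3, seed = 2))
  expect_gt(fit$metrics$r2, 0.98)
  expect_named(fit$metrics, c("mse", "rmse", "mae", "r2", "explained_variance"))
})

test_that("label-permuted targets score at chance level", {
  set.seed(23)
  x <- matrix(rnorm(400), 200, 2)
  y <- rep(c("a", "b"), 100)
  accs <- vapply(1:5, function(s) {
    yy <- withr::with_seed(s, sample(y))
    fit_predictor(x, yy, "classify", hidden = c(4),
                  cfg = train_config(epochs = 15, seed = s))$metrics$balanced_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("single-class targets and tiny datasets are refused", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(fit_predictor(x, rep("a", 20), "classify"), class = "msvae_config_error")
  expect_error(fit_predictor(x[1:5, ], rep(c("a", "b"), c(2, 3))[1:5], "classify"),
    class = "msvae_config_error"
  )
})

test_that("permutation feature importance satisfies its oracles", {
  set.seed(31)
  n <- 400
  a <- rnorm(n)
  b <- rnorm(n)
  y <- 3 * a + rnorm(n, sd = 0.05)
  x <- cbind(a = a, b = b)
  fit <- fit_predictor(x, y, "regress", hidden = c(16),
                       cfg = train_config(epochs = 60, learning_rate = 3e-3, seed = 7))
  ho <- fit$split$test
  pfi <- permutation_feature_importance(
    fit$predictor, x[ho, ], y[ho],
    metric = "mse", repeats = 20, seed = 9
  )
  imp <- setNames(pfi$importance, pfi$feature)
  # the informative feature dominates; the null feature sits at zero
  expect_gt(imp[["a"]], 10 * abs(imp[["b"]]))
  expect_lt(abs(imp[["b"]]), 0.02 * imp[["a"]])

  # unused feature on an accuracy metric: |importance| < 0.02
  yclass <- ifelse(a > 0, "pos", "neg")
  xc <- cbind(a = a, null = b)
  fitc <- fit_predictor(xc, yclass, "classify", hidden = c(8),
                        cfg = train_config(epochs = 30, seed = 11))
  pfic <- permutation_feature_importance(
    fitc$predictor, xc[fitc$split$test, ], yclass[fitc$split$test],
    metric = "accuracy", repeats = 20, seed = 13
  )
  expect_lt(abs(pfic$importance[pfic$feature == "null"]), 0.02)

  expect_error(
    permutation_feature_importance(fitc$predictor, xc, yclass, repeats = 0),
    class = "msvae_config_error"
  )
})

test_that("PFI is invariant to duplicating an irrelevant feature", {
  set.seed(33)
  n <- 300
  a <- rnorm(n)
  irr <- rnorm(n)
  y <- ifelse(a > 0, "p", "n")
  x1 <- cbind(a = a, irr = irr)
  x2 <- cbind(a = a, irr = irr, irr2 = irr)
  f1 <- fit_predictor(x1, y, "classify", hidden = c(8),
                      cfg = train_config(epochs = 100, learning_rate = 3e-3, seed = 3))
  f2 <- fit_predictor(x2, y, "classify", hidden = c(8),
                      cfg = train_config(epochs = 100, learning_rate = 3e-3, seed = 3))
  p1 <- permutation_feature_importance(f1$predictor, x1[f1$split$test, ],
    y[f1$split$test], metric = "accuracy", repeats = 20, seed = 5)
  p2 <- permutation_feature_importance(f2$predictor, x2[f2$split$test, ],
    y[f2$split$test], metric = "accuracy", repeats = 20, seed = 5)
  i1 <- p1$importance[p1$feature == "a"]
  i2 <- p2$importance[p2$feature == "a"]
  expect_lt(abs(i1 - i2), 0.05)
})

test_that("factor cross-correlation recovers the affine mass/precursor relation", {
  cfg <- generator_config(n_compounds = 300, design = "mona_like", seed = 51)
  ds <- generate_dataset(cfg)
  enc <- encode_factors(ds)
  cc <- cross_correlate_factors(enc)
  expect_equal(diag(cc), rep(1, ncol(cc)), ignore_attr = TRUE)
  expect_equal(cc, t(cc))
  # precursor_mz = total_exact_mass +/- one proton: near-perfect correlation
  expect_gt(cc["total_exact_mass", "precursor_mz"], 0.99)
})

test_that("independent simulated factors have near-zero cross-correlation", {
  set.seed(61)
  f <- cbind(a = rnorm(2000), b = sample(0:4, 2000, TRUE), c = runif(2000))
  cc <- cross_correlate_factors(f)
  off <- cc[upper.tri(cc)]
  expect_true(all(abs(off) < 0.08))

  # zero-variance factors are flagged as undefined, not errors
  f2 <- cbind(f, const = 1)
  cc2 <- cross_correlate_factors(f2)
  expect_true("const" %in% attr(cc2, "undefined"))
})
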