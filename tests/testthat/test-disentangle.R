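# Disentanglement scores, the two-step correlation analysis, greedy
# assignment, and the variance-explained regression.

# independent factor sampler shared by the metric tests: one discrete factor
# per column, drawn uniformly from a small code set
uniform_factor_sampler <- function(n_factors = 3, n_levels = 5) {
  function(n) {
    matrix(sample.int(n_levels, n * n_factors, replace = TRUE) - 1L, n, n_factors)
  }
}

test_that("axis-aligned copy representations score as fully disentangled", {
  sampler <- uniform_factor_sampler(3)
  copy_rep <- function(f) f
  b <- betavae_score(copy_rep, sampler, n_points = 300, pair_batch = 32, seed = 1)
  expect_gte(b$value, 0.95)
  f <- factorvae_score(copy_rep, sampler, n_votes = 300, vote_batch = 32, seed = 1)
  expect_gte(f$value, 0.95)
})

test_that("noise representations score at chance over 5 seeds", {
  sampler <- uniform_factor_sampler(3)
  noise_rep <- function(f) matrix(rnorm(nrow(f) * 3), nrow(f), 3)
  b_vals <- vapply(1:5, function(s) {
    betavae_score(noise_rep, sampler, n_points = 300, pair_batch = 16, seed = s)$value
  }, numeric(1))
  expect_lt(abs(mean(b_vals) - 1 / 3), 0.1)
  f_vals <- vapply(1:5, function(s) {
    factorvae_score(noise_rep, sampler, n_votes = 300, vote_batch = 16, seed = s)$value
  }, numeric(1))
  expect_lt(abs(mean(f_vals) - 1 / 3), 0.1)
})

test_that("the classifier metrics refuse degenerate protocols", {
  one_factor <- function(n) matrix(sample(0:4, n, TRUE), n, 1)
  expect_error(betavae_score(function(f) f, one_factor),
    class = "msvae_protocol_error"
  )
  # a representation with every dimension constant cannot vote
  sampler <- uniform_factor_sampler(2)
  const_rep <- function(f) matrix(0, nrow(f), 2)
  expect_error(factorvae_score(const_rep, sampler),
    class = "msvae_degenerate_representation"
  )
})

test_that("a collapsed latent dimension is pruned and never votes", {
  sampler <- uniform_factor_sampler(2)
  rep_fn <- function(f) cbind(f, 0.7) # third dimension constant
  s <- factorvae_score(rep_fn, sampler, n_votes = 200, vote_batch = 32, seed = 2)
  expect_equal(s$protocol$pruned_dims, 3L)
  expect_gte(s$value, 0.95)
})

test_that("MIG hits its exact constructions on fully crossed designs", {
  # full factorial so empirical marginals are exactly independent
  g <- expand.grid(f1 = 0:4, f2 = 0:4, f3 = 0:4)
  f <- as.matrix(g[rep(seq_len(nrow(g)), 4), ])
  # copy representation: z_j = f_j exactly -> MIG = 1
  expect_equal(mig_score(f, f)$value, 1, tolerance = 1e-6)

  # duplicated factor: top-two mutual informations tie -> MIG = 0 for that
  # factor; with a single factor under audit the score is exactly 0
  z_dup <- cbind(f[, 1], f[, 1])
  expect_equal(mig_score(z_dup, f[, 1, drop = FALSE])$value, 0, tolerance = 1e-12)

  # zero-entropy factors are excluded and flagged
  fz <- cbind(f[, 1:2], const = 0)
  s <- mig_score(cbind(f[, 1:2], rnorm(nrow(f))), fz)
  expect_true("const" %in% s$protocol$excluded_factors)
})

test_that("the empirical MI inside MIG matches an exhaustive-sum oracle", {
  # hand-built 2x2 joint, fully enumerated
  counts <- matrix(c(30, 10, 5, 55), 2, 2)
  a <- rep(rep(1:2, each = 2), times = as.vector(t(counts)))
  b <- rep(rep(1:2, times = 2), times = as.vector(t(counts)))
  p <- counts / sum(counts)
  oracle <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      pij <- p[i, j]
      oracle <- oracle + pij * log(pij / (sum(p[i, ]) * sum(p[, j])))
    }
  }
  expect_equal(msvae:::discrete_mi(
    rep(1:2, times = rowSums(counts))[order(order(a))] * 0 + a, b
  ), oracle, tolerance = 1e-9)
  # entropy oracle
  expect_equal(msvae:::discrete_entropy(a),
    -sum(rowSums(p) * log(rowSums(p))),
    tolerance = 1e-12
  )
})

test_that("all metric scores lie in [0,1] and survive latent permutation", {
  sampler <- uniform_factor_sampler(3)
  perm_rep <- function(f) f[, c(3, 1, 2)]
  for (fn in list(
    function(s) betavae_score(perm_rep, sampler, n_points = 200, pair_batch = 16, seed = s)$value,
    function(s) factorvae_score(perm_rep, sampler, n_votes = 200, vote_batch = 16, seed = s)$value
  )) {
    v <- fn(1)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_gte(v, 0.9) # permuting latent order must not hurt the score
  }
  f <- sampler(2000)
  expect_gte(mig_score(f[, c(2, 3, 1)], f)$value, 0.9)
})

test_that("build_partitions enumerates the hand-counted example", {
  f <- cbind(
    A = rep(c(0, 1), each = 20),
    B = rep(seq(0, 9.5, 0.5), 2)
  )
  spec <- partition_spec(
    A = c(0, 1),
    B = list(low = 0, high = 10, step = 5),
    min_size = 5
  )
  parts <- build_partitions(f, spec)
  # varying A: one partition per B-bin (2); varying B: one per A label (2)
  expect_equal(nrow(parts), 4)
  expect_equal(sum(parts$varying_factor == "A"), 2)
  expect_equal(sum(parts$varying_factor == "B"), 2)
  expect_equal(attr(parts, "n_dropped"), 0)

  expect_error(
    build_partitions(f, partition_spec(
      A = c(0, 1), B = list(low = 0, high = 10, step = 5), min_size = 500
    )),
    class = "msvae_empty_analysis"
  )
})

test_that("partition correlations handle exact, noisy, and degenerate cases", {
  set.seed(3)
  f <- runif(30, 0, 10)
  latent <- cbind(f, -2 * f + rnorm(30, sd = 0.01), 5)
  cells <- partition_correlations(1:30, f, latent, factor_name = "f")
  expect_equal(cells$r[1], 1, tolerance = 1e-12)
  expect_lte(cells$r[2], -0.99)
  expect_false(cells$defined[3]) # constant latent flagged, not an error
})

test_that("aggregate_correlations summarizes distributions honestly", {
  cells <- tibble::tibble(
    factor = "f", latent_index = 1L,
    r = c(0.5, 0.5, 0.5), p_value = 0.01, partition_id = 1:3, n = 10, defined = TRUE
  )
  s <- aggregate_correlations(cells)
  expect_equal(s$mean_r, 0.5)
  expect_equal(s$sd_r, 0)

  # cancellation is surfaced: mean 0 with large spread
  cells2 <- cells
  cells2$r <- c(0.9, -0.9, 0)
  cells2 <- cells2[1:2, ]
  s2 <- aggregate_correlations(cells2)
  expect_equal(s2$mean_r, 0)
  expect_equal(s2$sd_r, 0.9)
})

test_that("assign_factors reproduces the published worked example exactly", {
  mean_r <- matrix(
    c(
      -0.12, -0.31, 0.49,
      -0.18, -0.04, -0.02,
      -0.10, 0.24, -0.12
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(
      c("Z1", "Z2", "Z3"),
      c("total_exact_mass", "collision_energy", "instrument_type")
    )
  )
  res <- assign_factors(mean_r)
  mapping <- setNames(res$mapping$latent_index, res$mapping$factor)
  expect_equal(mapping[["instrument_type"]], 1L)
  expect_equal(mapping[["total_exact_mass"]], 2L)
  expect_equal(mapping[["collision_energy"]], 3L)
})

test_that("assign_factors handles identity, ties, and partial tables", {
  ident <- diag(3)
  colnames(ident) <- c("a", "b", "c")
  res <- assign_factors(ident)
  expect_equal(res$mapping$latent_index, 1:3)
  expect_true(res$distinct)

  flat <- matrix(0.3, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  res_flat <- assign_factors(flat)
  expect_equal(sort(res_flat$mapping$latent_index), 1:3) # tie-broken, injective
  expect_false(res_flat$distinct)

  short <- matrix(c(0.9, 0.1, 0.2, 0.8), 1, 4,
    dimnames = list("Z1", c("a", "b", "c", "d"))
  )
  expect_warning(res_short <- assign_factors(short), "partial")
  expect_false(res_short$complete)
  expect_equal(nrow(res_short$mapping), 1)
})

test_that("the two-step analysis recovers a signed permutation in 10/10 seeds", {
  n <- 1200
  spec <- partition_spec(
    mass = list(low = 200, high = 500, step = 50),
    energy = list(low = 10, high = 55, step = 5),
    instrument = 0:4,
    min_size = 10
  )
  recovered <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      f <- cbind(
        mass = runif(n, 200, 500),
        energy = sample(seq(10, 50, 5), n, TRUE),
        instrument = sample(0:4, n, TRUE)
      )
      perm <- sample(3)
      signs <- sample(c(-1, 1), 3, TRUE)
      A <- matrix(0, 3, 3)
      A[cbind(seq_len(3), perm)] <- signs
      # scale factors to unit-ish variance so the noise SD is meaningful
      fs <- scale(f)
      z <- fs %*% t(A) + matrix(rnorm(3 * n, sd = 0.05), n, 3)
      res <- two_step_correlation(f, z, spec)
      m <- abs(attr(res$summary, "mean_r_matrix"))
      diag_ok <- TRUE
      for (k in seq_len(3)) {
        # latent row carrying factor k is z_j with A[j, k] != 0
        j <- which(A[, k] != 0)
        diag_ok <- diag_ok && m[j, colnames(f)[k]] > 0.9 &&
          all(m[-j, colnames(f)[k]] < 0.2)
      }
      got <- setNames(res$assignment$mapping$latent_index, res$assignment$mapping$factor)
      match_ok <- all(got[colnames(f)] == apply(A != 0, 2, which))
      diag_ok && match_ok && res$assignment$distinct
    })
  }, logical(1))
  expect_equal(sum(recovered), 10L)
})

test_that("variance-explained regression matches its OLS properties", {
  set.seed(71)
  tbl <- data.frame(
    beta = rep(c(0.01, 0.1, 1), each = 40),
    n_peaks = rep(rep(c(10, 50), each = 20), 3),
    arch = rep(c("m1", "m2"), 60)
  )
  # score an exact linear function of beta
  tbl$score <- 2 * tbl$beta + 1
  r <- variance_explained_by_hyperparameters(tbl, "score", list("beta"))
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  # pure noise: every single-parameter subset explains almost nothing
  tbl$score <- rnorm(nrow(tbl))
  r2 <- variance_explained_by_hyperparameters(
    tbl, "score", list("beta", "n_peaks", "arch")
  )
  expect_true(all(r2$r_squared < 0.05))

  # nested subsets are monotone in R^2
  tbl$score <- 2 * tbl$beta + 0.01 * tbl$n_peaks + rnorm(nrow(tbl), sd = 0.1)
  r3 <- variance_explained_by_hyperparameters(
    tbl, "score",
    list("beta", c("beta", "n_peaks"), c("beta", "n_peaks", "arch"))
  )
  expect_true(all(diff(r3$r_squared) >= -1e-12))
})
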