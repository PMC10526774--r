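# Latent-space traversal grids, spherical interpolation, interpolant
# matching against a spectral database, and a 2D principal-component
# projection of latent codes.

#' Decode a 2D latent traversal grid
#'
#' Lattice points are sampled evenly over a plane spanned by two latent
#' dimensions while all remaining dimensions are held fixed, then decoded in
#' row-major order (the first axis varies slowest).
#'
#' @param model A trained [betavae()].
#' @param dims Pair of distinct 1-based latent indices spanning the plane.
#' @param ranges Numeric `2 x 2` matrix (or list of two length-2 vectors):
#'   per-axis (low, high).
#' @param steps Pair of step counts (>= 1 each).
#' @param fixed Values for the remaining latent dimensions (length
#'   `latent_dim`; entries at `dims` are ignored). Default 0.
#' @return A tibble with one row per lattice point: `i`, `j` (grid indices),
#'   the two latent coordinates `u`, `v`, and a `decoded` list-column of
#'   spectrum vectors.
#' @export
traversal_grid <- function(model, dims = c(1L, 2L), ranges = list(c(-3, 3), c(-3, 3)),
                           steps = c(5L, 5L), fixed = NULL) {
  if (length(dims) != 2L || dims[1] == dims[2]) abort("dims must be two distinct indices")
  if (any(dims < 1L | dims > model$latent_dim)) {
    abort("plane index outside the latent dimension", class = "msvae_config_error")
  }
  if (is.matrix(ranges)) ranges <- list(ranges[1, ], ranges[2, ])
  fixed <- fixed %||% numeric(model$latent_dim)
  stopifnot(length(fixed) == model$latent_dim, all(steps >= 1L))
  us <- seq(ranges[[1]][1], ranges[[1]][2], length.out = steps[1])
  vs <- seq(ranges[[2]][1], ranges[[2]][2], length.out = steps[2])
  grid <- expand.grid(j = seq_len(steps[2]), i = seq_len(steps[1]))[, c("i", "j")]
  Z <- matrix(rep(fixed, each = nrow(grid)), nrow(grid), model$latent_dim)
  Z[, dims[1]] <- us[grid$i]
  Z[, dims[2]] <- vs[grid$j]
  decoded <- decode(model, Z)
  tibble(
    i = grid$i, j = grid$j, u = us[grid$i], v = vs[grid$j],
    decoded = lapply(seq_len(nrow(decoded)), function(r) decoded[r, ])
  )
}

#' Spherical linear interpolation between two latent points
#'
#' Follows the great-circle arc
#' `slerp(p, q, t) = (sin((1 - t) * omega) * p + sin(t * omega) * q) / sin(omega)`
#' with `omega` the angle between `p` and `q`, falling back to linear
#' interpolation when the angle is below 1e-6.
#'
#' @param p,q Nonzero latent vectors of equal length.
#' @param t Interpolation parameter(s) in `[0, 1]`.
#' @return A matrix with one row per value of `t` (a vector if `length(t) == 1`).
#' @export
slerp <- function(p, q, t) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != length(q)) abort("p and q differ in length", class = "msvae_shape_error")
  np <- sqrt(sum(p^2))
  nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) abort("slerp is undefined for zero vectors")
  omega <- acos(pmin(pmax(sum(p * q) / (np * nq), -1), 1))
  out <- if (omega < 1e-6) {
    vapply(t, function(ti) (1 - ti) * p + ti * q, numeric(length(p)))
  } else {
    vapply(t, function(ti) {
      (sin((1 - ti) * omega) * p + sin(ti * omega) * q) / sin(omega)
    }, numeric(length(p)))
  }
  if (length(t) == 1L) as.numeric(out) else t(out)
}

#' Interpolate between two spectra and match interpolants against a database
#'
#' The two spectra are encoded to their posterior means, `n_interpolants`
#' points (endpoints included) are sampled along the slerp arc, decoded, and
#' each decoded interpolant is compared against every database entry; the
#' best match under the metric is reported.
#'
#' @param model A trained [betavae()].
#' @param a,b Spectrum vectors (endpoints).
#' @param database Numeric matrix of spectrum vectors to match against.
#' @param n_interpolants Number of points along the arc (>= 2).
#' @inheritParams similarity
#' @return A tibble with one row per interpolant: `t`, `latent` and `decoded`
#'   list-columns, `match_index`, and `match_similarity`.
#' @export
interpolate_and_match <- function(model, a, b, database, n_interpolants = 7L,
                                  metric = "cos_sim") {
  metric <- match.arg(metric, SIMILARITY_METRICS)
  database <- rbind(database)
  if (nrow(database) == 0L) abort("empty database", class = "msvae_empty_dataset")
  za <- encode(model, a)$mean[1, ]
  zb <- encode(model, b)$mean[1, ]
  ts <- seq(0, 1, length.out = max(2L, n_interpolants))
  Z <- slerp(za, zb, ts)
  decoded <- decode(model, Z)
  best <- lapply(seq_len(nrow(decoded)), function(i) {
    sims <- similarity_to_all(decoded[i, ], database, metric)
    idx <- if (metric == "cos_sim") which.max(sims) else which.min(sims)
    list(index = idx, sim = sims[idx])
  })
  tibble(
    t = ts,
    latent = lapply(seq_len(nrow(Z)), function(i) Z[i, ]),
    decoded = lapply(seq_len(nrow(decoded)), function(i) decoded[i, ]),
    match_index = vapply(best, `[[`, integer(1), "index"),
    match_similarity = vapply(best, `[[`, numeric(1), "sim")
  )
}

#' Project latent codes onto their top two principal components
#'
#' Deterministic sign convention: within each component the loading with the
#' largest magnitude is made positive.
#'
#' @param latent Numeric matrix (rows = points, >= 3), at least 2 columns.
#' @return A list with `coordinates` (tibble `pc1`, `pc2`) and
#'   `variance_proportion` (length-2 numeric).
#' @export
project_2d <- function(latent) {
  latent <- as.matrix(latent)
  if (nrow(latent) < 3L || ncol(latent) < 2L) {
    abort("need at least 3 points in at least 2 dimensions", class = "msvae_shape_error")
  }
  if (all(apply(latent, 2L, var) < .Machine$double.eps)) {
    abort("zero-variance input", class = "msvae_numerical_error")
  }
  p <- prcomp(latent, center = TRUE, scale. = FALSE)
  rot <- p$rotation[, 1:2, drop = FALSE]
  for (k in 1:2) {
    if (rot[which.max(abs(rot[, k])), k] < 0) {
      rot[, k] <- -rot[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  list(
    coordinates = tibble(pc1 = p$x[, 1], pc2 = p$x[, 2]),
    variance_proportion = (p$sdev^2 / sum(p$sdev^2))[1:2]
  )
}
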