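# Reconstruction-quality metrics, the average-reconstruction baseline, and
# the ranked spectral-similarity score.

SIMILARITY_METRICS <- c("cos_sim", "eu_dist", "per_change", "per_diff")

#' Similarity between two spectrum vectors
#'
#' * `cos_sim`: inner product over the product of norms (defined as 0 when
#'   either norm is 0, so padding-only vectors never crash evaluation);
#' * `eu_dist`: root-sum-square difference;
#' * `per_change`: mean over cells of `(b - a) / (|a| + eps)`;
#' * `per_diff`: mean over cells of `|b - a| / ((|a| + |b|) / 2 + eps)`;
#' with `eps = 1e-8` stabilizing the per-cell ratios.
#'
#' @param a,b Numeric vectors of equal length.
#' @param metric One of `"cos_sim"`, `"eu_dist"`, `"per_change"`, `"per_diff"`.
#' @return A single number.
#' @export
similarity <- function(a, b, metric = SIMILARITY_METRICS) {
  metric <- match.arg(metric)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) abort("vectors differ in length", class = "msvae_shape_error")
  eps <- 1e-8
  switch(metric,
    cos_sim = {
      na <- sqrt(sum(a^2))
      nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    },
    eu_dist = sqrt(sum((b - a)^2)),
    per_change = mean((b - a) / (abs(a) + eps)),
    per_diff = mean(abs(b - a) / ((abs(a) + abs(b)) / 2 + eps))
  )
}

# Vectorized one-vs-many similarity used by ranking and matching.
similarity_to_all <- function(query, database, metric) {
  apply(database, 1L, function(row) similarity(query, row, metric))
}

#' Average-reconstruction baseline score
#'
#' The element-wise mean sample of the dataset is compared with every sample:
#' `(1/n) * sum_i score(x_i, x_bar)`. This is a baseline, not a model metric:
#' a trained model whose reconstructions do not beat it has collapsed to
#' reproducing the dataset mean.
#'
#' @param vectors Numeric matrix (rows = samples).
#' @inheritParams similarity
#' @return A single number.
#' @export
average_reconstruction_score <- function(vectors, metric = SIMILARITY_METRICS) {
  metric <- match.arg(metric)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0L) abort("empty dataset", class = "msvae_empty_dataset")
  x_bar <- colMeans(vectors)
  mean(apply(vectors, 1L, function(x) similarity(x, x_bar, metric)))
}

#' Reconstruction report for a model on a dataset
#'
#' Per-sample and mean values of all four similarity metrics between each
#' spectrum vector and its reconstruction, alongside the matching
#' average-reconstruction baselines.
#'
#' @param model A trained [betavae()]/[jointvae()].
#' @param vectors Numeric matrix of spectrum vectors.
#' @return An `msvae_recon_report`: list with `per_sample` (tibble) and
#'   `summary` (tibble with columns `metric`, `model_mean`, `baseline`).
#' @export
reconstruction_report <- function(model, vectors) {
  vectors <- as.matrix(vectors)
  x_hat <- decode(model, encode(model, vectors)$mean)
  per_sample <- purrr::map_dfc(SIMILARITY_METRICS, function(m) {
    tibble(!!m := vapply(
      seq_len(nrow(vectors)),
      function(i) similarity(vectors[i, ], x_hat[i, ], m), numeric(1)
    ))
  })
  per_sample <- dplyr::bind_cols(tibble(row = seq_len(nrow(vectors))), per_sample)
  summary <- tibble(
    metric = SIMILARITY_METRICS,
    model_mean = vapply(SIMILARITY_METRICS, function(m) mean(per_sample[[m]]), numeric(1)),
    baseline = vapply(
      SIMILARITY_METRICS,
      function(m) average_reconstruction_score(vectors, m), numeric(1)
    )
  )
  structure(list(per_sample = per_sample, summary = summary),
    class = "msvae_recon_report"
  )
}

#' @export
print.msvae_recon_report <- function(x, ...) {
  cat("<reconstruction report>\n")
  print(x$summary)
  invisible(x)
}

#' Ranked spectral-similarity score
#'
#' Each query (typically a reconstruction) is compared against every database
#' entry; the database is sorted by the metric (descending for cosine
#' similarity, ascending for distances, ties broken by database order) and
#' the 0-based position of the ground-truth entry is the query's rank. The
#' summary reports the mean, standard deviation, minimum and quartiles of the
#' ranks.
#'
#' @param reconstructions Numeric matrix of query vectors.
#' @param database Numeric matrix of reference vectors.
#' @param truth_index Integer vector: for each query, the database row holding
#'   its ground truth.
#' @inheritParams similarity
#' @return An `msvae_ranked_score`: list with `ranks` (tibble query/rank) and
#'   `summary` (tibble mean/std/min/q25/median/q75).
#' @export
ranked_score <- function(reconstructions, database, truth_index,
                         metric = SIMILARITY_METRICS) {
  metric <- match.arg(metric)
  reconstructions <- rbind(reconstructions)
  database <- rbind(database)
  if (nrow(database) == 0L) abort("empty database", class = "msvae_empty_dataset")
  truth_index <- as.integer(truth_index)
  stopifnot(length(truth_index) == nrow(reconstructions))
  if (any(truth_index < 1L | truth_index > nrow(database))) {
    abort("truth_index outside the database", class = "msvae_config_error")
  }
  decreasing <- metric == "cos_sim"
  ranks <- vapply(seq_len(nrow(reconstructions)), function(i) {
    sims <- similarity_to_all(reconstructions[i, ], database, metric)
    ord <- order(if (decreasing) -sims else sims) # stable: ties by database order
    which(ord == truth_index[i]) - 1L
  }, integer(1))
  q <- quantile(ranks, c(0.25, 0.5, 0.75))
  structure(
    list(
      ranks = tibble(query = seq_along(ranks), rank = ranks),
      summary = tibble(
        metric = metric, mean = mean(ranks), std = sd(ranks), min = min(ranks),
        q25 = q[[1]], median = q[[2]], q75 = q[[3]]
      )
    ),
    class = "msvae_ranked_score"
  )
}

#' @export
print.msvae_ranked_score <- function(x, ...) {
  cat("<ranked similarity score>\n")
  print(x$summary)
  invisible(x)
}
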