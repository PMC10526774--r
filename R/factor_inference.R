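# Supervised prediction of MS/MS factors from spectra or latent codes,
# permutation feature importance with grouped features, and factor
# cross-correlation.

#' Assemble predictor inputs for a factor-inference task
#'
#' In `"spectrum"` mode the input is the spectrum vector concatenated with
#' the encoded non-target factor columns; in `"latent"` mode the
#' posterior-mean latent code replaces the spectrum block. Rows with a
#' missing value in the target or any included factor are dropped (and
#' reported), never imputed.
#'
#' @param vectors Numeric matrix of spectrum vectors.
#' @param factors Numeric factor matrix from [encode_factors()] (columns
#'   named by factor).
#' @param target_factor Name of the column to predict.
#' @param input_mode `"spectrum"` or `"latent"`.
#' @param model Trained VAE, required in latent mode.
#' @param included_factors Factor columns used as side features (default: all
#'   columns except the target).
#' @return A list with `x` (input matrix), `y` (target values), `groups`
#'   (named list of column-index groups for PFI: one group per factor plus a
#'   single group for the whole spectrum/latent block), `kept` (row indices),
#'   and `n_dropped`.
#' @export
build_task_inputs <- function(vectors, factors, target_factor,
                              input_mode = c("spectrum", "latent"),
                              model = NULL, included_factors = NULL) {
  input_mode <- match.arg(input_mode)
  vectors <- as.matrix(vectors)
  factors <- as.matrix(factors)
  stopifnot(nrow(vectors) == nrow(factors))
  if (!target_factor %in% colnames(factors)) {
    abort(sprintf("target factor '%s' not found", target_factor), class = "msvae_config_error")
  }
  included_factors <- included_factors %||% setdiff(colnames(factors), target_factor)
  if (target_factor %in% included_factors) {
    abort("the target cannot be one of the included factors", class = "msvae_config_error")
  }
  block <- if (input_mode == "latent") {
    if (is.null(model)) {
      abort("latent mode requires a trained model", class = "msvae_config_error")
    }
    encode(model, vectors)$mean
  } else {
    vectors
  }
  colnames(block) <- paste0(
    if (input_mode == "latent") "latent_" else "cell_", seq_len(ncol(block))
  )
  side <- factors[, included_factors, drop = FALSE]
  keep <- stats::complete.cases(cbind(factors[, target_factor], side))
  x <- cbind(block, side)[keep, , drop = FALSE]
  groups <- c(
    setNames(list(seq_len(ncol(block))), if (input_mode == "latent") "latent" else "spectrum"),
    setNames(
      lapply(seq_along(included_factors), function(i) ncol(block) + i),
      included_factors
    )
  )
  list(
    x = x, y = factors[keep, target_factor], groups = groups,
    kept = which(keep), n_dropped = sum(!keep)
  )
}

classification_metrics <- function(truth, pred, levels) {
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  cm <- table(truth, pred)
  tp <- diag(cm)
  recall <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), NA_real_)
  precision <- ifelse(colSums(cm) > 0, tp / colSums(cm), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
    2 * precision * recall / (precision + recall), NA_real_
  )
  tibble(
    accuracy = mean(truth == pred),
    balanced_accuracy = mean(recall, na.rm = TRUE),
    recall_macro = mean(recall, na.rm = TRUE),
    precision_macro = mean(precision, na.rm = TRUE),
    f1 = mean(f1, na.rm = TRUE)
  )
}

regression_metrics <- function(truth, pred) {
  res <- truth - pred
  tibble(
    mse = mean(res^2),
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res)),
    r2 = 1 - sum(res^2) / sum((truth - mean(truth))^2),
    explained_variance = 1 - var(res) / var(truth)
  )
}

# seeded stratified 80/20 split; stratification by class for classification
holdout_split <- function(y, task, seed, train_fraction = 0.8) {
  withr::with_seed(seed, {
    if (task == "classify") {
      idx <- unlist(lapply(split(seq_along(y), y), function(g) {
        sample(g, max(1L, floor(train_fraction * length(g))))
      }))
    } else {
      idx <- sample(seq_along(y), floor(train_fraction * length(y)))
    }
    sort(idx)
  })
}

#' Fit a feed-forward factor predictor with held-out evaluation
#'
#' A dense network (hidden layers with batch normalization and ReLU, linear
#' output) trained on a seeded stratified 80/20 split; classification uses
#' softmax cross-entropy, regression squared error.
#'
#' @param x Input matrix (e.g. from [build_task_inputs()]).
#' @param y Target values (labels or numerics).
#' @param task `"classify"` or `"regress"`.
#' @param hidden Hidden-layer widths.
#' @param cfg A [train_config()].
#' @return A list with `predictor` (an `msvae_predictor`), `metrics` (tibble
#'   of held-out classification metrics: accuracy, balanced accuracy, macro
#'   recall/precision, F1 -- or regression metrics: MSE, RMSE, MAE, R-squared,
#'   explained variance), and `split` (train/test indices).
#' @export
fit_predictor <- function(x, y, task = c("classify", "regress"),
                          hidden = c(32), cfg = train_config(epochs = 30L)) {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (nrow(x) < 10L) abort("need at least 10 samples", class = "msvae_config_error")
  if (task == "classify") {
    lev <- sort(unique(as.character(y)))
    if (length(lev) < 2L) {
      abort("classification requires at least 2 classes", class = "msvae_config_error")
    }
    yy <- match(as.character(y), lev)
  } else {
    lev <- NULL
    yy <- as.numeric(y)
  }
  train_idx <- holdout_split(if (task == "classify") as.character(y) else yy, task, cfg$seed)
  test_idx <- setdiff(seq_len(nrow(x)), train_idx)
  predictor <- train_head(x[train_idx, , drop = FALSE], yy[train_idx], task, hidden, cfg, lev)
  pred <- predict(predictor, x[test_idx, , drop = FALSE])
  metrics <- if (task == "classify") {
    classification_metrics(as.character(y)[test_idx], pred, lev)
  } else {
    regression_metrics(yy[test_idx], pred)
  }
  list(
    predictor = predictor, metrics = metrics,
    split = list(train = train_idx, test = test_idx)
  )
}

predictor_score <- function(predictor, x, y, metric) {
  pred <- predict(predictor, x)
  switch(metric,
    accuracy = mean(as.character(y) == pred),
    balanced_accuracy = classification_metrics(
      as.character(y), pred, predictor$levels
    )$balanced_accuracy,
    mse = mean((as.numeric(y) - pred)^2),
    rmse = sqrt(mean((as.numeric(y) - pred)^2)),
    r2 = 1 - sum((as.numeric(y) - pred)^2) / sum((as.numeric(y) - mean(as.numeric(y)))^2),
    abort(sprintf("unknown metric '%s'", metric))
  )
}

#' Grouped permutation feature importance
#'
#' For each feature group the group's columns are shuffled jointly (one
#' permutation per repeat), the evaluation metric is recomputed, and the
#' importance is the mean performance drop relative to the unpermuted
#' baseline. Grouping keeps the whole spectrum (or latent) block as a single
#' feature, so it receives one score like each metadata factor. For error
#' metrics (mse/rmse) the drop is measured as the increase in error.
#'
#' @param predictor An `msvae_predictor`.
#' @param x,y Held-out inputs and targets.
#' @param groups Named list of column-index vectors (see
#'   [build_task_inputs()]); defaults to one group per column.
#' @param metric Evaluation metric: `"accuracy"`, `"balanced_accuracy"`,
#'   `"mse"`, `"rmse"` or `"r2"`.
#' @param repeats Number of permutation repeats per group (>= 1).
#' @param seed Seed for the permutations.
#' @return An `msvae_pfi`: tibble with `feature`, `importance`, `baseline`,
#'   plus attributes `repeats` and `seed`.
#' @export
permutation_feature_importance <- function(predictor, x, y, groups = NULL,
                                           metric = "accuracy", repeats = 10L,
                                           seed = 1L) {
  if (repeats < 1L) abort("repeats must be >= 1", class = "msvae_config_error")
  x <- as.matrix(x)
  groups <- groups %||% setNames(as.list(seq_len(ncol(x))), colnames(x) %||%
    paste0("feature_", seq_len(ncol(x))))
  higher_better <- !metric %in% c("mse", "rmse")
  baseline <- predictor_score(predictor, x, y, metric)
  imp <- withr::with_seed(seed, {
    vapply(groups, function(cols) {
      drops <- vapply(seq_len(repeats), function(r) {
        xp <- x
        perm <- sample(nrow(x))
        xp[, cols] <- x[perm, cols, drop = FALSE]
        score <- predictor_score(predictor, xp, y, metric)
        if (higher_better) baseline - score else score - baseline
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  structure(
    tibble(feature = names(groups), importance = unname(imp), baseline = baseline),
    class = c("msvae_pfi", class(tibble())),
    repeats = as.integer(repeats), seed = as.integer(seed), metric = metric
  )
}

#' Cross-correlate MS/MS factors
#'
#' Pairwise Pearson correlation between numerically encoded factors on
#' pairwise-complete rows. Correlating integer-coded categorical labels is
#' kept deliberately (it is how label/latent relations are probed throughout
#' the package) but depends on the coding; a rank-based mode is available as
#' a robustness check.
#'
#' @param factors Numeric factor matrix from [encode_factors()].
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation matrix with unit diagonal; zero-variance factors give
#'   `NA` entries, with the flagged factor names in attribute `undefined`.
#' @export
cross_correlate_factors <- function(factors, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  factors <- as.matrix(factors)
  zero_var <- vapply(seq_len(ncol(factors)), function(j) {
    x <- factors[, j]
    x <- x[!is.na(x)]
    length(x) < 2L || var(x) == 0
  }, logical(1))
  cc <- suppressWarnings(cor(factors, use = "pairwise.complete.obs", method = method))
  diag(cc) <- 1
  structure(cc, undefined = colnames(factors)[zero_var])
}
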