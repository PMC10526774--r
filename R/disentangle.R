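# Supervised disentanglement scores (BetaVAE, FactorVAE, MIG) and the
# two-step factor/latent pairwise-correlation analysis with greedy
# factor-to-latent assignment.

new_metric_score <- function(name, value, protocol) {
  structure(
    list(name = name, value = value, protocol = protocol),
    class = "msvae_metric_score"
  )
}

#' @export
print.msvae_metric_score <- function(x, ...) {
  cat(sprintf("<%s score> %.4f\n", x$name, x$value))
  invisible(x)
}

#' BetaVAE disentanglement score
#'
#' For each training point one generative factor is picked and a batch of
#' sample pairs agreeing on that factor is drawn; the mean absolute latent
#' difference over the batch is the feature vector and the factor index the
#' label. A multinomial linear classifier is fit and the score is its
#' held-out accuracy: if each factor controls one latent coordinate, that
#' coordinate's mean difference is near zero whenever the factor is fixed,
#' making the factor index linearly separable.
#'
#' @param representation Function mapping a factor matrix (rows = samples) to
#'   a latent matrix.
#' @param factor_sampler Function of `n` returning a factor matrix with
#'   independent columns.
#' @param n_points Number of training points for the classifier.
#' @param pair_batch Pairs averaged per training point.
#' @param seed Seed for the protocol.
#' @return An `msvae_metric_score` with `value` in `[0, 1]`.
#' @export
betavae_score <- function(representation, factor_sampler, n_points = 500L,
                          pair_batch = 64L, seed = 1L) {
  probe <- factor_sampler(2L)
  n_factors <- ncol(probe)
  if (is.null(n_factors) || n_factors < 2L) {
    abort("the BetaVAE score needs at least 2 factors", class = "msvae_protocol_error")
  }
  withr::with_seed(seed, {
    ks <- sample.int(n_factors, n_points, replace = TRUE)
    feats <- t(vapply(ks, function(k) {
      fa <- factor_sampler(pair_batch)
      fb <- factor_sampler(pair_batch)
      fb[, k] <- fa[, k] # the pair agrees on factor k
      colMeans(abs(representation(fa) - representation(fb)))
    }, numeric(ncol(representation(probe)))))
    df <- data.frame(feats, k = factor(ks))
    train <- sample(n_points, floor(0.8 * n_points))
    fit <- suppressMessages(nnet::multinom(k ~ ., data = df[train, ], trace = FALSE))
    pred <- predict(fit, newdata = df[-train, ])
    acc <- mean(pred == df$k[-train])
  })
  new_metric_score("betavae", acc, list(
    n_points = n_points, pair_batch = pair_batch, seed = seed
  ))
}

#' FactorVAE disentanglement score
#'
#' Latent dimensions are normalized by their empirical standard deviation
#' over a reference sample; dimensions whose standard deviation falls below
#' `collapse_threshold` times the median are pruned (a collapsed dimension
#' would otherwise always win the variance argmin). Per vote, one factor is
#' fixed, a batch is drawn, and the dimension with the smallest variance of
#' normalized codes votes for that factor; the score is the accuracy of the
#' per-dimension majority-vote classifier.
#'
#' @inheritParams betavae_score
#' @param n_votes Number of votes.
#' @param vote_batch Samples per vote.
#' @param collapse_threshold Relative standard-deviation cutoff for pruning
#'   collapsed dimensions.
#' @export
factorvae_score <- function(representation, factor_sampler, n_votes = 500L,
                            vote_batch = 64L, collapse_threshold = 0.05,
                            seed = 1L) {
  probe <- factor_sampler(2L)
  n_factors <- ncol(probe)
  if (is.null(n_factors) || n_factors < 2L) {
    abort("the FactorVAE score needs at least 2 factors", class = "msvae_protocol_error")
  }
  withr::with_seed(seed, {
    ref <- representation(factor_sampler(1000L))
    sds <- apply(ref, 2L, sd)
    keep <- sds >= collapse_threshold * median(sds) & sds > 0
    if (!any(keep)) {
      abort("all latent dimensions collapsed", class = "msvae_degenerate_representation")
    }
    votes <- t(vapply(seq_len(n_votes), function(v) {
      k <- sample.int(n_factors, 1L)
      f <- factor_sampler(vote_batch)
      f[, k] <- f[1L, k] # factor k fixed across the batch
      z <- sweep(representation(f)[, keep, drop = FALSE], 2L, sds[keep], `/`)
      c(dim = unname(which.min(apply(z, 2L, var))), k = k)
    }, c(dim = 0, k = 0)))
    tab <- table(factor(votes[, "dim"], levels = seq_len(sum(keep))), votes[, "k"])
    acc <- sum(apply(tab, 1L, max)) / n_votes
  })
  new_metric_score("factorvae", acc, list(
    n_votes = n_votes, vote_batch = vote_batch,
    collapse_threshold = collapse_threshold, seed = seed,
    pruned_dims = which(!keep)
  ))
}

# empirical mutual information / entropy from discrete codes (natural log)
discrete_mi <- function(a, b) {
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  idx <- which(joint > 0, arr.ind = TRUE)
  sum(joint[idx] * log(joint[idx] / (pa[idx[, 1]] * pb[idx[, 2]])))
}

discrete_entropy <- function(a) {
  p <- table(a) / length(a)
  p <- p[p > 0]
  -sum(p * log(p))
}

# equal-width binning of a latent/continuous column
bin_equal_width <- function(x, n_bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(rep(1L, length(x)))
  }
  pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
}

#' Mutual Information Gap (MIG)
#'
#' Each latent dimension is discretized into `n_bins` equal-width bins and
#' the empirical mutual information with every factor is computed. Per
#' factor, the gap is the difference between the highest and second-highest
#' mutual information, normalized by the factor's entropy; the score is the
#' mean gap over factors (clipped to `[0, 1]`). Zero-entropy factors are
#' excluded and flagged.
#'
#' @param latent Numeric latent matrix (>= 2 columns).
#' @param factors Factor matrix; columns with more than `n_bins` distinct
#'   numeric values are themselves discretized into equal-width bins.
#' @param n_bins Number of bins per dimension.
#' @return An `msvae_metric_score`; the per-factor mutual-information matrix
#'   is in `protocol$mi` (rows = latent dimensions).
#' @export
mig_score <- function(latent, factors, n_bins = 20L) {
  latent <- as.matrix(latent)
  factors <- as.matrix(factors)
  if (ncol(latent) < 2L) abort("MIG needs at least 2 latent dimensions", class = "msvae_protocol_error")
  z_disc <- apply(latent, 2L, bin_equal_width, n_bins = n_bins)
  f_disc <- apply(factors, 2L, function(f) {
    if (length(unique(f)) > n_bins) bin_equal_width(f, n_bins) else f
  })
  mi <- matrix(0, ncol(latent), ncol(factors),
    dimnames = list(NULL, colnames(factors))
  )
  for (j in seq_len(ncol(latent))) {
    for (k in seq_len(ncol(factors))) {
      mi[j, k] <- discrete_mi(z_disc[, j], f_disc[, k])
    }
  }
  h <- apply(f_disc, 2L, discrete_entropy)
  usable <- h > 0
  gaps <- vapply(which(usable), function(k) {
    s <- sort(mi[, k], decreasing = TRUE)
    (s[1] - s[2]) / h[k]
  }, numeric(1))
  value <- min(max(mean(gaps), 0), 1)
  new_metric_score("mig", value, list(
    n_bins = n_bins, mi = mi, entropy = h,
    excluded_factors = colnames(factors)[!usable]
  ))
}

## ---------------------------------------------------------------------------
## Two-step pairwise correlation analysis

#' Partitioning constraints for the two-step correlation analysis
#'
#' The analysis restricts the dataset to factor ranges (the broad subset),
#' then forms narrow partitions in which only one factor varies while every
#' other factor is fixed to a single bin or label. Continuous factors are
#' binned into half-open `[low, low + step)` intervals.
#'
#' @param ... One named constraint per analysis factor: a continuous factor
#'   as `list(low =, high =, step =)` (step defaults to 5) or a categorical
#'   factor as a vector of allowed codes/labels.
#' @param min_size Minimum partition size (default 10).
#' @return A `partition_spec`.
#' @export
partition_spec <- function(..., min_size = 10L) {
  constraints <- list(...)
  if (length(constraints) == 1L && is.null(names(constraints)) && is.list(constraints[[1]])) {
    constraints <- constraints[[1]]
  }
  if (is.null(names(constraints)) || any(!nzchar(names(constraints)))) {
    abort("every constraint must be named by its factor")
  }
  constraints <- lapply(constraints, function(con) {
    if (is.list(con)) {
      con$step <- con$step %||% 5
      stopifnot(con$step > 0, con$low < con$high)
      c(con, type = "continuous")
    } else {
      list(values = con, type = "categorical")
    }
  })
  structure(list(constraints = constraints, min_size = as.integer(min_size)),
    class = "partition_spec"
  )
}

# per-row bin id for a factor under its constraint; NA = outside the range
constraint_bins <- function(x, con) {
  if (con$type == "continuous") {
    b <- floor((x - con$low) / con$step)
    b[x < con$low | x >= con$high] <- NA
    lab <- sprintf("[%g,%g)", con$low + b * con$step, con$low + (b + 1) * con$step)
    lab[is.na(b)] <- NA
    lab
  } else {
    ifelse(x %in% con$values, as.character(x), NA)
  }
}

#' Build single-varying-factor partitions
#'
#' For each analysis factor, rows inside the broad range restriction are
#' grouped by the Cartesian product of the other factors' bins/labels; each
#' group in which only the chosen factor varies is one partition. Partitions
#' smaller than `min_size` are dropped and counted.
#'
#' @param factors Numeric factor matrix (columns named; e.g. from
#'   [encode_factors()]).
#' @param spec A [partition_spec()] covering every analysis factor.
#' @return An `msvae_partitions` tibble: `varying_factor`, `partition_id`,
#'   `fixed` (label describing the fixed cell), `rows` (list-column of member
#'   row indices), `n`; dropped-partition counts in attribute `n_dropped`.
#' @export
build_partitions <- function(factors, spec) {
  factors <- as.matrix(factors)
  fnames <- names(spec$constraints)
  missing <- setdiff(fnames, colnames(factors))
  if (length(missing)) {
    abort(sprintf("factors not in the matrix: %s", paste(missing, collapse = ", ")))
  }
  bins <- vapply(fnames, function(f) {
    constraint_bins(factors[, f], spec$constraints[[f]])
  }, character(nrow(factors)))
  in_range <- rowSums(is.na(bins)) == 0L
  out <- list()
  n_dropped <- 0L
  for (f in fnames) {
    others <- setdiff(fnames, f)
    cell <- apply(bins[in_range, others, drop = FALSE], 1L, paste, collapse = " | ")
    groups <- split(which(in_range), cell)
    for (g in names(groups)) {
      rows <- groups[[g]]
      if (length(rows) < spec$min_size) {
        n_dropped <- n_dropped + 1L
        next
      }
      out[[length(out) + 1L]] <- tibble(
        varying_factor = f,
        fixed = paste(paste(others, g, sep = " = "), collapse = ""),
        rows = list(rows),
        n = length(rows)
      )
    }
  }
  if (!length(out)) {
    abort("no partition meets the minimum size", class = "msvae_empty_analysis")
  }
  res <- dplyr::bind_rows(out)
  res$partition_id <- seq_len(nrow(res))
  res <- res[, c("varying_factor", "partition_id", "fixed", "rows", "n")]
  structure(res,
    class = c("msvae_partitions", class(tibble())),
    n_dropped = n_dropped
  )
}

#' Correlate the varying factor with every latent coordinate in a partition
#'
#' Pearson r and p-value between the partition's varying factor and each
#' latent dimension, on the partition members only. Zero-variance cases give
#' flagged undefined cells rather than errors.
#'
#' @param rows Member row indices of the partition.
#' @param varying Numeric values of the varying factor (full-dataset column).
#' @param latent Latent matrix aligned with the factor matrix rows.
#' @param factor_name,partition_id Labels carried into the output.
#' @return Tibble of correlation cells: `factor`, `latent_index`, `r`,
#'   `p_value`, `partition_id`, `n`, `defined`.
#' @export
partition_correlations <- function(rows, varying, latent, factor_name = "factor",
                                   partition_id = 1L) {
  latent <- as.matrix(latent)
  f <- varying[rows]
  purrr::map_dfr(seq_len(ncol(latent)), function(j) {
    z <- latent[rows, j]
    if (length(rows) < 3L || var(f) == 0 || var(z) == 0) {
      return(tibble(
        factor = factor_name, latent_index = j, r = NA_real_,
        p_value = NA_real_, partition_id = partition_id,
        n = length(rows), defined = FALSE
      ))
    }
    ct <- cor.test(f, z, method = "pearson")
    tibble(
      factor = factor_name, latent_index = j, r = unname(ct$estimate),
      p_value = ct$p.value, partition_id = partition_id,
      n = length(rows), defined = TRUE
    )
  })
}

#' Run the correlation step over all partitions
#'
#' @param partitions An `msvae_partitions` tibble from [build_partitions()].
#' @param factors Factor matrix the partitions were built from.
#' @param latent Latent matrix (posterior means), rows aligned with
#'   `factors`.
#' @return Tibble of all correlation cells (see [partition_correlations()]).
#' @export
correlate_partitions <- function(partitions, factors, latent) {
  factors <- as.matrix(factors)
  purrr::map_dfr(seq_len(nrow(partitions)), function(i) {
    partition_correlations(
      partitions$rows[[i]],
      factors[, partitions$varying_factor[i]],
      latent,
      factor_name = partitions$varying_factor[i],
      partition_id = partitions$partition_id[i]
    )
  })
}

#' Aggregate correlation cells into the mean-r table
#'
#' Distributions of partition-level Pearson coefficients are summarized per
#' factor x latent pair: a factor correlates with a latent variable better on
#' average when the mean is further from 0, and consistently when the
#' standard deviation is small -- both are reported. Undefined cells are
#' excluded from the summaries (not zero-imputed); factor/latent pairs with
#' no valid cell are flagged.
#'
#' @param cells Correlation-cell tibble from [correlate_partitions()].
#' @return An `msvae_correlation_summary`: tibble with `factor`,
#'   `latent_index`, `mean_r`, `sd_r`, `n_cells`; the latent x factor mean-r
#'   matrix is in attribute `mean_r_matrix`.
#' @export
aggregate_correlations <- function(cells) {
  summ <- cells |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$factor, .data$latent_index) |>
    dplyr::summarise(
      mean_r = mean(.data$r),
      # population SD: the spread of the observed partition coefficients
      sd_r = sqrt(mean((.data$r - mean(.data$r))^2)),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
  all_pairs <- tidyr::expand_grid(
    factor = unique(cells$factor),
    latent_index = sort(unique(cells$latent_index))
  )
  summ <- dplyr::left_join(all_pairs, summ, by = c("factor", "latent_index"))
  mat <- tidyr::pivot_wider(
    summ[, c("factor", "latent_index", "mean_r")],
    names_from = "factor", values_from = "mean_r"
  )
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- paste0("Z", mat$latent_index)
  structure(summ,
    class = c("msvae_correlation_summary", class(tibble())),
    mean_r_matrix = m,
    flagged = summ$factor[is.na(summ$mean_r)]
  )
}

#' Greedy factor-to-latent assignment
#'
#' Repeatedly matches the factor/latent pair with the highest remaining
#' absolute mean correlation, removing both from play (ties broken by lower
#' latent index, then factor name order; undefined entries treated as 0).
#' The assignment is `distinct` when the mapping is injective and each
#' factor's matched absolute mean correlation strictly exceeds its runner-up
#' across the other latent variables -- the operational form of "each factor
#' correlates with one latent variable exclusively".
#'
#' @param mean_r A latent x factor matrix of mean correlations (rows
#'   `Z1..Zk`), or an `msvae_correlation_summary`.
#' @return An `msvae_assignment`: list with `mapping` (tibble `factor`,
#'   `latent_index`, `mean_r`), `distinct`, `complete` (FALSE when there were
#'   fewer latent dimensions than factors), and the input `mean_r` matrix.
#' @export
assign_factors <- function(mean_r) {
  if (inherits(mean_r, "msvae_correlation_summary")) {
    mean_r <- attr(mean_r, "mean_r_matrix")
  }
  mean_r <- as.matrix(mean_r)
  work <- mean_r
  work[is.na(work)] <- 0
  n_latent <- nrow(work)
  factors <- colnames(work) %||% paste0("F", seq_len(ncol(work)))
  colnames(work) <- factors
  complete <- n_latent >= ncol(work)
  if (!complete) {
    warn("fewer latent dimensions than factors: assignment will be partial")
  }
  mapping <- list()
  free_rows <- seq_len(n_latent)
  free_cols <- order(factors) # factor-name tie-break order
  while (length(free_rows) && length(free_cols)) {
    sub <- abs(work[free_rows, free_cols, drop = FALSE])
    best <- max(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    hit <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE][1, ]
    row <- free_rows[hit[1]]
    col <- free_cols[hit[2]]
    mapping[[length(mapping) + 1L]] <- tibble(
      factor = factors[col], latent_index = row, mean_r = mean_r[row, col]
    )
    free_rows <- setdiff(free_rows, row)
    free_cols <- setdiff(free_cols, col)
  }
  mapping <- dplyr::bind_rows(mapping)
  injective <- !anyDuplicated(mapping$latent_index) && nrow(mapping) == ncol(work)
  exclusive <- all(vapply(seq_len(nrow(mapping)), function(i) {
    col <- abs(work[, mapping$factor[i]])
    runner_up <- max(col[-mapping$latent_index[i]], -Inf)
    abs(mapping$mean_r[i]) > runner_up
  }, logical(1)))
  structure(
    list(
      mapping = mapping[order(mapping$factor), ],
      distinct = injective && exclusive,
      complete = complete,
      mean_r = mean_r
    ),
    class = "msvae_assignment"
  )
}

#' @export
print.msvae_assignment <- function(x, ...) {
  cat(sprintf(
    "<factor-to-latent assignment> distinct = %s\n",
    x$distinct
  ))
  print(x$mapping)
  invisible(x)
}

#' Two-step factor/latent correlation analysis
#'
#' Convenience wrapper running [build_partitions()],
#' [correlate_partitions()], [aggregate_correlations()] and
#' [assign_factors()] in sequence.
#'
#' @inheritParams build_partitions
#' @inheritParams correlate_partitions
#' @return A list with `partitions`, `cells`, `summary`, and `assignment`.
#' @export
two_step_correlation <- function(factors, latent, spec) {
  partitions <- build_partitions(factors, spec)
  cells <- correlate_partitions(partitions, factors, latent)
  summary <- aggregate_correlations(cells)
  list(
    partitions = partitions, cells = cells, summary = summary,
    assignment = assign_factors(summary)
  )
}

#' Variance in disentanglement scores explained by hyperparameters
#'
#' Ordinary least-squares regression of a score column on one-hot-expanded
#' hyperparameter subsets, optionally with the full interaction set, giving
#' an R-squared per subset.
#'
#' @param scores Data frame with one row per model: hyperparameter columns
#'   plus a numeric score column.
#' @param score Name of the score column.
#' @param subsets List of character vectors of hyperparameter names; each
#'   yields one R-squared.
#' @param interactions If `TRUE`, each subset enters with its full Cartesian
#'   interaction set.
#' @return Tibble with `subset`, `r_squared`, `rank_deficient`.
#' @export
variance_explained_by_hyperparameters <- function(scores, score = "score",
                                                  subsets, interactions = FALSE) {
  scores <- as.data.frame(scores)
  purrr::map_dfr(subsets, function(vars) {
    for (v in vars) {
      if (length(unique(scores[[v]])) < 2L) {
        abort(sprintf("hyperparameter '%s' has fewer than 2 distinct values", v))
      }
      scores[[v]] <- factor(scores[[v]])
    }
    op <- if (interactions && length(vars) > 1L) " * " else " + "
    fml <- stats::as.formula(paste(score, "~", paste(vars, collapse = op)))
    fit <- lm(fml, data = scores)
    # a perfect fit is legitimate here (e.g. a score that is an exact
    # function of one hyperparameter); silence the summary caveat
    r2 <- suppressWarnings(summary(fit)$r.squared)
    tibble(
      subset = paste(vars, collapse = if (interactions) " x " else " + "),
      r_squared = r2,
      rank_deficient = any(is.na(stats::coef(fit)))
    )
  })
}
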