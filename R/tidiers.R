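# broom-style tidy()/glance() methods for fitted objects and results.

#' @exportS3Method
tidy.msvae_history <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"epoch",
    names_to = "term", values_to = "value"
  )
}

#' @exportS3Method
glance.betavae <- function(x, ...) {
  out <- tibble(
    model = "betavae", input_dim = x$input_dim, latent_dim = x$latent_dim,
    beta = x$beta, trained_epochs = x$trained_epochs
  )
  if (!is.null(x$history)) {
    out <- dplyr::bind_cols(out, utils::tail(x$history, 1)[, -1])
  }
  out
}

#' @exportS3Method
glance.jointvae <- function(x, ...) {
  out <- tibble(
    model = "jointvae", input_dim = x$input_dim,
    cont_latent_dim = x$latent_dim,
    disc_categories = paste(x$disc_category_sizes, collapse = ","),
    cont_gamma = x$cont_gamma, disc_gamma = x$disc_gamma,
    trained_epochs = x$trained_epochs
  )
  if (!is.null(x$history)) {
    out <- dplyr::bind_cols(out, utils::tail(x$history, 1)[, -1])
  }
  out
}

#' @exportS3Method
tidy.msvae_assignment <- function(x, ...) {
  dplyr::mutate(x$mapping, distinct = x$distinct, complete = x$complete)
}

#' @exportS3Method
tidy.msvae_metric_score <- function(x, ...) {
  tibble(metric = x$name, value = x$value)
}

#' @exportS3Method
tidy.msvae_recon_report <- function(x, ...) x$summary

#' @exportS3Method
tidy.msvae_ranked_score <- function(x, ...) x$summary

#' @exportS3Method
glance.msvae_ranked_score <- function(x, ...) x$summary
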