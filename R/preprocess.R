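# Filter/transform pipeline and the sparse 2N-cell spectrum vector.

#' Preprocessing configuration
#'
#' Parameters of the filter/transform pipeline that turns a peak list into a
#' fixed-length vector: peaks below `min_intensity` (percent of the base peak
#' after rescaling) are rejected, peaks above `max_mz` are rejected, the top
#' `max_num_peaks` peaks by intensity are kept, intensities are rescaled into
#' `[min_intensity, 100]` (dynamic range expansion) or normalized to a base
#' peak of 100, and finally interleaved (m/z, intensity) pairs are scaled into
#' `[0, 1]`.
#'
#' @param max_num_peaks Maximum number of peaks N kept per spectrum; the vector
#'   has 2N cells.
#' @param min_intensity Minimum relative intensity, in percent of the base peak.
#' @param max_mz Maximum m/z retained, Da.
#' @param rescale_intensity If `TRUE`, expand the dynamic range so the weakest
#'   surviving peak maps to `min_intensity` and the base peak to 100; if
#'   `FALSE`, only normalize the base peak to 100.
#' @param mz_reference Fixed denominator mapping m/z into `[0, 1]` (defaults to
#'   `max_mz` so decoding is well defined across datasets).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(max_num_peaks = 50, min_intensity = 0.1,
                              max_mz = 2500, rescale_intensity = TRUE,
                              mz_reference = max_mz) {
  stopifnot(max_num_peaks >= 1, min_intensity >= 0, min_intensity <= 100, max_mz > 0)
  if (mz_reference <= 0) abort("mz_reference must be positive", class = "msvae_config_error")
  structure(
    list(
      max_num_peaks = as.integer(max_num_peaks),
      min_intensity = min_intensity,
      max_mz = max_mz,
      rescale_intensity = isTRUE(rescale_intensity),
      mz_reference = mz_reference
    ),
    class = "preprocess_config"
  )
}

# normalize to base peak 100 (the [0,100] relative-abundance convention)
normalize_base_peak <- function(peaks) {
  peaks$intensity <- peaks$intensity / max(peaks$intensity) * 100
  peaks
}

#' Filter a peak list
#'
#' Applies, in order: the relative-intensity threshold, the m/z ceiling, and
#' top-N truncation by intensity (ties broken by lower m/z). Intensities are
#' thresholded on the base-peak-normalized scale.
#'
#' @param peaks Tibble with `mz` and `intensity` columns.
#' @param cfg A [preprocess_config()].
#' @return Filtered peaks, sorted by intensity descending.
#' @export
filter_spectrum <- function(peaks, cfg) {
  peaks <- validate_peaks(peaks)
  rel <- peaks$intensity / max(peaks$intensity) * 100
  peaks <- peaks[rel >= cfg$min_intensity, , drop = FALSE]
  peaks <- peaks[peaks$mz <= cfg$max_mz, , drop = FALSE]
  if (nrow(peaks) == 0L) {
    abort("all peaks removed by filtering", class = "msvae_empty_spectrum")
  }
  ord <- order(-peaks$intensity, peaks$mz)
  peaks[head(ord, cfg$max_num_peaks), , drop = FALSE]
}

#' Rescale peak intensities
#'
#' With dynamic range expansion on and at least two distinct intensities, an
#' affine map sends the weakest peak to `min_intensity` and the base peak to
#' 100. A single-peak spectrum is not rescaled (its peak is set to 100 by the
#' base-peak convention), and a degenerate all-equal spectrum maps to 100.
#' With expansion off, intensities are normalized so the base peak is 100.
#'
#' @inheritParams filter_spectrum
#' @return Rescaled peaks.
#' @export
rescale_spectrum <- function(peaks, cfg) {
  peaks <- validate_peaks(peaks)
  if (!cfg$rescale_intensity || nrow(peaks) == 1L) {
    return(normalize_base_peak(peaks))
  }
  lo <- min(peaks$intensity)
  hi <- max(peaks$intensity)
  if (hi == lo) {
    peaks$intensity <- rep(100, nrow(peaks))
    return(peaks)
  }
  peaks$intensity <- cfg$min_intensity +
    (peaks$intensity - lo) / (hi - lo) * (100 - cfg$min_intensity)
  peaks
}

#' Vectorize a filtered, rescaled peak list
#'
#' Peaks are interleaved as (m/z, intensity) pairs in descending intensity
#' order: m/z is divided by `mz_reference` and clipped to `[0, 1]`, intensity
#' divided by 100, and (0, 0) padding pairs fill the vector to length
#' `2 * max_num_peaks`. A true peak can never have a scaled m/z of 0, so
#' padding is unambiguous.
#'
#' @inheritParams filter_spectrum
#' @return Numeric vector of length `2 * max_num_peaks` with the real-pair
#'   count as attribute `n_real_peaks`.
#' @export
vectorize <- function(peaks, cfg) {
  peaks <- validate_peaks(peaks)
  if (cfg$mz_reference <= 0) abort("mz_reference must be positive", class = "msvae_config_error")
  ord <- order(-peaks$intensity, peaks$mz)
  peaks <- peaks[head(ord, cfg$max_num_peaks), , drop = FALSE]
  mz_scaled <- pmin(pmax(peaks$mz / cfg$mz_reference, 0), 1)
  int_scaled <- peaks$intensity / 100
  cells <- numeric(2L * cfg$max_num_peaks)
  idx <- seq_len(nrow(peaks))
  cells[2L * idx - 1L] <- mz_scaled
  cells[2L * idx] <- int_scaled
  structure(cells, n_real_peaks = nrow(peaks))
}

#' Decode a spectrum vector back into a peak list
#'
#' Inverse of [vectorize()] on the non-padding support: pairs whose scaled
#' intensity falls below `min_intensity / 100` or whose scaled m/z is 0 are
#' treated as padding and dropped. Decoder outputs pass through the same rule,
#' so sub-threshold hallucinated pairs never surface as peaks.
#'
#' @param cells Numeric vector of cells in `[0, 1]`.
#' @inheritParams filter_spectrum
#' @return A peak tibble (possibly with zero rows, signalling an empty
#'   spectrum).
#' @export
devectorize <- function(cells, cfg) {
  cells <- as.numeric(cells)
  stopifnot(length(cells) %% 2L == 0L)
  mz_scaled <- cells[seq(1L, length(cells), by = 2L)]
  int_scaled <- cells[seq(2L, length(cells), by = 2L)]
  keep <- mz_scaled > 0 & int_scaled >= cfg$min_intensity / 100
  tibble(
    mz = mz_scaled[keep] * cfg$mz_reference,
    intensity = int_scaled[keep] * 100
  )
}

#' Preprocess a whole dataset into a vector matrix
#'
#' Applies filter, rescale and vectorize to every spectrum. Spectra emptied by
#' filtering are dropped and counted; rows of the vector matrix stay aligned
#' with rows of the factor matrix.
#'
#' @param dataset An [ms_dataset()].
#' @param cfg A [preprocess_config()].
#' @param code_maps Passed to [encode_factors()].
#' @return A list with `vectors` (numeric matrix, one row per retained
#'   spectrum), `factors` (numeric factor matrix from [encode_factors()]),
#'   `kept` (row indices into `dataset`), and `drop_report` (tibble of dropped
#'   spectrum ids with reasons).
#' @export
preprocess_dataset <- function(dataset, cfg, code_maps = NULL) {
  stopifnot(inherits(dataset, "ms_dataset"))
  vecs <- vector("list", nrow(dataset))
  dropped <- logical(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    res <- tryCatch(
      vectorize(rescale_spectrum(filter_spectrum(dataset$peaks[[i]], cfg), cfg), cfg),
      msvae_empty_spectrum = function(e) NULL
    )
    if (is.null(res)) dropped[i] <- TRUE else vecs[[i]] <- as.numeric(res)
  }
  if (all(dropped)) {
    abort("all spectra were dropped by preprocessing", class = "msvae_empty_dataset")
  }
  kept <- which(!dropped)
  vectors <- do.call(rbind, vecs[kept])
  rownames(vectors) <- dataset$spectrum_id[kept]
  factors <- encode_factors(dataset, code_maps = code_maps)[kept, , drop = FALSE]
  list(
    vectors = vectors,
    factors = factors,
    kept = kept,
    drop_report = tibble(
      spectrum_id = dataset$spectrum_id[dropped],
      reason = rep("all peaks below thresholds", sum(dropped))
    )
  )
}
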