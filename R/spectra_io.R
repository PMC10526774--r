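# Reading/writing MS/MS spectral libraries (MSP, MGF) and the in-memory
# dataset container used by the rest of the package.

# Factor columns carried by every dataset. Numeric factors may be NA when the
# source library does not report them; categorical factors are plain character
# columns with vocabularies tracked as an attribute.
MS_NUMERIC_FACTORS <- c("collision_energy", "total_exact_mass", "precursor_mz")
MS_CATEGORICAL_FACTORS <- c(
  "precursor_type", "instrument", "instrument_type", "ionization_mode",
  "kingdom", "superclass", "class_", "subclass"
)
MS_FACTORS <- c(MS_NUMERIC_FACTORS, MS_CATEGORICAL_FACTORS)

#' Construct an MS/MS spectrum dataset
#'
#' An `ms_dataset` is a tibble with one row per spectrum: a `spectrum_id`
#' column, a `compound_id` column, a `peaks` list-column (each element a tibble
#' with `mz` and `intensity`), and one column per metadata factor (collision
#' energy, precursor information, instrument labels, ionization mode, compound
#' taxonomy). Categorical factor vocabularies (label -> integer code, in
#' first-appearance order unless supplied) are stored in the
#' `factor_vocabularies` attribute, free-text provenance in `provenance`.
#'
#' @param spectra A data frame with at least a `peaks` list-column; missing
#'   factor columns are added as `NA`.
#' @param provenance Free-text description of where the spectra came from.
#' @param factor_vocabularies Optional named list mapping each categorical
#'   factor to an ordered character vector of labels; integer codes are the
#'   position in this vector minus one unless the vector has names giving
#'   explicit codes.
#' @return An `ms_dataset` tibble.
#' @export
ms_dataset <- function(spectra, provenance = "", factor_vocabularies = NULL) {
  spectra <- as_tibble(spectra)
  if (nrow(spectra) == 0L) {
    abort("an ms_dataset must contain at least one spectrum", class = "msvae_empty_dataset")
  }
  if (!"peaks" %in% names(spectra)) {
    abort("`spectra` must have a `peaks` list-column")
  }
  if (!"spectrum_id" %in% names(spectra)) {
    spectra$spectrum_id <- sprintf("spectrum_%04d", seq_len(nrow(spectra)))
  }
  if (!"compound_id" %in% names(spectra)) spectra$compound_id <- NA_character_
  for (f in MS_NUMERIC_FACTORS) {
    if (!f %in% names(spectra)) spectra[[f]] <- NA_real_
  }
  for (f in MS_CATEGORICAL_FACTORS) {
    if (!f %in% names(spectra)) spectra[[f]] <- NA_character_
  }
  spectra$peaks <- lapply(spectra$peaks, validate_peaks)
  vocab <- factor_vocabularies %||% build_vocabularies(spectra)
  structure(
    spectra,
    provenance = provenance,
    factor_vocabularies = vocab,
    class = c("ms_dataset", class(as_tibble(spectra)))
  )
}

validate_peaks <- function(peaks) {
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0L) {
    abort("a spectrum must contain at least one peak", class = "msvae_empty_spectrum")
  }
  if (!all(is.finite(peaks$mz)) || any(peaks$mz <= 0)) {
    abort("peak m/z values must be finite and positive", class = "msvae_invalid_peak")
  }
  if (!all(is.finite(peaks$intensity)) || any(peaks$intensity < 0)) {
    abort("peak intensities must be finite and non-negative", class = "msvae_invalid_peak")
  }
  peaks[, c("mz", "intensity")]
}

build_vocabularies <- function(spectra) {
  vocab <- list()
  for (f in MS_CATEGORICAL_FACTORS) {
    labs <- unique(spectra[[f]])
    labs <- labs[!is.na(labs)]
    if (length(labs)) vocab[[f]] <- as.character(labs)
  }
  vocab
}

#' @export
print.ms_dataset <- function(x, ...) {
  cat(sprintf(
    "<ms_dataset> %d spectra, %d compounds\n",
    nrow(x), dplyr::n_distinct(x$compound_id)
  ))
  NextMethod()
}

#' Dataset provenance and factor vocabularies
#' @param dataset An `ms_dataset`.
#' @return `ms_provenance()` returns the free-text provenance string;
#'   `ms_vocabularies()` the named list of categorical label vectors.
#' @export
ms_provenance <- function(dataset) attr(dataset, "provenance", exact = TRUE) %||% ""

#' @rdname ms_provenance
#' @export
ms_vocabularies <- function(dataset) attr(dataset, "factor_vocabularies", exact = TRUE) %||% list()

## ---------------------------------------------------------------------------
## Metadata key mapping shared by both dialects

normalize_key <- function(key) gsub("[^a-z0-9]", "", tolower(key))

KEY_ALIASES <- list(
  compound_id = c("inchikey", "compoundid", "id"),
  name = c("name", "title", "compoundname"),
  collision_energy = c("collisionenergy", "ce", "collisionenergyev"),
  total_exact_mass = c("totalexactmass", "exactmass", "monoisotopicmass"),
  precursor_mz = c("precursormz", "pepmass", "precursormass"),
  precursor_type = c("precursortype", "adduct"),
  instrument = c("instrument", "source_instrument"),
  instrument_type = c("instrumenttype"),
  ionization_mode = c("ionizationmode", "ionmode", "polarity", "mode"),
  kingdom = "kingdom",
  superclass = "superclass",
  class_ = "class",
  subclass = "subclass"
)

map_metadata <- function(meta) {
  keys <- normalize_key(names(meta))
  out <- list(other = list())
  for (i in seq_along(meta)) {
    hit <- NULL
    for (field in names(KEY_ALIASES)) {
      if (keys[[i]] %in% KEY_ALIASES[[field]]) {
        hit <- field
        break
      }
    }
    if (is.null(hit)) {
      out$other[[names(meta)[i]]] <- meta[[i]]
    } else {
      out[[hit]] <- meta[[i]]
    }
  }
  out
}

parse_numeric_factor <- function(x) {
  if (is.null(x) || !nzchar(x)) return(NA_real_)
  # best-effort: first numeric token (library CE strings carry units/ranges)
  m <- regmatches(x, regexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", x))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

normalize_ion_mode <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(NA_character_)
  x <- tolower(trimws(x))
  if (x %in% c("positive", "p", "+", "pos", "1+")) return("positive")
  if (x %in% c("negative", "n", "-", "neg", "1-")) return("negative")
  abort(sprintf("unrecognized ionization mode '%s'", x), class = "msvae_parse_error")
}

record_to_row <- function(meta, peaks, source_line) {
  mapped <- map_metadata(meta)
  ce_raw <- mapped$collision_energy %||% NA_character_
  tibble(
    spectrum_id = NA_character_,
    compound_id = as.character(mapped$compound_id %||% mapped$name %||% NA_character_),
    name = as.character(mapped$name %||% NA_character_),
    peaks = list(peaks),
    collision_energy = parse_numeric_factor(ce_raw),
    collision_energy_raw = as.character(ce_raw),
    total_exact_mass = parse_numeric_factor(mapped$total_exact_mass %||% NA_character_),
    precursor_mz = parse_numeric_factor(mapped$precursor_mz %||% NA_character_),
    precursor_type = as.character(mapped$precursor_type %||% NA_character_),
    instrument = as.character(mapped$instrument %||% NA_character_),
    instrument_type = as.character(mapped$instrument_type %||% NA_character_),
    ionization_mode = normalize_ion_mode(mapped$ionization_mode %||% NA_character_),
    kingdom = as.character(mapped$kingdom %||% NA_character_),
    superclass = as.character(mapped$superclass %||% NA_character_),
    class_ = as.character(mapped$class_ %||% NA_character_),
    subclass = as.character(mapped$subclass %||% NA_character_),
    other_metadata = list(mapped$other)
  )
}

parse_peak_line <- function(line, lineno) {
  parts <- strsplit(trimws(line), "[\t ;]+")[[1]]
  vals <- suppressWarnings(as.numeric(parts[1:2]))
  if (length(parts) < 2L || anyNA(vals)) {
    abort(sprintf("malformed peak line at line %d: '%s'", lineno, line),
      class = "msvae_parse_error"
    )
  }
  if (vals[1] <= 0 || vals[2] < 0) {
    abort(sprintf(
      "invalid peak at line %d: m/z must be > 0 and intensity >= 0 (got %g, %g)",
      lineno, vals[1], vals[2]
    ), class = "msvae_parse_error")
  }
  vals
}

## ---------------------------------------------------------------------------
## Readers

#' Read MS/MS spectra from an MSP or MGF library file
#'
#' Metadata keys are mapped case-insensitively onto the standard factor fields
#' (collision energy, precursor m/z, instrument labels, ionization mode,
#' taxonomy); unmapped keys are preserved per spectrum in the `other_metadata`
#' list-column. Collision-energy strings that carry units or ranges are kept
#' verbatim in `collision_energy_raw` with a best-effort numeric value in
#' `collision_energy`.
#'
#' @param path Path to the library file.
#' @param format `"msp"` (NIST-style `Name:`/`Num Peaks:` records) or `"mgf"`
#'   (`BEGIN IONS`/`END IONS` blocks).
#' @param code_maps Optional explicit categorical code maps passed on as
#'   dataset vocabularies (named integer vectors, names = labels).
#' @return An [ms_dataset()].
#' @export
read_spectra <- function(path, format = c("msp", "mgf"), code_maps = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- switch(format, msp = parse_msp(lines), mgf = parse_mgf(lines))
  if (!length(rows)) {
    abort(sprintf("no spectra found in %s", path), class = "msvae_empty_dataset")
  }
  spectra <- dplyr::bind_rows(rows)
  spectra$spectrum_id <- sprintf("spectrum_%04d", seq_len(nrow(spectra)))
  vocab <- NULL
  if (!is.null(code_maps)) {
    vocab <- lapply(code_maps, function(m) names(sort(m)))
    vocab <- utils::modifyList(build_vocabularies(ms_dataset(spectra)), vocab)
  }
  ds <- ms_dataset(spectra,
    provenance = sprintf("read_spectra(%s, format = '%s')", path, format),
    factor_vocabularies = vocab
  )
  if (!is.null(code_maps)) attr(ds, "code_maps") <- code_maps
  ds
}

parse_msp <- function(lines) {
  rows <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    meta <- list()
    # metadata lines until "Num Peaks:"
    npeaks <- NA_integer_
    while (i <= n && nzchar(trimws(lines[i]))) {
      line <- lines[i]
      m <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
      if (length(m) != 3L) {
        abort(sprintf("malformed metadata line at line %d: '%s'", i, line),
          class = "msvae_parse_error"
        )
      }
      key <- trimws(m[2])
      val <- trimws(m[3])
      i <- i + 1L
      if (normalize_key(key) == "numpeaks") {
        npeaks <- as.integer(val)
        break
      }
      meta[[key]] <- val
    }
    if (is.na(npeaks)) {
      abort("MSP record without a 'Num Peaks:' line", class = "msvae_parse_error")
    }
    pk <- matrix(NA_real_, npeaks, 2)
    for (j in seq_len(npeaks)) {
      while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
      if (i > n) abort("unexpected end of file inside peak list", class = "msvae_parse_error")
      pk[j, ] <- parse_peak_line(lines[i], i)
      i <- i + 1L
    }
    rows[[length(rows) + 1L]] <-
      record_to_row(meta, tibble(mz = pk[, 1], intensity = pk[, 2]), i)
  }
  rows
}

parse_mgf <- function(lines) {
  rows <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (toupper(trimws(lines[i])) != "BEGIN IONS") {
      i <- i + 1L
      next
    }
    i <- i + 1L
    meta <- list()
    pk <- list()
    while (i <= n && toupper(trimws(lines[i])) != "END IONS") {
      line <- trimws(lines[i])
      if (!nzchar(line)) {
        i <- i + 1L
        next
      }
      if (grepl("=", line, fixed = TRUE)) {
        key <- sub("=.*$", "", line)
        meta[[key]] <- sub("^[^=]*=", "", line)
      } else {
        pk[[length(pk) + 1L]] <- parse_peak_line(line, i)
      }
      i <- i + 1L
    }
    if (i > n) abort("BEGIN IONS without END IONS", class = "msvae_parse_error")
    i <- i + 1L
    if (!length(pk)) {
      abort("MGF block without peaks", class = "msvae_empty_spectrum")
    }
    pk <- do.call(rbind, pk)
    rows[[length(rows) + 1L]] <-
      record_to_row(meta, tibble(mz = pk[, 1], intensity = pk[, 2]), i)
  }
  rows
}

## ---------------------------------------------------------------------------
## Writers

#' Write an MS/MS dataset to an MSP or MGF library file
#'
#' Output round-trips through [read_spectra()]: m/z values are printed with 6
#' decimals and intensities with 4.
#'
#' @param dataset An [ms_dataset()].
#' @param path Output file path.
#' @param format `"msp"` or `"mgf"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(dataset, path, format = c("msp", "mgf")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "ms_dataset"))
  lapply(dataset$peaks, validate_peaks)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  fmt_num <- function(x) formatC(x, format = "fg", digits = 15)
  for (r in seq_len(nrow(dataset))) {
    row <- dataset[r, ]
    peaks <- row$peaks[[1]]
    meta <- c(
      Name = row$name %||% row$compound_id,
      InChIKey = row$compound_id,
      Collision_energy = if (!is.na(row$collision_energy)) fmt_num(row$collision_energy),
      Total_exact_mass = if (!is.na(row$total_exact_mass)) fmt_num(row$total_exact_mass),
      PrecursorMZ = if (!is.na(row$precursor_mz)) fmt_num(row$precursor_mz),
      Precursor_type = row$precursor_type,
      Instrument = row$instrument,
      Instrument_type = row$instrument_type,
      Ionization_mode = row$ionization_mode,
      Kingdom = row$kingdom,
      Superclass = row$superclass,
      Class = row$class_,
      Subclass = row$subclass
    )
    meta <- meta[!is.na(meta) & nzchar(meta)]
    peak_lines <- sprintf(
      "%s %s",
      formatC(peaks$mz, format = "f", digits = 6),
      formatC(peaks$intensity, format = "f", digits = 4)
    )
    if (format == "msp") {
      writeLines(c(
        paste0(names(meta), ": ", meta),
        sprintf("Num Peaks: %d", nrow(peaks)),
        peak_lines, ""
      ), con)
    } else {
      keys <- toupper(names(meta))
      keys[keys == "NAME"] <- "TITLE"
      keys[keys == "PRECURSORMZ"] <- "PEPMASS"
      writeLines(c(
        "BEGIN IONS",
        paste0(keys, "=", meta),
        peak_lines,
        "END IONS", ""
      ), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Factor encoding

#' Encode dataset factors as a numeric matrix
#'
#' Numeric factors are passed through unchanged (missing values stay `NA` and
#' are reported, never imputed). Categorical factors are coded as integers
#' using the dataset vocabularies (first-appearance order) or an explicit code
#' map, so analyses that run Pearson correlation on label codes are
#' reproducible.
#'
#' @param dataset An [ms_dataset()].
#' @param code_maps Optional named list; each element is a named integer vector
#'   mapping labels to codes for one categorical factor, e.g.
#'   `list(instrument_type = c("ESI-QFT" = 0, "LC-ESI-QTOF" = 1))`.
#' @param factors Factor columns to encode (default: all standard factors
#'   present with at least one observed value).
#' @return A numeric matrix (rows = spectra, columns = factors) with the code
#'   maps used attached as the `code_maps` attribute and the count of missing
#'   values per column as `n_missing`.
#' @export
encode_factors <- function(dataset, code_maps = NULL, factors = NULL) {
  stopifnot(inherits(dataset, "ms_dataset"))
  code_maps <- code_maps %||% attr(dataset, "code_maps", exact = TRUE) %||% list()
  vocab <- ms_vocabularies(dataset)
  if (is.null(factors)) {
    factors <- MS_FACTORS[vapply(MS_FACTORS, function(f) any(!is.na(dataset[[f]])), logical(1))]
  }
  cols <- list()
  used_maps <- list()
  for (f in factors) {
    x <- dataset[[f]]
    if (f %in% MS_NUMERIC_FACTORS) {
      cols[[f]] <- as.numeric(x)
    } else {
      map <- code_maps[[f]]
      if (is.null(map)) {
        labs <- vocab[[f]] %||% unique(x[!is.na(x)])
        map <- setNames(seq_along(labs) - 1L, labs)
      }
      bad <- setdiff(unique(x[!is.na(x)]), names(map))
      if (length(bad)) {
        abort(sprintf(
          "factor '%s' has labels outside the code map: %s",
          f, paste(bad, collapse = ", ")
        ), class = "msvae_coding_error")
      }
      cols[[f]] <- unname(map[x])
      used_maps[[f]] <- map
    }
  }
  out <- if (length(cols)) {
    do.call(cbind, cols)
  } else {
    matrix(numeric(), nrow(dataset), 0L)
  }
  rownames(out) <- dataset$spectrum_id
  structure(out,
    code_maps = used_maps,
    n_missing = colSums(is.na(out))
  )
}

#' Decode integer-coded categorical factors back to labels
#'
#' @param codes Numeric vector of codes for one factor.
#' @param code_map Named integer vector (labels -> codes), e.g. from the
#'   `code_maps` attribute of [encode_factors()].
#' @return Character vector of labels.
#' @export
decode_factor <- function(codes, code_map) {
  idx <- match(codes, code_map)
  if (any(is.na(idx) & !is.na(codes))) {
    abort("codes outside the code map", class = "msvae_coding_error")
  }
  names(code_map)[idx]
}
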