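# Small in-code fixtures shared across test files.

make_peaks <- function(mz, intensity) tibble::tibble(mz = mz, intensity = intensity)

# a tiny two-spectrum dataset with full metadata
toy_dataset <- function() {
  ms_dataset(tibble::tibble(
    compound_id = c("AAAA-KEY", "BBBB-KEY"),
    name = c("alanine", "citrate"),
    peaks = list(
      make_peaks(c(90.055, 44.05, 72.044), c(100, 60, 20)),
      make_peaks(c(191.019, 111.008, 87.008), c(100, 80, 35))
    ),
    collision_energy = c(40, 20),
    total_exact_mass = c(89.048, 192.027),
    precursor_mz = c(90.055, 191.019),
    precursor_type = c("[M+H]+", "[M-H]-"),
    instrument = c("QTOF-1", "QFT-2"),
    instrument_type = c("LC-ESI-QTOF", "ESI-QFT"),
    ionization_mode = c("positive", "negative"),
    kingdom = c("Organic compounds", "Organic compounds"),
    superclass = c("Organic acids", "Organic acids"),
    class_ = c("Amino acids", "TCA acids"),
    subclass = c(NA, NA)
  ), provenance = "toy fixture")
}

# random peak lists for property-style tests
random_peaks <- function(n_peaks, max_mz = 1000) {
  make_peaks(
    mz = runif(n_peaks, 10, max_mz),
    intensity = runif(n_peaks, 0, 100)
  )
}

# brute-force oracle for the filter/rescale/vectorize pipeline, written
# independently of the implementation (explicit loops, no shared helpers)
oracle_preprocess <- function(peaks, cfg) {
  mz <- peaks$mz
  it <- peaks$intensity
  rel <- it / max(it) * 100
  keep <- rel >= cfg$min_intensity
  mz <- mz[keep]
  it <- it[keep]
  keep2 <- mz <= cfg$max_mz
  mz <- mz[keep2]
  it <- it[keep2]
  if (!length(mz)) {
    return(NULL)
  }
  ord <- order(-it, mz)
  if (length(ord) > cfg$max_num_peaks) ord <- ord[1:cfg$max_num_peaks]
  mz <- mz[ord]
  it <- it[ord]
  if (cfg$rescale_intensity && length(it) > 1 && max(it) > min(it)) {
    it <- cfg$min_intensity + (it - min(it)) / (max(it) - min(it)) * (100 - cfg$min_intensity)
  } else if (cfg$rescale_intensity && length(it) > 1) {
    it <- rep(100, length(it))
  } else {
    it <- it / max(it) * 100
  }
  cells <- numeric(2 * cfg$max_num_peaks)
  for (i in seq_along(mz)) {
    v <- mz[i] / cfg$mz_reference
    cells[2 * i - 1] <- min(max(v, 0), 1)
    cells[2 * i] <- it[i] / 100
  }
  cells
}

# a quickly trainable synthetic setup shared by model-level tests
small_training_setup <- function(n_compounds = 60, seed = 11, max_num_peaks = 10) {
  cfg <- generator_config(
    n_compounds = n_compounds, design = "mona_like",
    collision_energies = seq(10, 50, 10),
    instrument_types = c("LC-ESI-QTOF", "ESI-QFT"),
    spectra_per_compound = 4, seed = seed
  )
  ds <- generate_dataset(cfg)
  pcfg <- preprocess_config(max_num_peaks = max_num_peaks, max_mz = 600)
  prep <- preprocess_dataset(ds, pcfg)
  list(cfg = cfg, dataset = ds, pcfg = pcfg, prep = prep)
}
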