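# Seeded synthetic MS/MS spectra with known, controllable factors of
# generation. The generator exists so that every downstream stage --
# especially disentanglement recovery -- is testable without any download.
#
# Factor effects are applied in separable steps so the factors are independent
# by construction (the assumption the disentanglement machinery makes):
#   * collision energy re-weights fragment channels toward more, lower-mass
#     fragments as energy rises (softmax logit shift scaled by energy_slope);
#   * instrument type applies a fixed multiplicative gain signature over a
#     coarse m/z grid;
#   * ionization mode shifts all m/z by +/- one proton mass;
#   * multiplicative log-normal noise perturbs intensities.

#' Synthetic-spectrum generator configuration
#'
#' @param n_compounds Number of compound templates.
#' @param mass_range Exact-mass range (low, high), Da.
#' @param collision_energies Collision-energy levels available to the design.
#' @param instrument_types Character vector of instrument-type labels; each
#'   gets its own intensity-distortion signature.
#' @param instrument_weights Sampling weights over instrument types for the
#'   unbalanced `mona_like` design (recycled/normalized).
#' @param ionization_modes Subset of `c("positive", "negative")`.
#' @param energy_slope Strength of the collision-energy response; 0 switches
#'   the mass shift off.
#' @param instrument_distortion_sd Log-scale SD of each instrument's gain
#'   signature.
#' @param noise_sd SD of the multiplicative log-normal intensity noise.
#' @param design `"hmdb_like"` (balanced: exactly 6 spectra per compound, 2
#'   ionization modes x collision energies 10/20/40, one instrument) or
#'   `"mona_like"` (unbalanced multi-instrument, multi-energy draws).
#' @param spectra_per_compound Spectra drawn per compound in the `mona_like`
#'   design.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_compounds = 100,
                             mass_range = c(150, 500),
                             collision_energies = c(10, 20, 40),
                             instrument_types = c(
                               "LC-ESI-QTOF", "ESI-QFT", "LC-ESI-ITFT",
                               "LC-ESI-QFT", "Linear Ion Trap"
                             ),
                             instrument_weights = NULL,
                             ionization_modes = c("positive", "negative"),
                             energy_slope = 0.08,
                             instrument_distortion_sd = 0.6,
                             noise_sd = 0.1,
                             design = c("hmdb_like", "mona_like"),
                             spectra_per_compound = 6,
                             seed = 1L) {
  design <- match.arg(design)
  stopifnot(
    length(mass_range) == 2L, mass_range[1] < mass_range[2],
    noise_sd >= 0, energy_slope >= 0, n_compounds >= 0
  )
  if (is.null(instrument_weights)) {
    instrument_weights <- rep(1, length(instrument_types))
  }
  instrument_weights <- rep_len(instrument_weights, length(instrument_types))
  structure(
    list(
      n_compounds = as.integer(n_compounds),
      mass_range = mass_range,
      collision_energies = collision_energies,
      instrument_types = instrument_types,
      instrument_weights = instrument_weights / sum(instrument_weights),
      ionization_modes = ionization_modes,
      energy_slope = energy_slope,
      instrument_distortion_sd = instrument_distortion_sd,
      noise_sd = noise_sd,
      design = design,
      spectra_per_compound = as.integer(spectra_per_compound),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Generate a library of compound fragmentation templates
#'
#' Each template holds an exact mass (uniform over the configured range),
#' 10-40 fragment channels at fractions of the exact mass, and positive
#' channel propensities. Fully determined by the configuration seed.
#'
#' @param cfg A [generator_config()].
#' @return Tibble with one row per compound: `compound_id`, `exact_mass`,
#'   `fragment_masses` and `fragment_propensities` list-columns.
#' @export
generate_library <- function(cfg) {
  if (cfg$n_compounds == 0L) {
    return(tibble(
      compound_id = character(), exact_mass = numeric(),
      fragment_masses = list(), fragment_propensities = list()
    ))
  }
  withr::with_seed(cfg$seed, {
    exact_mass <- runif(cfg$n_compounds, cfg$mass_range[1], cfg$mass_range[2])
    n_frag <- sample(10:40, cfg$n_compounds, replace = TRUE)
    tibble(
      compound_id = sprintf("SYN-%05d", seq_len(cfg$n_compounds)),
      exact_mass = exact_mass,
      fragment_masses = lapply(seq_len(cfg$n_compounds), function(i) {
        sort(runif(n_frag[i], 0.05, 0.98) * exact_mass[i])
      }),
      fragment_propensities = lapply(seq_len(cfg$n_compounds), function(i) {
        rgamma(n_frag[i], shape = 1.5, rate = 1)
      })
    )
  })
}

# deterministic per-instrument gain signature over a coarse m/z grid
instrument_gain <- function(instrument_type, cfg, mz) {
  idx <- match(instrument_type, cfg$instrument_types)
  if (is.na(idx)) abort(sprintf("unknown instrument type '%s'", instrument_type))
  grid_width <- 25 # Da per gain cell
  n_cells <- ceiling((cfg$mass_range[2] + grid_width) / grid_width)
  gains <- withr::with_seed(cfg$seed + 7919L * idx, {
    exp(rnorm(n_cells, 0, cfg$instrument_distortion_sd))
  })
  gains[pmin(floor(mz / grid_width) + 1L, n_cells)]
}

#' Generate one synthetic spectrum from a compound template
#'
#' Collision energy shifts the softmax channel weights by
#' `-energy_slope * CE * (fragment_mass / exact_mass)` and raises the number
#' of included channels, reproducing the qualitative fragmentation law that
#' low energy gives a few peaks at higher masses and high energy gives more
#' peaks at lower masses. Instrument type multiplies intensities by its gain
#' signature, ionization mode shifts all m/z by one proton mass, and
#' log-normal noise with SD `noise_sd` perturbs intensities.
#'
#' @param template One-row slice of [generate_library()] output (or a list
#'   with the same fields).
#' @param factors List/row with at least `collision_energy`,
#'   `instrument_type`, `ionization_mode`.
#' @param cfg A [generator_config()].
#' @param seed Integer seed for this spectrum's noise draws.
#' @return A peak tibble (`mz`, `intensity`), base peak normalized to 100.
#' @export
generate_spectrum <- function(template, factors, cfg, seed = 1L) {
  masses <- template$fragment_masses[[1]]
  prop <- template$fragment_propensities[[1]]
  exact_mass <- template$exact_mass[[1]]
  ce <- factors$collision_energy
  ce_max <- max(cfg$collision_energies, 50)

  # channel weights: softmax of log-propensity with an energy-dependent
  # penalty that grows with fragment mass
  logits <- log(prop) - cfg$energy_slope * ce * (masses / exact_mass)
  w <- exp(logits - max(logits))
  w <- w / sum(w)

  # higher energy opens more fragmentation channels; selection is by channel
  # weight, which is mass-independent when energy_slope = 0
  frac <- 0.3 + 0.7 * pmin(ce / ce_max, 1)
  k <- max(3L, min(length(masses), round(frac * length(masses))))
  keep <- order(-w)[seq_len(k)]
  keep <- sort(keep)

  mz <- masses[keep]
  intensity <- w[keep]
  intensity <- intensity * instrument_gain(factors$instrument_type, cfg, mz)
  mz <- mz + if (identical(factors$ionization_mode, "negative")) -PROTON_MASS else PROTON_MASS
  if (cfg$noise_sd > 0) {
    intensity <- intensity * withr::with_seed(seed, exp(rnorm(length(intensity), 0, cfg$noise_sd)))
  }
  tibble(mz = mz, intensity = intensity / max(intensity) * 100)
}

#' Generate a complete synthetic dataset
#'
#' `hmdb_like`: exactly 6 spectra per compound (2 ionization modes crossed
#' with collision energies 10/20/40 by default), a single instrument type, and
#' perfectly balanced modes. `mona_like`: `spectra_per_compound` random
#' factor combinations per compound, instruments drawn with the configured
#' imbalance weights and collision energies drawn uniformly from the
#' configured levels.
#'
#' @param cfg A [generator_config()].
#' @return An [ms_dataset()] with every factor field populated.
#' @export
generate_dataset <- function(cfg) {
  lib <- generate_library(cfg)
  if (nrow(lib) == 0L) abort("empty library", class = "msvae_empty_dataset")

  taxonomy <- c("Benzenoids", "Lipids", "Organic acids", "Organoheterocyclics")
  design <- withr::with_seed(cfg$seed + 1L, {
    if (cfg$design == "hmdb_like") {
      grid <- expand.grid(
        ionization_mode = cfg$ionization_modes[1:2],
        collision_energy = cfg$collision_energies,
        stringsAsFactors = FALSE
      )
      df <- merge(data.frame(compound_id = lib$compound_id), grid)
      df$instrument_type <- cfg$instrument_types[1]
      df
    } else {
      n <- nrow(lib) * cfg$spectra_per_compound
      data.frame(
        compound_id = rep(lib$compound_id, each = cfg$spectra_per_compound),
        ionization_mode = sample(cfg$ionization_modes, n, replace = TRUE),
        collision_energy = sample(cfg$collision_energies, n, replace = TRUE),
        instrument_type = sample(cfg$instrument_types, n,
          replace = TRUE, prob = cfg$instrument_weights
        )
      )
    }
  })
  design <- design[order(match(design$compound_id, lib$compound_id)), ]
  row.names(design) <- NULL

  lib_idx <- match(design$compound_id, lib$compound_id)
  spectra <- lapply(seq_len(nrow(design)), function(i) {
    generate_spectrum(
      lib[lib_idx[i], ],
      as.list(design[i, ]),
      cfg,
      seed = cfg$seed + 31L * i
    )
  })
  mass <- lib$exact_mass[lib_idx]
  positive <- design$ionization_mode == "positive"
  ds <- tibble(
    compound_id = design$compound_id,
    name = design$compound_id,
    peaks = spectra,
    collision_energy = design$collision_energy,
    collision_energy_raw = as.character(design$collision_energy),
    total_exact_mass = mass,
    precursor_mz = mass + ifelse(positive, PROTON_MASS, -PROTON_MASS),
    precursor_type = ifelse(positive, "[M+H]+", "[M-H]-"),
    instrument = paste0(design$instrument_type, " #1"),
    instrument_type = design$instrument_type,
    ionization_mode = design$ionization_mode,
    kingdom = "Organic compounds",
    superclass = taxonomy[(lib_idx %% length(taxonomy)) + 1L],
    class_ = paste0(taxonomy[(lib_idx %% length(taxonomy)) + 1L], " class"),
    subclass = NA_character_
  )
  ms_dataset(ds, provenance = sprintf(
    "synthetic %s design, %d compounds, seed %d",
    cfg$design, cfg$n_compounds, cfg$seed
  ))
}
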