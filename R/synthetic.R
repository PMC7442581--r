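#' Species names used by the synthetic generator
#'
#' Five Pooideae grasses with near-identical pollen morphology; the pairs
#' (A. odoratum, P. alpina) and (B. inermis, H. bulbosum) are chemically
#' close, which is what makes single-grain classification non-trivial.
#' @return character vector of length 5
#' @export
pollen_species <- function() {
  c("A_odoratum", "B_inermis", "H_bulbosum", "L_perenne", "P_alpina")
}

# shared band positions (cm^-1) and widths of the pollen fingerprint:
# carbohydrates (989, 1045, 1331), lipids/carbohydrates (1161),
# phospholipid P=O (1236), COO- of amino acids (1408), amide II (1549),
# amide I (1659), lipid ester C=O (1745)
pollen_band_centers <- c(989, 1045, 1161, 1236, 1331, 1408, 1549, 1659, 1745)
pollen_band_fwhm    <- c(28, 30, 26, 24, 26, 24, 28, 32, 22)

#' Default species band library
#'
#' Returns one profile per species: Gaussian band amplitudes over the nine
#' fingerprint bands plus the species' mean paraffin mass fraction. The
#' smaller-grained species (P. alpina, A. odoratum) take up the most
#' embedding paraffin per probed volume and H. bulbosum the least, so the
#' fraction means are ordered
#' P. alpina ~ A. odoratum > B. inermis ~ L. perenne > H. bulbosum.
#'
#' @return named list of profiles, each a list with elements `name`,
#'   `bands` (data frame `center`, `fwhm`, `amplitude`),
#'   `paraffin_fraction_mean`, `paraffin_fraction_sd`
#' @export
default_band_library <- function() {
  amp <- rbind(
    A_odoratum = c(1.00, 0.78, 0.45, 0.20, 0.34, 0.24, 0.55, 0.88, 0.16),
    B_inermis  = c(0.72, 1.00, 0.62, 0.36, 0.18, 0.22, 0.36, 0.58, 0.34),
    H_bulbosum = c(0.82, 0.94, 0.50, 0.28, 0.26, 0.16, 0.48, 0.68, 0.26),
    L_perenne  = c(0.90, 0.88, 0.54, 0.24, 0.22, 0.30, 0.40, 0.74, 0.28),
    P_alpina   = c(0.92, 0.86, 0.36, 0.30, 0.28, 0.34, 0.50, 0.80, 0.20)
  )
  f_mean <- c(A_odoratum = 0.27, B_inermis = 0.19, H_bulbosum = 0.12,
              L_perenne = 0.18, P_alpina = 0.26)
  # the relative paraffin contribution varies strongly between grains of
  # one species (reported component shares of ~25 +/- 9 percent), so the
  # per-grain sd is about a third of the largest mean
  out <- lapply(pollen_species(), function(sp) {
    list(
      name = sp,
      bands = data.frame(center = pollen_band_centers,
                         fwhm = pollen_band_fwhm,
                         amplitude = amp[sp, ]),
      paraffin_fraction_mean = unname(f_mean[sp]),
      paraffin_fraction_sd = 0.09
    )
  })
  names(out) <- pollen_species()
  out
}

#' Sum-of-Gaussians constituent spectrum
#'
#' Each band contributes `amplitude * exp(-4 ln 2 (nu - center)^2 / fwhm^2)`
#' so that `amplitude` is the peak height and `fwhm` the full width at half
#' maximum in cm^-1.
#'
#' @param bands data frame with columns `center`, `fwhm`, `amplitude`
#' @param axis numeric wavenumber axis
#' @return non-negative absorbance vector on `axis`
#' @export
gaussian_mixture_spectrum <- function(bands, axis) {
  y <- numeric(length(axis))
  if (is.null(bands) || nrow(bands) == 0) return(y)
  stopifnot(all(bands$fwhm > 0), all(bands$amplitude >= 0))
  for (b in seq_len(nrow(bands))) {
    y <- y + bands$amplitude[b] *
      exp(-4 * log(2) * (axis - bands$center[b])^2 / bands$fwhm[b]^2)
  }
  y
}

#' Pure soft-paraffin constituent spectrum
#'
#' Dominated by the CH2 bending / CH3 deformation band at 1462 cm^-1 and
#' the CH3 rocking band at 1377 cm^-1; scaled to unit maximum.
#'
#' @param axis numeric wavenumber axis
#' @return non-negative vector on `axis` with maximum 1
#' @export
paraffin_reference <- function(axis = default_axis()) {
  bands <- data.frame(center = c(1377, 1462),
                      fwhm = c(18, 24),
                      amplitude = c(0.55, 1.00))
  y <- gaussian_mixture_spectrum(bands, axis)
  y / max(y)
}

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the single-grain study design: 5 species x 2
#' populations x 5 plants x 20 grains = 1000 embedded pollen spectra, 190
#' pure-paraffin spectra and one unembedded plant per species (100
#' spectra), on a 519-point axis over 800-1800 cm^-1. Band-amplitude
#' perturbations are hierarchical log-normals with population > plant >
#' grain spread, so population hold-out is genuinely harder than
#' leave-one-out. The paraffin fraction of each grain is a clipped normal
#' around the species mean, with an additional population-level offset
#' (grain morphology, which sets the paraffin share, varies between
#' populations too).
#'
#' @param axis_lo,axis_hi,axis_n axis specification (cm^-1, point count)
#' @param species list of species profiles as from [default_band_library()]
#' @param plants_per_population,grains_per_plant design counts
#' @param n_paraffin_spectra number of pure paraffin spectra
#' @param grains_per_unembedded_plant unembedded spectra per species (one
#'   plant each)
#' @param population_shift_sd,plant_shift_sd,grain_shift_sd log-normal sd
#'   of the band-amplitude multipliers at each level of the hierarchy
#' @param population_paraffin_sd sd of the population-level offset on the
#'   paraffin fraction
#' @param baseline_degree,baseline_coef_sd polynomial baseline (degree,
#'   coefficient sd) on the axis mapped to [-1, 1]
#' @param unembedded_baseline_factor multiplier on `baseline_coef_sd` for
#'   unembedded spectra, which additionally get a broad sinusoidal
#'   scatter-like component
#' @param scale_sd log-normal sd of the multiplicative path-length scale
#' @param noise_sd sd of iid additive noise (absorbance units)
#' @param seed integer; fully determines the generated data
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(axis_lo = 800, axis_hi = 1800, axis_n = 519L,
                             species = default_band_library(),
                             plants_per_population = 5L,
                             grains_per_plant = 20L,
                             n_paraffin_spectra = 190L,
                             grains_per_unembedded_plant = 20L,
                             population_shift_sd = 0.08,
                             plant_shift_sd = 0.04,
                             grain_shift_sd = 0.03,
                             population_paraffin_sd = 0.05,
                             baseline_degree = 2L,
                             baseline_coef_sd = 0.02,
                             unembedded_baseline_factor = 5,
                             scale_sd = 0.10,
                             noise_sd = 0.004,
                             seed = 1L) {
  cfg <- list(axis_lo = axis_lo, axis_hi = axis_hi, axis_n = as.integer(axis_n),
              species = species,
              plants_per_population = as.integer(plants_per_population),
              grains_per_plant = as.integer(grains_per_plant),
              n_paraffin_spectra = as.integer(n_paraffin_spectra),
              grains_per_unembedded_plant = as.integer(grains_per_unembedded_plant),
              population_shift_sd = population_shift_sd,
              plant_shift_sd = plant_shift_sd,
              grain_shift_sd = grain_shift_sd,
              population_paraffin_sd = population_paraffin_sd,
              baseline_degree = as.integer(baseline_degree),
              baseline_coef_sd = baseline_coef_sd,
              unembedded_baseline_factor = unembedded_baseline_factor,
              scale_sd = scale_sd, noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  bad <- character()
  sds <- c("population_shift_sd", "plant_shift_sd", "grain_shift_sd",
           "population_paraffin_sd", "baseline_coef_sd", "scale_sd",
           "noise_sd")
  for (f in sds) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) bad <- c(bad, f)
  cnt <- c("plants_per_population", "grains_per_plant",
           "n_paraffin_spectra", "grains_per_unembedded_plant", "axis_n")
  for (f in cnt) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) bad <- c(bad, f)
  if (cfg$axis_lo >= cfg$axis_hi) bad <- c(bad, "axis_lo/axis_hi")
  if (!length(cfg$species)) bad <- c(bad, "species")
  for (sp in cfg$species) {
    m <- sp$paraffin_fraction_mean; s <- sp$paraffin_fraction_sd
    if (m < 0 || m > 1 || s < 0) bad <- c(bad, paste0("species:", sp$name))
  }
  if (length(bad)) {
    stop("invalid synthetic_config fields: ", paste(unique(bad), collapse = ", "))
  }
  invisible(cfg)
}

# evaluate code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic single-grain FTIR study
#'
#' Simulates the measurement model
#' `y = scale * ((1 - f) * pollen + f * paraffin) + baseline + noise`
#' for every grain, where `pollen` is the species band spectrum with
#' hierarchical (population, plant, grain) log-normal amplitude
#' perturbations and `f` is the grain's paraffin mass fraction (clipped
#' normal around the species mean plus a population offset). Pure paraffin
#' spectra are `scale * paraffin + baseline + noise`; unembedded spectra
#' use inflated polynomial baselines plus a broad sinusoid, mimicking the
#' scatter-distorted spectra seen without embedding.
#'
#' @param config a [synthetic_config()]
#' @return list with elements `embedded`, `paraffin`, `unembedded`
#'   ([spectra_set]s) and `truth` (data frame with the true `f`, `scale`,
#'   baseline coefficients and effective band amplitudes per spectrum)
#' @export
generate_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  axis <- seq(cfg$axis_lo, cfg$axis_hi, length.out = cfg$axis_n)
  t01 <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  par_ref <- paraffin_reference(axis)
  nb <- length(pollen_band_centers)
  deg <- cfg$baseline_degree
  poly_basis <- sapply(0:deg, function(d) t01^d)   # axis_n x (deg+1)

  rand_baseline <- function(coef_sd) {
    coefs <- stats::rnorm(deg + 1, 0, coef_sd)
    list(coefs = coefs, y = as.vector(poly_basis %*% coefs))
  }

  rows <- list(); truth <- list(); k <- 0
  add <- function(y, meta, tr) {
    k <<- k + 1
    rows[[k]] <<- y
    meta$spectrum_id <- tr$spectrum_id
    truth[[k]] <<- cbind(meta,
                         as.data.frame(tr[setdiff(names(tr), "spectrum_id")]))
  }

  # gaussian basis shared by all species (unit-amplitude bands)
  gbasis <- sapply(seq_len(nb), function(b) {
    exp(-4 * log(2) * (axis - pollen_band_centers[b])^2 /
          pollen_band_fwhm[b]^2)
  })                                               # axis_n x nb

  emb_meta <- list(); emb_idx <- integer()
  for (sp in cfg$species) {
    base_amp <- sp$bands$amplitude
    for (pop in 1:2) {
      pop_mult <- exp(stats::rnorm(nb, 0, cfg$population_shift_sd))
      pop_f <- stats::rnorm(1, 0, cfg$population_paraffin_sd)
      for (pl in seq_len(cfg$plants_per_population)) {
        plant_mult <- exp(stats::rnorm(nb, 0, cfg$plant_shift_sd))
        plant_id <- sprintf("%s_pop%d_pl%d", sp$name, pop, pl)
        for (g in seq_len(cfg$grains_per_plant)) {
          grain_mult <- exp(stats::rnorm(nb, 0, cfg$grain_shift_sd))
          amps <- base_amp * pop_mult * plant_mult * grain_mult
          f <- clip01(stats::rnorm(1, sp$paraffin_fraction_mean + pop_f,
                                   sp$paraffin_fraction_sd))
          scale <- exp(stats::rnorm(1, 0, cfg$scale_sd))
          bl <- rand_baseline(cfg$baseline_coef_sd)
          noise <- stats::rnorm(cfg$axis_n, 0, cfg$noise_sd)
          pollen <- as.vector(gbasis %*% amps)
          y <- scale * ((1 - f) * pollen + f * par_ref) + bl$y + noise
          sid <- sprintf("%s_g%02d", plant_id, g)
          add(y,
              data.frame(species = sp$name, population = pop,
                         plant_id = plant_id,
                         grain_id = sprintf("g%02d", g),
                         sample_type = "embedded_pollen"),
              c(list(spectrum_id = sid, f = f, scale = scale),
                stats::setNames(as.list(bl$coefs), paste0("b", 0:deg)),
                stats::setNames(as.list(amps), paste0("amp", seq_len(nb)))))
          emb_idx <- c(emb_idx, k)
        }
      }
    }
  }
  n_emb <- k

  for (i in seq_len(cfg$n_paraffin_spectra)) {
    scale <- exp(stats::rnorm(1, 0, cfg$scale_sd))
    bl <- rand_baseline(cfg$baseline_coef_sd)
    noise <- stats::rnorm(cfg$axis_n, 0, cfg$noise_sd)
    y <- scale * par_ref + bl$y + noise
    add(y,
        data.frame(species = NA_character_, population = NA_integer_,
                   plant_id = NA_character_,
                   grain_id = NA_character_, sample_type = "pure_paraffin"),
        c(list(spectrum_id = sprintf("paraffin_%03d", i), f = 1,
               scale = scale),
          stats::setNames(as.list(bl$coefs), paste0("b", 0:deg)),
          stats::setNames(as.list(rep(NA_real_, nb)),
                          paste0("amp", seq_len(nb)))))
  }
  n_par <- k - n_emb

  for (sp in cfg$species) {
    base_amp <- sp$bands$amplitude
    plant_mult <- exp(stats::rnorm(nb, 0, cfg$plant_shift_sd))
    plant_id <- sprintf("%s_unemb_pl1", sp$name)
    for (g in seq_len(cfg$grains_per_unembedded_plant)) {
      grain_mult <- exp(stats::rnorm(nb, 0, cfg$grain_shift_sd))
      amps <- base_amp * plant_mult * grain_mult
      scale <- exp(stats::rnorm(1, 0, cfg$scale_sd))
      bl <- rand_baseline(cfg$baseline_coef_sd *
                            cfg$unembedded_baseline_factor)
      period <- stats::runif(1, 600, 1200)
      phase <- stats::runif(1, 0, 2 * pi)
      sin_amp <- stats::rnorm(1, 0, cfg$baseline_coef_sd *
                                cfg$unembedded_baseline_factor)
      scatter <- sin_amp * sin(2 * pi * (axis - min(axis)) / period + phase)
      noise <- stats::rnorm(cfg$axis_n, 0, cfg$noise_sd)
      y <- scale * as.vector(gbasis %*% amps) + bl$y + scatter + noise
      add(y,
          data.frame(species = sp$name, population = 1L,
                     plant_id = plant_id, grain_id = sprintf("g%02d", g),
                     sample_type = "unembedded_pollen"),
          c(list(spectrum_id = sprintf("%s_g%02d", plant_id, g), f = 0,
                 scale = scale),
            stats::setNames(as.list(bl$coefs), paste0("b", 0:deg)),
            stats::setNames(as.list(amps), paste0("amp", seq_len(nb)))))
    }
  }
  n_unemb <- k - n_emb - n_par

  amat <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  make_set <- function(idx, tag) {
    m <- truth[idx, c("spectrum_id", "species", "population", "plant_id",
                      "grain_id", "sample_type")]
    spectra_set(amat[idx, , drop = FALSE], axis, m,
                provenance = sprintf("synthetic %s (seed %d)", tag,
                                     cfg$seed))
  }
  list(
    embedded = make_set(seq_len(n_emb), "embedded_pollen"),
    paraffin = make_set(n_emb + seq_len(n_par), "pure_paraffin"),
    unembedded = make_set(n_emb + n_par + seq_len(n_unemb),
                          "unembedded_pollen"),
    truth = truth
  )
}
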