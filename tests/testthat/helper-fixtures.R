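# small fixtures shared across test files; everything is generated in code

toy_axis <- function(n = 101, lo = 800, hi = 1800) seq(lo, hi, length.out = n)

# a 3-spectrum set with full metadata on a short axis
toy_set <- function(n = 3, axis = toy_axis()) {
  set.seed(42)
  amat <- matrix(runif(n * length(axis)), n)
  meta <- data.frame(
    spectrum_id = sprintf("sp%d", seq_len(n)),
    species = rep(pollen_species(), length.out = n),
    population = rep(1:2, length.out = n),
    plant_id = sprintf("pl%d", seq_len(n)),
    grain_id = sprintf("g%d", seq_len(n)),
    sample_type = "embedded_pollen"
  )
  spectra_set(amat, axis, meta)
}

# small but structurally complete synthetic study
small_config <- function(seed = 1, ...) {
  synthetic_config(grains_per_plant = 4, n_paraffin_spectra = 30,
                   grains_per_unembedded_plant = 4, seed = seed, ...)
}

# two well-separated Gaussian classes in a modest feature space
separable_classes <- function(n_per = 15, p = 30, gap = 10, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  X[seq_len(n_per), 1] <- X[seq_len(n_per), 1] + gap
  list(X = X, y = factor(rep(c("a", "b"), each = n_per)))
}
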