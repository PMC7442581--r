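#' Asymmetric least squares (AsLS) baseline parameters
#'
#' The baseline `z` minimises `sum_i w_i (y_i - z_i)^2 + lambda ||D2 z||^2`
#' with asymmetric weights `w_i = p` above the baseline and `1 - p` below,
#' iterated to convergence. Defaults (`lambda = 1e6`, `p = 0.001`) are
#' tuned for ~500-point mid-infrared absorbance spectra: stiff enough to
#' ignore absorption bands, flexible enough to follow slow offsets.
#'
#' @param lambda smoothness penalty, > 0
#' @param p asymmetry weight in (0, 1)
#' @param max_iter maximum reweighting iterations
#' @return an `asls_params` list
#' @export
asls_params <- function(lambda = 1e6, p = 0.001, max_iter = 20L) {
  stopifnot(lambda > 0, p > 0, p < 1, max_iter >= 1)
  structure(list(lambda = lambda, p = p, max_iter = as.integer(max_iter)),
            class = "asls_params")
}

#' AsLS baseline correction of a single spectrum
#'
#' Whittaker-smoother implementation using sparse second differences.
#' Iteration stops when the above/below-baseline weight pattern no longer
#' changes; non-convergence within `max_iter` sets `converged = FALSE`
#' rather than raising an error.
#'
#' @param y finite absorbance vector, length >= 5
#' @param params an [asls_params()]
#' @return list with `baseline`, `corrected` (= `y - baseline`),
#'   `converged`, `iterations`
#' @export
asls_baseline <- function(y, params = asls_params()) {
  if (anyNA(y) || !all(is.finite(y))) stop("input must be finite")
  m <- length(y)
  stopifnot(m >= 5)
  P <- asls_penalty(m, params$lambda)
  w <- rep(1, m)
  converged <- FALSE
  it <- 0
  for (it in seq_len(params$max_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.vector(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > z, params$p, 1 - params$p)
    if (all(w_new == w)) { converged <- TRUE; break }
    w <- w_new
  }
  list(baseline = z, corrected = y - z, converged = converged,
       iterations = it)
}

# lambda * D2'D2 is identical for every spectrum of a given length;
# cache it so correcting a whole set builds it once
.asls_cache <- new.env(parent = emptyenv())

asls_penalty <- function(m, lambda) {
  key <- paste(m, lambda)
  if (!is.null(.asls_cache[[key]])) return(.asls_cache[[key]])
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  P <- lambda * Matrix::crossprod(D)
  .asls_cache[[key]] <- P
  P
}

#' AsLS baseline correction of every spectrum in a set
#'
#' @param set a [spectra_set]
#' @param params an [asls_params()]
#' @return the corrected [spectra_set]
#' @export
asls_correct <- function(set, params = asls_params()) {
  stopifnot(inherits(set, "spectra_set"))
  out <- set
  for (i in seq_len(n_spectra(set))) {
    out$spectra[i, ] <- asls_baseline(set$spectra[i, ], params)$corrected
  }
  append_provenance(out, sprintf("asls_baseline(lambda=%g, p=%g)",
                                 params$lambda, params$p))
}

#' Scale a vector to unit Euclidean norm
#'
#' @param y nonzero numeric vector
#' @return `y / ||y||_2`
#' @export
vector_normalize <- function(y) {
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) stop("cannot vector-normalize the zero vector")
  y / nrm
}

#' Vector-normalize every spectrum in a set
#' @param set a [spectra_set]
#' @return the normalized [spectra_set]
#' @export
vector_normalize_set <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  out <- set
  out$spectra <- t(apply(set$spectra, 1, vector_normalize))
  append_provenance(out, "vector_normalize")
}

#' Savitzky-Golay smoothing or differentiation
#'
#' Least-squares polynomial convolution filter. With `deriv = 2` the
#' output is the second derivative with respect to wavenumber, i.e. the
#' filtered differences divided by the grid spacing squared.
#'
#' @param y numeric vector, length >= `window`
#' @param window odd filter length (default 9)
#' @param polyorder polynomial order (default 2), < `window`
#' @param deriv derivative order: 0 (smoothing) or 2
#' @param spacing grid spacing used to scale derivatives; default 1
#' @return filtered vector of the same length
#' @export
savgol <- function(y, window = 9L, polyorder = 2L, deriv = 0L, spacing = 1) {
  if (window %% 2 == 0) stop("window must be odd")
  stopifnot(polyorder < window, length(y) >= window, deriv %in% c(0L, 2L))
  signal::sgolayfilt(y, p = polyorder, n = window, m = deriv, ts = spacing)
}

#' Savitzky-Golay filter applied to every spectrum in a set
#'
#' @inheritParams savgol
#' @param set a [spectra_set]; the grid spacing is taken from its axis
#' @return the filtered [spectra_set]
#' @export
savgol_set <- function(set, window = 9L, polyorder = 2L, deriv = 0L) {
  stopifnot(inherits(set, "spectra_set"))
  sp <- mean(diff(set$wavenumbers))
  out <- set
  out$spectra <- t(apply(set$spectra, 1, savgol, window = window,
                         polyorder = polyorder, deriv = deriv,
                         spacing = sp))
  append_provenance(out, sprintf("savgol(window=%d, polyorder=%d, deriv=%d)",
                                 window, polyorder, deriv))
}

#' Omit a spectral region and re-baseline the flanking segments
#'
#' Removes the axis window `(lo, hi)` -- by default 1300-1500 cm^-1, where
#' paraffin absorbs most strongly -- keeping the two segments
#' `[axis_min, lo]` and `[hi, axis_max]` (bounds inclusive). Each segment
#' is AsLS baseline-corrected independently before concatenation, so the
#' cut does not introduce a step between segments.
#'
#' @param set a [spectra_set]
#' @param lo,hi omitted window bounds, strictly inside the axis range
#' @param baseline an [asls_params()] used per segment
#' @return a [spectra_set] on the concatenated (gapped) axis
#' @export
omit_region_concat <- function(set, lo = 1300, hi = 1500,
                               baseline = asls_params()) {
  stopifnot(inherits(set, "spectra_set"), lo < hi)
  ax <- set$wavenumbers
  if (lo <= min(ax) || hi >= max(ax)) {
    stop("omitted window must lie strictly inside the axis range")
  }
  left <- ax <= lo
  right <- ax >= hi
  if (!any(left) || !any(right)) stop("empty segment after omission")
  seg <- function(keep) {
    s <- spectra_set(set$spectra[, keep, drop = FALSE], ax[keep], set$meta)
    asls_correct(s, baseline)
  }
  sl <- seg(left); sr <- seg(right)
  out <- spectra_set(cbind(sl$spectra, sr$spectra), c(ax[left], ax[right]),
                     set$meta, set$provenance)
  append_provenance(out, sprintf(
    "omit_region_concat(%g, %g) with per-segment AsLS", lo, hi))
}

#' Average spectra per plant
#'
#' One output spectrum per `plant_id`: the pointwise arithmetic mean of
#' all grains from that plant. Species and population metadata are
#' retained; grain identifiers are cleared. Output order follows the
#' first occurrence of each plant in the input.
#'
#' @param set a [spectra_set] whose spectra all carry `plant_id`
#' @return a [spectra_set] with one spectrum per plant
#' @export
average_by_plant <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  if (anyNA(set$meta$plant_id)) stop("every spectrum needs a plant_id")
  plants <- unique(set$meta$plant_id)
  amat <- matrix(NA_real_, length(plants), n_points(set))
  meta <- data.frame(spectrum_id = plants, species = NA_character_,
                     population = set$meta$population[1],
                     plant_id = plants, grain_id = NA_character_,
                     sample_type = set$meta$sample_type[1])
  for (i in seq_along(plants)) {
    rows <- set$meta$plant_id == plants[i]
    amat[i, ] <- colMeans(set$spectra[rows, , drop = FALSE])
    meta$species[i] <- set$meta$species[which(rows)[1]]
    meta$population[i] <- set$meta$population[which(rows)[1]]
  }
  out <- spectra_set(amat, set$wavenumbers, meta, set$provenance)
  append_provenance(out, sprintf("average_by_plant (%d plants)",
                                 length(plants)))
}
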