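#' Spectra collection on a shared wavenumber axis
#'
#' A `spectra_set` bundles an absorbance matrix (one row per spectrum), the
#' common wavenumber axis in cm^-1, per-spectrum sample metadata and a
#' provenance log. The axis is always stored strictly ascending; inputs with
#' descending axes are reversed on construction so that derivative and
#' baseline operations have a single sign convention.
#'
#' @param spectra numeric matrix, `n_spectra x n_points`, finite everywhere.
#'   A single spectrum may be given as a vector.
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), strictly
#'   monotone; length must equal `ncol(spectra)`.
#' @param meta data frame with one row per spectrum. Missing metadata
#'   columns (`species`, `population`, `plant_id`, `grain_id`,
#'   `sample_type`) are filled with `NA`.
#' @param provenance character vector of operations already applied.
#'
#' @return An object of class `spectra_set` with elements `wavenumbers`,
#'   `spectra`, `meta`, `provenance`.
#' @export
spectra_set <- function(spectra, wavenumbers, meta = NULL,
                        provenance = character()) {
  if (is.vector(spectra)) spectra <- matrix(spectra, nrow = 1)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(spectra)) {
    stop("length(wavenumbers) must equal ncol(spectra)")
  }
  if (anyNA(spectra) || !all(is.finite(spectra))) {
    stop("absorbance values must be finite")
  }
  d <- diff(wavenumbers)
  if (length(d) && all(d < 0)) {         # descending axis: flip
    wavenumbers <- rev(wavenumbers)
    spectra <- spectra[, rev(seq_len(ncol(spectra))), drop = FALSE]
    d <- diff(wavenumbers)
  }
  if (length(d) && any(d <= 0)) {
    stop("wavenumber axis must be strictly monotone")
  }
  meta <- normalize_meta(meta, nrow(spectra))
  rownames(spectra) <- meta$spectrum_id
  structure(
    list(wavenumbers = wavenumbers, spectra = spectra, meta = meta,
         provenance = as.character(provenance)),
    class = "spectra_set"
  )
}

meta_columns <- c("spectrum_id", "species", "population", "plant_id",
                  "grain_id", "sample_type")

normalize_meta <- function(meta, n) {
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop("meta must have one row per spectrum")
  if (is.null(meta$spectrum_id)) meta$spectrum_id <- sprintf("s%04d", seq_len(n))
  meta$spectrum_id <- as.character(meta$spectrum_id)
  if (anyDuplicated(meta$spectrum_id)) stop("spectrum_id values must be unique")
  for (col in setdiff(meta_columns, names(meta))) meta[[col]] <- rep(NA, n)
  meta <- meta[, c(meta_columns, setdiff(names(meta), meta_columns)),
               drop = FALSE]
  rownames(meta) <- NULL
  meta
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d points, %.1f-%.1f cm^-1\n",
              n_spectra(x), n_points(x),
              min(x$wavenumbers), max(x$wavenumbers)))
  sp <- unique(stats::na.omit(x$meta$species))
  if (length(sp)) cat("  species:", paste(sp, collapse = ", "), "\n")
  if (length(x$provenance)) {
    cat("  provenance:\n")
    for (p in x$provenance) cat("   -", p, "\n")
  }
  invisible(x)
}

#' Number of spectra / axis points in a spectra_set
#' @param x a `spectra_set`
#' @return integer count
#' @export
n_spectra <- function(x) nrow(x$spectra)

#' @rdname n_spectra
#' @export
n_points <- function(x) ncol(x$spectra)

#' Default 519-point analysis axis spanning 800-1800 cm^-1
#'
#' The fingerprint region used throughout the pipeline, discretised to 519
#' points (the input dimension of the neural-network classifier).
#'
#' @param n_points number of grid points
#' @param lo,hi axis end points in cm^-1 (inclusive)
#' @return numeric vector of wavenumbers
#' @export
default_axis <- function(n_points = 519L, lo = 800, hi = 1800) {
  seq(lo, hi, length.out = n_points)
}

append_provenance <- function(set, entry) {
  set$provenance <- c(set$provenance, entry)
  set
}

#' Subset a spectra_set by spectrum index
#'
#' @param set a `spectra_set`
#' @param i integer or logical index over spectra
#' @return a `spectra_set` with the selected spectra
#' @export
subset_spectra <- function(set, i) {
  spectra_set(set$spectra[i, , drop = FALSE], set$wavenumbers,
              set$meta[i, , drop = FALSE], set$provenance)
}

#' Restrict a spectra_set to a wavenumber window
#'
#' Retains axis points nu with `lo <= nu <= hi` (both bounds inclusive,
#' matching the "1800 to 800 cm^-1" convention for the fingerprint region).
#' Idempotent: re-applying the same window is a no-op.
#'
#' @param set a `spectra_set`
#' @param lo,hi window bounds in cm^-1, `lo < hi`
#' @return a `spectra_set` on the restricted axis
#' @export
select_region <- function(set, lo, hi) {
  stopifnot(inherits(set, "spectra_set"), lo < hi)
  keep <- set$wavenumbers >= lo & set$wavenumbers <= hi
  if (!any(keep)) stop("no axis points in [", lo, ", ", hi, "]")
  out <- spectra_set(set$spectra[, keep, drop = FALSE],
                     set$wavenumbers[keep], set$meta, set$provenance)
  append_provenance(out, sprintf("select_region(%g, %g)", lo, hi))
}

#' Combine spectra_sets sharing one axis
#'
#' @param ... `spectra_set` objects with bitwise-identical axes
#' @return a single `spectra_set`; provenance is taken from the first set
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  ax <- sets[[1]]$wavenumbers
  for (s in sets) {
    if (!identical(s$wavenumbers, ax)) stop("axes differ between sets")
  }
  metas <- lapply(sets, function(s) s$meta)
  common <- Reduce(intersect, lapply(metas, names))
  meta <- do.call(rbind, lapply(metas, function(m) m[, common, drop = FALSE]))
  spectra_set(do.call(rbind, lapply(sets, function(s) s$spectra)),
              ax, meta, sets[[1]]$provenance)
}
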