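#' Extended multiplicative signal correction (EMSC) model
#'
#' The design regresses each spectrum on a constant, linear and quadratic
#' term in the wavenumber axis (affinely mapped to [-1, 1] for
#' conditioning), optional interferent constituent spectra, and a
#' reference spectrum:
#' `y = a + c t + d t^2 + sum_j e_j I_j + b r + residual`.
#' The corrected spectrum `(y - a - c t - d t^2 - sum_j e_j I_j) / b`
#' removes baseline and interferent contributions and normalises by the
#' reference coefficient, so no separate normalization step is needed.
#'
#' The "simple" EMSC has no interferents and uses the set mean as
#' reference; the paraffin-constituent ("complex") model adds the averaged
#' pure-paraffin spectrum as an interferent and uses a pollen constituent
#' spectrum as reference.
#'
#' @param reference reference spectrum on the model axis (not all zero)
#' @param wavenumbers model axis
#' @param interferents optional matrix (one column per interferent
#'   constituent) or single vector on the same axis
#' @param degree polynomial degree of the baseline part (default 2)
#' @return an `emsc_model` with the assembled design matrix
#' @export
emsc_model <- function(reference, wavenumbers, interferents = NULL,
                       degree = 2L) {
  reference <- as.numeric(reference)
  stopifnot(length(reference) == length(wavenumbers),
            any(reference != 0))
  t01 <- 2 * (wavenumbers - min(wavenumbers)) /
    (max(wavenumbers) - min(wavenumbers)) - 1
  poly <- sapply(0:degree, function(d) t01^d)
  colnames(poly) <- c("a", "c", "d", paste0("poly", 3:10))[seq_len(degree + 1)]
  if (!is.null(interferents)) {
    interferents <- as.matrix(interferents)
    stopifnot(nrow(interferents) == length(wavenumbers))
    colnames(interferents) <- paste0("e", seq_len(ncol(interferents)))
  }
  design <- cbind(poly, interferents, b = reference)
  if (qr(design)$rank < ncol(design)) {
    stop("EMSC design matrix is rank deficient")
  }
  structure(list(reference = reference, wavenumbers = wavenumbers,
                 interferents = interferents, degree = as.integer(degree),
                 design = design),
            class = "emsc_model")
}

#' Fit an EMSC model and correct a spectra set
#'
#' Ordinary least squares of every spectrum on the model design, followed
#' by subtraction of the polynomial and interferent parts and division by
#' the reference coefficient `b`. Spectra with `|b| < 1e-8` cannot be
#' normalised; they are excluded from the corrected set and listed in
#' `excluded`.
#'
#' @param set a [spectra_set] on the model's axis
#' @param model an [emsc_model()]
#' @return list with `corrected` (a [spectra_set]) and `coefficients`
#'   (data frame, one row per input spectrum: `a`, `c`, `d`, `e*`, `b`),
#'   plus `excluded` (character vector of uncorrectable spectrum ids)
#' @export
emsc_fit_correct <- function(set, model) {
  stopifnot(inherits(set, "spectra_set"), inherits(model, "emsc_model"))
  if (!isTRUE(all.equal(set$wavenumbers, model$wavenumbers,
                        tolerance = 1e-8))) {
    stop("spectra axis does not match the EMSC model axis")
  }
  M <- model$design
  qrM <- qr(M)
  coefs <- t(qr.coef(qrM, t(set$spectra)))   # n x ncol(M)
  colnames(coefs) <- colnames(M)
  b <- coefs[, "b"]
  bad <- abs(b) < 1e-8
  non_ref <- M[, setdiff(colnames(M), "b"), drop = FALSE]
  corrected <- (set$spectra -
                  coefs[, setdiff(colnames(M), "b"), drop = FALSE] %*%
                  t(non_ref)) / b
  out <- spectra_set(corrected[!bad, , drop = FALSE], set$wavenumbers,
                     set$meta[!bad, , drop = FALSE], set$provenance)
  kind <- if (is.null(model$interferents)) "simple"
          else sprintf("%d-interferent", ncol(model$interferents))
  out <- append_provenance(out, sprintf(
    "emsc_fit_correct(%s, degree=%d)%s", kind, model$degree,
    if (any(bad)) sprintf(" [excluded %d uncorrectable]", sum(bad)) else ""))
  list(corrected = out,
       coefficients = data.frame(spectrum_id = set$meta$spectrum_id,
                                 as.data.frame(coefs)),
       excluded = set$meta$spectrum_id[bad])
}

#' Simple EMSC of a set: mean reference, linear + quadratic baseline
#'
#' @param set a [spectra_set]
#' @param reference optional reference spectrum; defaults to the set mean
#' @return as [emsc_fit_correct()]
#' @export
emsc_simple <- function(set, reference = NULL) {
  if (is.null(reference)) reference <- colMeans(set$spectra)
  emsc_fit_correct(set, emsc_model(reference, set$wavenumbers))
}

#' EMSC with a paraffin constituent spectrum
#'
#' The paraffin interferent is removed from each spectrum and the
#' paraffin coefficient `e1` is returned as a per-grain paraffin-share
#' diagnostic.
#'
#' @param set a [spectra_set]
#' @param pollen_reference pollen constituent (reference) spectrum
#' @param paraffin paraffin constituent spectrum
#' @return as [emsc_fit_correct()]
#' @export
emsc_paraffin <- function(set, pollen_reference, paraffin) {
  emsc_fit_correct(set, emsc_model(pollen_reference, set$wavenumbers,
                                   interferents = paraffin))
}
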