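#' Joint non-negative matrix factorization of pollen and paraffin spectra
#'
#' Stacks the (baseline-corrected, vector-normalized) pollen spectra and
#' the pure-paraffin spectra into one matrix X (rows = spectra), clips
#' small negatives left by baseline correction at zero, and factorizes
#' `X ~ W H` with `W >= 0` (n_spectra x k weights) and `H >= 0`
#' (k x n_points component spectra) by hierarchical alternating least
#' squares minimising the Frobenius norm. The best of `restarts` random
#' initialisations is kept; results are deterministic given `seed`.
#'
#' @param pollen a [spectra_set] of pollen spectra
#' @param paraffin a [spectra_set] of pure paraffin spectra (may be
#'   `NULL` to factorize pollen alone)
#' @param k number of components (default 6)
#' @param seed integer seed controlling the random initialisations
#' @param restarts number of random restarts
#' @param max_iter update sweeps per restart
#' @param tol relative change in residual below which updates stop
#' @return an `nmf_decomposition`: `components` (k x n_points), `weights`
#'   (n x k), `fit_residual` (Frobenius norm of X - WH), `residuals` (per
#'   restart), `k`, `seed`, `restarts`, `meta`, `wavenumbers`,
#'   `is_pollen` (logical per row)
#' @export
joint_nmf <- function(pollen, paraffin = NULL, k = 6L, seed = 1L,
                      restarts = 5L, max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(pollen, "spectra_set"), k >= 2)
  sets <- if (is.null(paraffin)) list(pollen) else list(pollen, paraffin)
  joint <- if (length(sets) == 2) bind_spectra(pollen, paraffin) else pollen
  X <- pmax(joint$spectra, 0)
  if (k > min(dim(X))) stop("k exceeds min(n_spectra, n_points)")
  best <- NULL
  residuals <- numeric(restarts)
  for (r in seq_len(restarts)) {
    fit <- with_seed(seed + r - 1L, nmf_factorize(X, k, max_iter, tol))
    residuals[r] <- fit$residual
    if (is.null(best) || fit$residual < best$residual) best <- fit
  }
  structure(list(components = best$H, weights = best$W, k = as.integer(k),
                 fit_residual = best$residual, residuals = residuals,
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 wavenumbers = joint$wavenumbers, meta = joint$meta,
                 is_pollen = seq_len(nrow(X)) <= n_spectra(pollen)),
            class = "nmf_decomposition")
}

# Hierarchical alternating least squares (block-coordinate descent on
# single components) for the Frobenius objective; every update projects
# onto the non-negative orthant, so W, H stay non-negative throughout.
nmf_factorize <- function(X, k, max_iter, tol) {
  n <- nrow(X); p <- ncol(X)
  eps <- .Machine$double.eps
  scale0 <- sqrt(mean(X) / k)
  W <- matrix(stats::runif(n * k, 0, 2 * scale0), n, k)
  H <- matrix(stats::runif(k * p, 0, 2 * scale0), k, p)
  res_old <- Inf
  for (it in seq_len(max_iter)) {
    WtX <- crossprod(W, X); WtW <- crossprod(W)
    for (j in seq_len(k)) {
      H[j, ] <- pmax(0, H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) /
                       max(WtW[j, j], eps))
    }
    XHt <- tcrossprod(X, H); HHt <- tcrossprod(H)
    for (j in seq_len(k)) {
      W[, j] <- pmax(0, W[, j] + (XHt[, j] - W %*% HHt[, j]) /
                       max(HHt[j, j], eps))
    }
    if (it %% 10 == 0 || it == max_iter) {
      res <- sqrt(sum((X - W %*% H)^2))
      if (is.finite(res_old) && (res_old - res) < tol * max(res_old, eps)) {
        res_old <- res
        break
      }
      res_old <- res
    }
  }
  list(W = W, H = H, residual = sqrt(sum((X - W %*% H)^2)))
}

#' Identify paraffin-carrying NMF components
#'
#' Automates the visual inspection step: component j is flagged as
#' paraffin if its Pearson correlation with the paraffin reference over
#' the 1300-1500 cm^-1 window exceeds `threshold`, or if its two largest
#' peaks fall within +/- `peak_tol` cm^-1 of the 1377 and 1462 cm^-1
#' paraffin bands. A manual override may be supplied.
#'
#' @param dec an `nmf_decomposition`
#' @param paraffin_ref paraffin reference spectrum on the decomposition's
#'   axis
#' @param threshold correlation threshold (default 0.8)
#' @param peak_tol peak matching tolerance in cm^-1 (default 6)
#' @param override optional logical vector of length k replacing the
#'   automatic flags
#' @return list with `paraffin_flags` (logical per component) and
#'   `criterion_scores` (the windowed correlations)
#' @export
identify_paraffin_components <- function(dec, paraffin_ref,
                                         threshold = 0.8, peak_tol = 6,
                                         override = NULL) {
  stopifnot(inherits(dec, "nmf_decomposition"),
            length(paraffin_ref) == length(dec$wavenumbers))
  win <- dec$wavenumbers >= 1300 & dec$wavenumbers <= 1500
  scores <- apply(dec$components, 1, function(h) {
    # correlation is scale-invariant, so require the window to carry a
    # non-trivial share of the component before trusting it: a component
    # with essentially no mass at 1300-1500 cm^-1 is not paraffin even
    # if its numerical residue there happens to track the reference
    if (stats::sd(h[win]) == 0 || max(h[win]) < 0.1 * max(h)) return(0)
    stats::cor(h[win], paraffin_ref[win])
  })
  peak_flag <- apply(dec$components, 1, function(h) {
    pk <- local_peaks(dec$wavenumbers, h)
    if (length(pk) < 2) return(FALSE)
    top2 <- sort(pk[order(h[match(pk, dec$wavenumbers)],
                          decreasing = TRUE)][1:2])
    all(abs(top2 - c(1377, 1462)) <= peak_tol)
  })
  flags <- scores > threshold | peak_flag
  if (!is.null(override)) {
    stopifnot(length(override) == dec$k)
    flags <- as.logical(override)
  }
  if (all(flags)) {
    stop("degenerate decomposition: every component flagged as paraffin")
  }
  list(paraffin_flags = unname(flags), criterion_scores = unname(scores))
}

local_peaks <- function(x, y) {
  i <- which(diff(sign(diff(y))) == -2) + 1
  x[i]
}

#' Reconstruct pollen spectra without the paraffin components
#'
#' For each pollen spectrum i, `xhat_i = sum_{j unflagged} W_ij H_j`.
#' Pure-paraffin rows of the joint decomposition are dropped. Spectra
#' whose unflagged weights are all zero reconstruct to the zero vector
#' and are noted in the provenance.
#'
#' @param dec an `nmf_decomposition`
#' @param labels output of [identify_paraffin_components()]
#' @param renormalize vector-normalize the reconstructions (default TRUE,
#'   so downstream classification sees unit-norm spectra)
#' @return a [spectra_set] of paraffin-free reconstructions
#' @export
reconstruct_without_paraffin <- function(dec, labels, renormalize = TRUE) {
  stopifnot(inherits(dec, "nmf_decomposition"),
            length(labels$paraffin_flags) == dec$k)
  keep <- !labels$paraffin_flags
  rows <- dec$is_pollen
  recon <- dec$weights[rows, keep, drop = FALSE] %*%
    dec$components[keep, , drop = FALSE]
  zero <- rowSums(recon) == 0
  out <- spectra_set(recon, dec$wavenumbers,
                     dec$meta[rows, , drop = FALSE])
  out <- append_provenance(out, sprintf(
    "nmf reconstruction without components {%s}%s",
    paste(which(labels$paraffin_flags), collapse = ","),
    if (any(zero)) sprintf(" [%d all-zero reconstructions]", sum(zero))
    else ""))
  if (renormalize) {
    nz <- !zero
    out$spectra[nz, ] <- t(apply(out$spectra[nz, , drop = FALSE], 1,
                                 vector_normalize))
    out <- append_provenance(out, "vector_normalize (post-NMF)")
  }
  out
}

#' Removed paraffin mass per pollen spectrum
#'
#' The l1 mass of the flagged-component part of each reconstruction,
#' `sum_{j flagged} W_ij ||H_j||_1` -- a per-grain estimate of the
#' paraffin contribution that correlates with the true embedding
#' fraction on synthetic data.
#'
#' @param dec an `nmf_decomposition`
#' @param labels output of [identify_paraffin_components()]
#' @return numeric vector over pollen spectra
#' @export
paraffin_mass_removed <- function(dec, labels) {
  flagged <- labels$paraffin_flags
  h_mass <- rowSums(abs(dec$components))
  as.vector(dec$weights[dec$is_pollen, flagged, drop = FALSE] %*%
              h_mass[flagged])
}

#' Relative spectral contribution of each NMF component
#'
#' Per spectrum, component j contributes
#' `100 * W_ij ||H_j||_1 / sum_k W_ik ||H_k||_1` percent; the table
#' reports the mean and standard deviation per species. Spectra with zero
#' total mass are excluded.
#'
#' @param dec an `nmf_decomposition` whose pollen rows carry species
#'   metadata
#' @return list with `per_spectrum` (matrix of percentages, rows summing
#'   to 100), `by_species` (data frame of mean and sd per species and
#'   component), `excluded` (spectrum ids with zero mass)
#' @export
relative_contributions <- function(dec) {
  stopifnot(inherits(dec, "nmf_decomposition"))
  rows <- dec$is_pollen
  h_mass <- rowSums(abs(dec$components))
  mass <- sweep(dec$weights[rows, , drop = FALSE], 2, h_mass, `*`)
  total <- rowSums(mass)
  ok <- total > 0
  contrib <- 100 * mass[ok, , drop = FALSE] / total[ok]
  species <- dec$meta$species[rows][ok]
  by_species <- do.call(rbind, lapply(split(seq_along(species), species),
    function(idx) {
      data.frame(species = species[idx[1]],
                 component = seq_len(dec$k),
                 mean = colMeans(contrib[idx, , drop = FALSE]),
                 sd = apply(contrib[idx, , drop = FALSE], 2, stats::sd))
    }))
  rownames(by_species) <- NULL
  list(per_spectrum = contrib, by_species = by_species,
       excluded = dec$meta$spectrum_id[rows][!ok])
}

#' Project new spectra onto fixed NMF components
#'
#' Non-negative least squares per spectrum via multiplicative updates
#' with the components held fixed; used to apply a training-set NMF to
#' held-out spectra without refitting the components.
#'
#' @param set a [spectra_set] on the decomposition's axis
#' @param dec an `nmf_decomposition`
#' @param max_iter update iterations
#' @return weight matrix, `n_spectra(set) x k`
#' @export
nmf_project <- function(set, dec, max_iter = 500L) {
  stopifnot(inherits(set, "spectra_set"),
            inherits(dec, "nmf_decomposition"))
  X <- pmax(set$spectra, 0)
  H <- dec$components
  eps <- .Machine$double.eps
  W <- matrix(mean(X) / dec$k, nrow(X), dec$k)
  HtH <- tcrossprod(H)
  XHt <- tcrossprod(X, H)
  for (it in seq_len(max_iter)) {
    W_new <- W * XHt / (W %*% HtH + eps)
    if (max(abs(W_new - W)) < 1e-10 * max(W, eps)) { W <- W_new; break }
    W <- W_new
  }
  W
}
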