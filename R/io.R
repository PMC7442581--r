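#' Read spectra from CSV
#'
#' Two dialects are supported. `wide`: one row per spectrum; metadata
#' columns (`spectrum_id` optional, then `species`, `population`,
#' `plant_id`, `grain_id`, `sample_type`) precede one column per
#' wavenumber, whose headers are the wavenumbers themselves. `long`: tidy
#' format with columns `spectrum_id`, metadata, `wavenumber`,
#' `absorbance`. Descending axes are reversed on read.
#'
#' @param path file path
#' @param dialect `"wide"` or `"long"`
#' @return a [spectra_set]
#' @export
read_spectra_csv <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("parse error: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]))
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") read_wide(df) else read_long(df)
}

required_meta <- c("species", "population", "plant_id", "grain_id",
                   "sample_type")

read_wide <- function(df) {
  num_head <- suppressWarnings(as.numeric(names(df)))
  is_wn <- !is.na(num_head)
  if (sum(is_wn) < 2) stop("schema error: no wavenumber columns found")
  missing <- setdiff(required_meta, names(df)[!is_wn])
  if (length(missing)) {
    stop("schema error: missing metadata columns: ",
         paste(missing, collapse = ", "))
  }
  wn <- num_head[is_wn]
  amat <- as.matrix(df[, is_wn, drop = FALSE])
  if (!is.numeric(amat)) {
    bad <- which(apply(df[, is_wn, drop = FALSE], 1,
                       function(r) anyNA(suppressWarnings(as.numeric(r)))))[1]
    stop(sprintf("parse error: non-numeric absorbance in data row %d", bad))
  }
  spectra_set(amat, wn, df[, !is_wn, drop = FALSE])
}

read_long <- function(df) {
  need <- c("spectrum_id", "wavenumber", "absorbance")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("schema error: missing columns: ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(df$absorbance)) {
    stop("parse error: non-numeric absorbance values")
  }
  ids <- unique(df$spectrum_id)
  first <- df[df$spectrum_id == ids[1], ]
  axis <- first$wavenumber
  amat <- matrix(NA_real_, length(ids), length(axis))
  meta_cols <- setdiff(names(df), c("wavenumber", "absorbance"))
  meta <- df[!duplicated(df$spectrum_id), meta_cols, drop = FALSE]
  for (i in seq_along(ids)) {
    rows <- df[df$spectrum_id == ids[i], ]
    if (nrow(rows) != length(axis) ||
        max(abs(rows$wavenumber - axis)) > 0.01) {
      stop("axis error: spectrum ", ids[i],
           " does not share the common wavenumber axis")
    }
    amat[i, ] <- rows$absorbance
  }
  spectra_set(amat, axis, meta)
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra_csv()]: the written file re-reads to an equal
#' set (absorbances within 1e-12, metadata exact).
#'
#' @param set a non-empty [spectra_set]
#' @param path output file path
#' @param dialect `"wide"` or `"long"`
#' @return `path`, invisibly
#' @export
write_spectra_csv <- function(set, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(set, "spectra_set"))
  if (n_spectra(set) == 0) stop("refusing to write an empty spectra_set")
  meta <- set$meta[, meta_columns, drop = FALSE]
  if (dialect == "wide") {
    amat <- set$spectra
    colnames(amat) <- format_num(set$wavenumbers)
    df <- cbind(meta, as.data.frame(amat, check.names = FALSE))
  } else {
    n <- n_spectra(set); p <- n_points(set)
    df <- cbind(
      meta[rep(seq_len(n), each = p), , drop = FALSE],
      data.frame(wavenumber = rep(set$wavenumbers, times = n),
                 absorbance = as.vector(t(set$spectra)))
    )
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 15, format = "g")
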