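#' Hyperspectral cube
#'
#' Container for a hyperspectral image: a 3-D array of `lines x samples x
#' bands` values (raw detector counts or calibrated reflectance) plus a
#' strictly increasing wavelength axis.
#'
#' @param data 3-D numeric array, `lines x samples x bands`.
#' @param wavelengths Numeric vector of band-center wavelengths (nm), one per
#'   band, strictly increasing.
#' @param calibrated Logical; `TRUE` once the cube holds reflectance produced
#'   by [calibrate_cube()].
#' @return An object of class `hypercube`: a list with elements `data`,
#'   `wavelengths` and `calibrated`.
#' @seealso [calibrate_cube()], [trim_bands()], [roi_mean_spectrum()]
#' @export
hypercube <- function(data, wavelengths, calibrated = FALSE) {
  if (length(dim(data)) != 3L) {
    stopf("`data` must be a 3-D array (lines x samples x bands)")
  }
  if (length(wavelengths) != dim(data)[3L]) {
    stopf("wavelength axis length (%d) must equal band count (%d)",
          length(wavelengths), dim(data)[3L])
  }
  if (any(diff(wavelengths) <= 0)) {
    stopf("`wavelengths` must be strictly increasing")
  }
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 calibrated = isTRUE(calibrated)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths),
              if (x$calibrated) "calibrated reflectance" else "raw counts"))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# Flatten the spatial plane: (lines*samples) x bands matrix; pixel index runs
# down lines first (column-major), matching R array layout.
cube_pixels <- function(cube) {
  d <- dim(cube$data)
  x <- cube$data
  dim(x) <- c(d[1L] * d[2L], d[3L])
  x
}

#' Calibrate a raw cube to reflectance
#'
#' Converts raw counts to relative reflectance with the usual flat-field
#' correction `(raw - dark) / (white - dark)`, using a dark reference (shutter
#' closed, ~0 % reflectance) and a white reference (standard panel, ~99.9 %
#' reflectance). The references are single line-scan frames (`samples x
#' bands`) broadcast along the scan (line) axis.
#'
#' Cells where `white == dark` (dead pixels) are set to 0 and reported via a
#' warning rather than propagating `NaN`. Calibrated reflectance is clipped to
#' `clip` (default \[0, 1.5\]) so occasional specular pixels cannot
#' destabilize downstream gray-level quantization.
#'
#' @param raw A [hypercube()] of raw counts.
#' @param white,dark Numeric `samples x bands` reference frames.
#' @param clip Length-2 numeric range to clip reflectance to.
#' @return A calibrated [hypercube()].
#' @export
calibrate_cube <- function(raw, white, dark, clip = c(0, 1.5)) {
  stopifnot(inherits(raw, "hypercube"))
  d <- dim(raw$data)
  white <- as.matrix(white)
  dark <- as.matrix(dark)
  if (!all(dim(white) == c(d[2L], d[3L])) ||
      !all(dim(dark) == c(d[2L], d[3L]))) {
    stopf("white/dark frames must be samples x bands (%d x %d)", d[2L], d[3L])
  }
  px <- cube_pixels(raw)
  idx <- rep(seq_len(d[2L]), each = d[1L])   # sample (column) of each pixel
  denom <- (white - dark)[idx, , drop = FALSE]
  num <- px - dark[idx, , drop = FALSE]
  bad <- denom == 0
  refl <- num / denom
  if (any(bad)) {
    refl[bad] <- 0
    warning(sprintf("%d dead cells (white == dark) set to 0 reflectance",
                    sum(bad)), call. = FALSE)
  }
  refl[refl < clip[1L]] <- clip[1L]
  refl[refl > clip[2L]] <- clip[2L]
  dim(refl) <- d
  hypercube(refl, raw$wavelengths, calibrated = TRUE)
}

#' Trim noisy head and tail bands
#'
#' Drops the first `n_head` and last `n_tail` bands of a cube or spectra
#' matrix together with the matching stretch of the wavelength axis. The
#' instrument's band edges carry a large share of detector noise; for the
#' 512-band 380-1030 nm configuration the working default elsewhere in the
#' package is `(82, 22)`, leaving 408 bands spanning roughly 480-1000 nm.
#'
#' @param x A [hypercube()] or [spectra_matrix()].
#' @param n_head,n_tail Non-negative counts of bands to drop at each end.
#' @return An object of the same class with `n_head + n_tail` fewer bands.
#' @export
trim_bands <- function(x, n_head = 82L, n_tail = 22L) {
  UseMethod("trim_bands")
}

check_trim <- function(k, n_head, n_tail) {
  if (n_head < 0 || n_tail < 0 || n_head + n_tail >= k) {
    stopf("cannot trim %d + %d bands from %d", n_head, n_tail, k)
  }
  seq.int(n_head + 1L, k - n_tail)
}

#' @export
trim_bands.hypercube <- function(x, n_head = 82L, n_tail = 22L) {
  keep <- check_trim(dim(x$data)[3L], n_head, n_tail)
  hypercube(x$data[, , keep, drop = FALSE], x$wavelengths[keep],
            calibrated = x$calibrated)
}

#' @export
trim_bands.spectra_matrix <- function(x, n_head = 82L, n_tail = 22L) {
  keep <- check_trim(ncol(x$values), n_head, n_tail)
  spectra_matrix(x$values[, keep, drop = FALSE], x$wavelengths[keep],
                 sample_ids = x$sample_ids, labels = x$labels)
}

#' Mean ROI spectrum of a calibrated cube
#'
#' Averages the spectra of all pixels inside a region-of-interest mask (the
#' stalk region), giving the one spectrum that represents the sample.
#'
#' @param cube A calibrated [hypercube()].
#' @param mask Logical `lines x samples` matrix; `TRUE` marks ROI pixels.
#' @return Numeric vector of per-band mean reflectance, named by wavelength.
#' @export
roi_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (!cube$calibrated) stopf("cube must be calibrated before ROI averaging")
  d <- dim(cube$data)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == d[1:2])) stopf("mask shape must match the cube's spatial plane")
  keep <- which(as.vector(mask))
  if (length(keep) == 0L) stopf("ROI mask is empty")
  px <- cube_pixels(cube)
  out <- colMeans(px[keep, , drop = FALSE])
  names(out) <- cube$wavelengths
  out
}

#' Matrix of sample spectra
#'
#' `N x K` matrix of ROI-mean reflectance spectra (one row per sample) with
#' the shared wavelength axis, sample identifiers, and DI class labels.
#'
#' @param values Numeric `N x K` matrix.
#' @param wavelengths Length-`K` strictly increasing numeric vector (nm).
#' @param sample_ids Optional character ids (default `s1..sN`).
#' @param labels Optional integer DI labels in `0..5`, length `N`.
#' @return Object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(values, wavelengths, sample_ids = NULL,
                           labels = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != length(wavelengths)) {
    stopf("ncol(values) must equal length(wavelengths)")
  }
  if (any(diff(wavelengths) <= 0)) stopf("`wavelengths` must be strictly increasing")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (!is.null(labels) && length(labels) != nrow(values)) {
    stopf("one label per row required")
  }
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 sample_ids = as.character(sample_ids),
                 labels = if (is.null(labels)) NULL else as.integer(labels)),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d bands (%.1f-%.1f nm)%s\n",
              nrow(x$values), ncol(x$values), min(x$wavelengths),
              max(x$wavelengths),
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' @export
as.matrix.spectra_matrix <- function(x, ...) x$values

#' @export
dim.spectra_matrix <- function(x) dim(x$values)

#' Savitzky-Golay smoothing of spectra
#'
#' Smooths each spectrum by local least-squares polynomial fitting
#' (Savitzky-Golay). Interior points use the centered window; the first and
#' last half-windows are completed by evaluating the polynomial fitted to the
#' nearest full window, so no reflection padding is involved and polynomials
#' up to degree `polyorder` are reproduced exactly everywhere.
#'
#' @param x A [spectra_matrix()], or a numeric matrix with one spectrum per
#'   row, or a single numeric spectrum.
#' @param window Odd window width in bands (default 9).
#' @param polyorder Polynomial order, `< window` (default 3).
#' @return Smoothed object of the same kind as the input.
#' @export
sg_smooth <- function(x, window = 9L, polyorder = 3L) {
  if (window %% 2L != 1L) stopf("`window` must be odd")
  if (polyorder >= window) stopf("`polyorder` must be < `window`")
  smooth_rows <- function(m) {
    if (ncol(m) < window) stopf("spectrum shorter than the smoothing window")
    t(apply(m, 1L, signal::sgolayfilt, p = polyorder, n = window))
  }
  if (inherits(x, "spectra_matrix")) {
    spectra_matrix(smooth_rows(x$values), x$wavelengths,
                   sample_ids = x$sample_ids, labels = x$labels)
  } else if (is.matrix(x)) {
    smooth_rows(x)
  } else {
    signal::sgolayfilt(as.numeric(x), p = polyorder, n = window)
  }
}
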