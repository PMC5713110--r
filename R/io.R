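#' Write / read a hypercube as ENVI flat binary
#'
#' Writes the cube as band-sequential (BSQ) or band-interleaved-by-line (BIL)
#' little-endian 4-byte floats in `<path>` with a plain-text ENVI header in
#' `<path>.hdr` carrying `samples`, `lines`, `bands`, interleave, data type
#' and the wavelength list. `read_envi` understands the same subset.
#'
#' @param cube A [hypercube()].
#' @param path Data file path (header written next to it as `.hdr`).
#' @param interleave `"bsq"` or `"bil"`.
#' @return `write_envi` returns `path` invisibly; `read_envi` a
#'   [hypercube()].
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  hdr <- c("ENVI",
           "description = {stemborer synthetic hyperspectral cube}",
           sprintf("samples = %d", d[2L]),
           sprintf("lines = %d", d[1L]),
           sprintf("bands = %d", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("calibrated = %d", as.integer(cube$calibrated)),
           sprintf("wavelength = {%s}",
                   paste(format(cube$wavelengths, trim = TRUE,
                                digits = 10), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band-major [sample within line, line, band]; BIL: [sample, band, line]
  x <- aperm(cube$data,
             if (interleave == "bsq") c(2L, 1L, 3L) else c(2L, 3L, 1L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  invisible(path)
}

parse_envi_field <- function(lines, key) {
  hit <- grep(sprintf("^%s\\s*=", key), lines, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  trimws(sub("^[^=]*=", "", hit[1L]))
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stopf("missing ENVI header %s", hdr_path)
  lines <- readLines(hdr_path)
  # re-join the wavelength block, which may span lines
  joined <- paste(lines, collapse = "\n")
  samples <- as.integer(parse_envi_field(lines, "samples"))
  nlines <- as.integer(parse_envi_field(lines, "lines"))
  bands <- as.integer(parse_envi_field(lines, "bands"))
  interleave <- tolower(parse_envi_field(lines, "interleave"))
  dtype <- as.integer(parse_envi_field(lines, "data type"))
  calibrated <- identical(parse_envi_field(lines, "calibrated"), "1")
  if (!dtype %in% c(4L, 5L)) stopf("only float ENVI data types 4/5 supported")
  wl_txt <- sub(".*wavelength\\s*=\\s*\\{([^}]*)\\}.*", "\\1", joined)
  wavelengths <- as.numeric(strsplit(wl_txt, ",")[[1L]])
  n <- samples * nlines * bands
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = if (dtype == 4L) 4L else 8L,
               endian = "little")
  if (interleave == "bsq") {
    dim(x) <- c(samples, nlines, bands)
    x <- aperm(x, c(2L, 1L, 3L))
  } else if (interleave == "bil") {
    dim(x) <- c(samples, bands, nlines)
    x <- aperm(x, c(3L, 1L, 2L))
  } else {
    stopf("unsupported interleave '%s'", interleave)
  }
  hypercube(x, wavelengths, calibrated = calibrated)
}

#' Write / read an ROI mask as PNG
#'
#' Nonzero pixels mark the ROI.
#'
#' @param mask Logical `lines x samples` matrix.
#' @param path PNG file path.
#' @return `write_roi_mask` returns `path` invisibly; `read_roi_mask` a
#'   logical matrix.
#' @export
write_roi_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0
}

#' Write / read a spectra matrix as CSV
#'
#' One row per sample: `sample_id`, `label` (DI, may be empty), then one
#' column per wavelength (named `wl_<nm>`).
#'
#' @param spectra A [spectra_matrix()].
#' @param path CSV file path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   a [spectra_matrix()].
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  df <- data.frame(sample_id = spectra$sample_ids,
                   label = if (is.null(spectra$labels)) NA_integer_ else
                     spectra$labels,
                   spectra$values, check.names = FALSE)
  colnames(df)[-(1:2)] <- sprintf("wl_%.6g", spectra$wavelengths)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(sub("^wl_", "", colnames(df)[-(1:2)]))
  labels <- if (all(is.na(df$label))) NULL else as.integer(df$label)
  spectra_matrix(as.matrix(df[, -(1:2), drop = FALSE]), wl,
                 sample_ids = df$sample_id, labels = labels)
}

#' Write a label sheet for a generated dataset
#'
#' @param sample_ids Character ids.
#' @param labels Integer DI labels.
#' @param path CSV path (`sample_id, DI`).
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(sample_ids, labels, path) {
  utils::write.csv(data.frame(sample_id = sample_ids, DI = as.integer(labels)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read a scene configuration as YAML
#'
#' Captures every [scene_config()] field (including the seed) so a synthetic
#' dataset can be regenerated bit-for-bit from its config file.
#'
#' @param cfg A [scene_config()].
#' @param path YAML file path.
#' @return `write_scene_config` returns `path` invisibly; `read_scene_config`
#'   a [scene_config()].
#' @export
write_scene_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scene_config"))
  fields <- unclass(cfg)
  fields$wavelengths <- NULL                # derived
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  do.call(scene_config, yaml::read_yaml(path))
}

#' Export one labeled scene to disk
#'
#' Writes the raw cube (ENVI), white/dark reference frames (ENVI, one line
#' each), and the ROI mask (PNG) under a common prefix.
#'
#' @param lc A [generate_scene()] result.
#' @param prefix Path prefix; files `<prefix>.raw`, `<prefix>.white`,
#'   `<prefix>.dark` (+ `.hdr`) and `<prefix>_mask.png` are created.
#' @return `prefix`, invisibly.
#' @export
write_scene <- function(lc, prefix) {
  stopifnot(inherits(lc, "labeled_cube"))
  write_envi(lc$cube, paste0(prefix, ".raw"))
  wl <- lc$cube$wavelengths
  frame_cube <- function(m) hypercube(array(m, c(1L, nrow(m), ncol(m))), wl)
  write_envi(frame_cube(lc$white), paste0(prefix, ".white"))
  write_envi(frame_cube(lc$dark), paste0(prefix, ".dark"))
  write_roi_mask(lc$roi_mask, paste0(prefix, "_mask.png"))
  invisible(prefix)
}
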