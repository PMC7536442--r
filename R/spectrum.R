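# Core containers: a single mass spectrum and a serial-section dataset
# (one 2D grid of spectra per tissue section).

#' Construct a mass spectrum
#'
#' @param mz Strictly ascending m/z values (Th).
#' @param intensity Nonnegative intensities, same length as `mz`.
#' @param polarity `"positive"` or `"negative"`.
#' @param centroided TRUE for stick (centroided) spectra, FALSE for
#'   profile spectra sampled on a dense m/z grid.
#' @return An object of class `"mass_spectrum"`.
#' @export
mass_spectrum <- function(mz, intensity, polarity = c("positive", "negative"),
                          centroided = TRUE) {
  polarity <- match.arg(polarity)
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (length(mz) > 1L && any(diff(mz) <= 0)) stop("mz must be strictly ascending")
  if (any(intensity < 0)) stop("intensities must be nonnegative")
  structure(list(mz = mz, intensity = intensity, polarity = polarity,
                 centroided = isTRUE(centroided)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d %s peaks, %s mode, TIC %.4g\n",
              length(x$mz), if (x$centroided) "centroided" else "profile",
              x$polarity, sum(x$intensity)))
  invisible(x)
}

#' Construct a section dataset
#'
#' One tissue section: a rectangular `rows x cols` grid of spectra at a
#' fixed pixel pitch. Missing pixels (off-slide, failed scans) are kept in
#' the grid as all-zero spectra and flagged in `missing` so matrices stay
#' rectangular.
#'
#' @param spectra List of `mass_spectrum`, length `rows * cols`, row-major
#'   (pixel (r, c) at index `(r - 1) * cols + c`, 0-based grid convention
#'   in all package APIs).
#' @param rows,cols Grid dimensions.
#' @param pitch_um In-plane pixel pitch (micrometres).
#' @param section_index 0-based index of the section in the series.
#' @param z_um z position of the section (micrometres).
#' @param polarity Shared polarity of all pixels.
#' @param missing Logical `rows x cols` matrix flagging missing pixels.
#' @return An object of class `"section_dataset"`.
#' @export
section_dataset <- function(spectra, rows, cols, pitch_um, section_index = 0L,
                            z_um = 0, polarity = c("positive", "negative"),
                            missing = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(rows >= 1L, cols >= 1L, pitch_um > 0)
  if (length(spectra) != rows * cols) {
    stop("need rows * cols = ", rows * cols, " spectra, got ", length(spectra))
  }
  pol <- vapply(spectra, function(s) s$polarity, character(1))
  if (!all(pol == polarity)) stop("all pixels must share the section polarity")
  if (is.null(missing)) missing <- matrix(FALSE, rows, cols)
  stopifnot(is.logical(missing), all(dim(missing) == c(rows, cols)))
  structure(list(spectra = spectra, rows = as.integer(rows),
                 cols = as.integer(cols), pitch_um = pitch_um,
                 section_index = as.integer(section_index), z_um = z_um,
                 polarity = polarity, missing = missing),
            class = "section_dataset")
}

#' @export
print.section_dataset <- function(x, ...) {
  cat(sprintf("<section_dataset> section %d: %d x %d px @ %g um, z = %g um, %s mode\n",
              x$section_index, x$rows, x$cols, x$pitch_um, x$z_um, x$polarity))
  invisible(x)
}

#' Pixel accessor
#' @param section A `section_dataset`.
#' @param row,col 0-based pixel coordinates.
#' @return The pixel's `mass_spectrum`.
#' @export
get_pixel <- function(section, row, col) {
  stopifnot(row >= 0, row < section$rows, col >= 0, col < section$cols)
  section$spectra[[row * section$cols + col + 1L]]
}

#' Total-ion-current image of a section
#'
#' @param section A `section_dataset`.
#' @return A `rows x cols` matrix of per-pixel intensity sums (the TIC
#'   image used for tissue detection and registration).
#' @export
tic_image <- function(section) {
  t(matrix(vapply(section$spectra, function(s) sum(s$intensity), numeric(1)),
           nrow = section$cols, ncol = section$rows))
}

#' Single-ion image of a section
#'
#' Sums intensity within a ppm window around a target m/z, per pixel.
#'
#' @param section A `section_dataset`.
#' @param mz Target m/z.
#' @param tolerance_ppm Half-window in ppm (default 30).
#' @return A `rows x cols` matrix.
#' @export
ion_image <- function(section, mz, tolerance_ppm = 30) {
  tol <- mz * tolerance_ppm * 1e-6
  vals <- vapply(section$spectra, function(s) {
    sel <- abs(s$mz - mz) <= tol
    if (any(sel)) sum(s$intensity[sel]) else 0
  }, numeric(1))
  t(matrix(vals, nrow = section$cols, ncol = section$rows))
}
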