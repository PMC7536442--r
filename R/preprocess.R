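# Spectrum-level preprocessing: TIC normalisation, peak picking,
# mass-range filtering and cross-section m/z binning into the shared
# nonnegative pixels x bins matrix consumed by the factorisation.

#' TIC-normalise a spectrum
#'
#' Scales intensities so their sum (the total ion current) equals `target`.
#' TIC normalisation removes pixel-to-pixel sensitivity drift so that
#' intensities are comparable across pixels and sections.
#'
#' @param spectrum A `mass_spectrum` with at least one positive intensity.
#' @param target Target TIC (default 1).
#' @return The normalised `mass_spectrum` (m/z unchanged).
#' @export
tic_normalize <- function(spectrum, target = 1) {
  stopifnot(inherits(spectrum, "mass_spectrum"), target > 0)
  tic <- sum(spectrum$intensity)
  if (tic <= 0) {
    stop("cannot TIC-normalise an all-zero spectrum (flag the pixel missing)")
  }
  spectrum$intensity <- spectrum$intensity * (target / tic)
  spectrum
}

#' TIC-normalise every pixel of a section
#'
#' All-zero pixels cannot be normalised; they are zeroed and flagged in the
#' section's `missing` mask rather than raising an error, so batch runs
#' survive off-slide pixels.
#'
#' @param section A `section_dataset`.
#' @param target Target TIC per pixel.
#' @return The section with normalised spectra and an updated missing mask.
#' @export
tic_normalize_section <- function(section, target = 1) {
  for (r in seq_len(section$rows) - 1L) {
    for (c in seq_len(section$cols) - 1L) {
      i <- r * section$cols + c + 1L
      s <- section$spectra[[i]]
      if (sum(s$intensity) <= 0) {
        section$missing[r + 1L, c + 1L] <- TRUE
      } else {
        section$spectra[[i]] <- tic_normalize(s, target)
      }
    }
  }
  section
}

#' Pick peaks from a profile spectrum
#'
#' Local maxima above an SNR threshold are centroided by intensity-weighted
#' mean m/z over a window. Noise is estimated robustly as
#' 1.4826 x median absolute deviation of the profile intensities. At equal
#' neighbouring intensities (a plateau) the lower-m/z sample is the
#' maximum, making the picker deterministic. Centroided spectra pass
#' through unchanged.
#'
#' @param spectrum A `mass_spectrum`.
#' @param snr Signal-to-noise threshold (default 3).
#' @param window Centroiding window width in Th (default 0.05); the
#'   weighted mean runs over samples within `window / 2` of the maximum.
#' @return A centroided `mass_spectrum` of (centroid m/z, peak height).
#' @export
pick_peaks <- function(spectrum, snr = 3, window = 0.05) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  if (!is.numeric(window) || window <= 0) stop("window must be positive")
  if (spectrum$centroided) return(spectrum)
  y <- spectrum$intensity; x <- spectrum$mz; n <- length(y)
  empty <- mass_spectrum(numeric(0), numeric(0), spectrum$polarity, TRUE)
  if (n < 3L) return(empty)
  noise <- 1.4826 * stats::mad(y, constant = 1)
  # local maxima: > left neighbour, >= right neighbour (plateaus keep the
  # lower-m/z sample)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max & y > snr * noise & y > 0)
  if (!length(idx)) return(empty)
  cen <- numeric(length(idx)); ht <- numeric(length(idx))
  half <- window / 2
  for (k in seq_along(idx)) {
    i <- idx[k]
    sel <- which(abs(x - x[i]) <= half & y > 0)
    cen[k] <- sum(x[sel] * y[sel]) / sum(y[sel])
    ht[k] <- y[i]
  }
  o <- order(cen)
  cen <- cen[o]; ht <- ht[o]
  keep <- c(TRUE, diff(cen) > 0)
  mass_spectrum(cen[keep], ht[keep], spectrum$polarity, TRUE)
}

#' Restrict peaks to a mass range
#'
#' Retains peaks with `low <= m/z <= high` (closed interval). The
#' acquisition window of the emulated experiment is m/z 50-1200.
#'
#' @param spectrum A `mass_spectrum`.
#' @param low,high Range bounds in Th, `low < high`.
#' @return The filtered `mass_spectrum`.
#' @export
filter_mass_range <- function(spectrum, low = 50, high = 1200) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (!(low < high)) stop("require low < high")
  keep <- spectrum$mz >= low & spectrum$mz <= high
  spectrum$mz <- spectrum$mz[keep]
  spectrum$intensity <- spectrum$intensity[keep]
  spectrum
}

# split a sorted cluster of centroids at its largest internal gap until no
# cluster is wider than tol (in ppm of its centre)
.split_cluster <- function(mz, w, tol_ppm) {
  width_ppm <- (mz[length(mz)] - mz[1]) / stats::weighted.mean(mz, w) * 1e6
  if (length(mz) == 1L || width_ppm <= tol_ppm) return(list(list(mz = mz, w = w)))
  gaps <- diff(mz)
  cut <- which.max(gaps)
  c(.split_cluster(mz[1:cut], w[1:cut], tol_ppm),
    .split_cluster(mz[(cut + 1):length(mz)], w[(cut + 1):length(mz)], tol_ppm))
}

#' Bin centroided peaks from many sections onto one m/z axis
#'
#' Pools every centroid from every pixel of every section, clusters them by
#' 1D single linkage (adjacent centroids closer than `tolerance_ppm` join
#' one bin), splits any cluster wider than the tolerance at its largest
#' internal gap, and sums each pixel's peak intensities per bin. Bin
#' centres are intensity-weighted means. The result is the nonnegative
#' pixels x bins data matrix the non-negative matrix factorisation runs on.
#'
#' @param sections List of centroided `section_dataset`s, all of one
#'   polarity.
#' @param tolerance_ppm Linkage/width tolerance in ppm (default 10).
#' @return A list of class `"data_matrix"`: `matrix` (pixels x bins,
#'   nonnegative), `bin_centers` (ascending m/z), `pixel_map` (data.frame
#'   `section, row, col` per matrix row, 0-based), `polarity`.
#' @export
bin_peaks <- function(sections, tolerance_ppm = 10) {
  stopifnot(length(sections) >= 1L)
  pol <- unique(vapply(sections, function(s) s$polarity, character(1)))
  if (length(pol) != 1L) stop("mixed polarity: bin each mode separately")
  all_mz <- list(); all_int <- list(); all_pix <- list()
  pix_rows <- list()
  row_id <- 0L
  for (si in seq_along(sections)) {
    sec <- sections[[si]]
    for (r in seq_len(sec$rows) - 1L) {
      for (c in seq_len(sec$cols) - 1L) {
        row_id <- row_id + 1L
        s <- sec$spectra[[r * sec$cols + c + 1L]]
        pix_rows[[row_id]] <- c(sec$section_index, r, c)
        if (length(s$mz)) {
          all_mz[[row_id]] <- s$mz
          all_int[[row_id]] <- s$intensity
          all_pix[[row_id]] <- rep.int(row_id, length(s$mz))
        }
      }
    }
  }
  mz <- unlist(all_mz); w <- unlist(all_int); pix <- unlist(all_pix)
  if (!length(mz)) stop("no peaks to bin")
  o <- order(mz)
  mz <- mz[o]; w <- w[o]; pix <- pix[o]
  # single linkage: break where the gap to the previous centroid exceeds tol
  tol_rel <- tolerance_ppm * 1e-6
  brk <- c(TRUE, diff(mz) > tol_rel * mz[-length(mz)])
  cl <- cumsum(brk)
  centers <- numeric(0); bin_of <- integer(length(mz))
  nb <- 0L
  for (g in split(seq_along(mz), cl)) {
    parts <- .split_cluster(mz[g], w[g], tolerance_ppm)
    off <- 0L
    for (p in parts) {
      nb <- nb + 1L
      take <- g[(off + 1L):(off + length(p$mz))]
      off <- off + length(p$mz)
      bin_of[take] <- nb
      centers[nb] <- stats::weighted.mean(p$mz, p$w)
    }
  }
  n_pix <- row_id
  X <- matrix(0, n_pix, nb)
  for (i in seq_along(mz)) X[pix[i], bin_of[i]] <- X[pix[i], bin_of[i]] + w[i]
  o2 <- order(centers)
  X <- X[, o2, drop = FALSE]
  centers <- centers[o2]
  pm <- do.call(rbind, pix_rows)
  structure(list(matrix = X, bin_centers = centers,
                 pixel_map = data.frame(section = pm[, 1], row = pm[, 2],
                                        col = pm[, 3]),
                 polarity = pol),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d pixels x %d m/z bins (%s mode)\n",
              nrow(x$matrix), ncol(x$matrix), x$polarity))
  invisible(x)
}
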