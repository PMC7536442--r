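# Fluorescence mask extraction, resampling onto the MSI grid, and spatial
# statistics between ion distributions and hypoxia masks, including the
# normalized band-depth statistic that quantifies a band lying "in the
# midst" of the stained region rather than at its rim.

#' Automatic threshold by the isodata (iterative intermeans) method
#'
#' The "default" automatic threshold of common image-analysis software:
#' from the mid-range starting point, iterate
#' t <- (mean(values <= t) + mean(values > t)) / 2 to convergence on a
#' 256-bin histogram. Because the histogram is built on the image's own
#' range, the mask is invariant under affine intensity rescaling with
#' positive slope.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param nbins Histogram bins (default 256).
#' @return An object of class `"binary_mask"`: `mask` (logical matrix,
#'   pixels strictly above threshold), `threshold`, `method`, `pitch_um`
#'   (NA until known).
#' @export
threshold_mask <- function(image, nbins = 256L) {
  stopifnot(is.matrix(image), is.numeric(image))
  rng <- range(image)
  if (rng[1] == rng[2]) stop("cannot threshold a constant image")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(pmin(findInterval(image, edges, rightmost.closed = TRUE),
                          nbins), nbins)
  t_cur <- mean(rng)
  for (i in 1:1000) {
    lo <- mids <= t_cur
    n_lo <- sum(counts[lo]); n_hi <- sum(counts[!lo])
    if (n_lo == 0 || n_hi == 0) break
    mu_lo <- sum(mids[lo] * counts[lo]) / n_lo
    mu_hi <- sum(mids[!lo] * counts[!lo]) / n_hi
    t_new <- (mu_lo + mu_hi) / 2
    if (abs(t_new - t_cur) < diff(rng) * 1e-12) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  structure(list(mask = image > t_cur, threshold = t_cur,
                 method = "isodata", pitch_um = NA_real_),
            class = "binary_mask")
}

#' Construct a binary mask from a logical matrix
#' @param mask Logical matrix.
#' @param pitch_um Pixel pitch (um).
#' @param threshold,method Provenance of the mask, if any.
#' @return A `"binary_mask"`.
#' @export
binary_mask <- function(mask, pitch_um = NA_real_, threshold = NA_real_,
                        method = "manual") {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, threshold = threshold, method = method,
                 pitch_um = pitch_um), class = "binary_mask")
}

.as_mask_matrix <- function(m) {
  if (inherits(m, "binary_mask")) m$mask else {
    stopifnot(is.matrix(m), is.logical(m)); m
  }
}

#' Resample a fine-pitch mask onto the coarser MSI grid
#'
#' Fluorescence is scanned on a much finer grid (micrometre-scale) than the
#' 120 um MSI raster; an MSI pixel becomes mask-positive when the fraction
#' of the fine pixels it covers that are positive reaches
#' `coverage`.
#'
#' @param mask A `binary_mask` (or logical matrix) at the fine pitch.
#' @param source_pitch_um,target_pitch_um Pitches; the ratio must be a
#'   whole number and divide the mask dimensions.
#' @param coverage Minimum positive coverage fraction (default 0.5).
#' @return A `binary_mask` on the MSI grid.
#' @export
resample_mask <- function(mask, source_pitch_um, target_pitch_um,
                          coverage = 0.5) {
  m <- .as_mask_matrix(mask)
  stopifnot(target_pitch_um >= source_pitch_um, coverage > 0, coverage <= 1)
  f <- target_pitch_um / source_pitch_um
  if (abs(f - round(f)) > 1e-9) {
    stop("pitch ratio ", f, " is not an integer; cannot resample on grids")
  }
  f <- as.integer(round(f))
  if (nrow(m) %% f != 0 || ncol(m) %% f != 0) {
    stop("mask dimensions not divisible by pitch ratio ", f)
  }
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  out <- matrix(FALSE, nr, nc)
  num <- matrix(as.numeric(m), nrow(m), ncol(m))
  for (r in seq_len(nr)) {
    rows <- ((r - 1) * f + 1):(r * f)
    block <- num[rows, , drop = FALSE]
    sums <- colSums(block)
    agg <- vapply(seq_len(nc), function(c) {
      sum(sums[((c - 1) * f + 1):(c * f)])
    }, numeric(1))
    out[r, ] <- agg / f^2 >= coverage
  }
  binary_mask(out, pitch_um = target_pitch_um,
              method = sprintf("resample(x%d, coverage=%g)", f, coverage))
}

#' Co-localization statistics between an ion distribution and a mask
#'
#' Dice is computed between the reference mask and the ion mask (the
#' continuous ion image is auto-thresholded by [threshold_mask()] within
#' tissue). M1 is the fraction of total ion intensity falling inside the
#' reference; M2 the fraction of the reference covered by the ion mask.
#' Pearson r correlates the continuous ion image with the (0/1) reference.
#' All statistics are restricted to tissue pixels: background would
#' inflate every coefficient.
#'
#' @param ion Numeric matrix (continuous ion image) or logical matrix /
#'   `binary_mask` (pre-thresholded).
#' @param reference A `binary_mask` (or logical matrix) on the same grid.
#' @param tissue Optional logical matrix restricting the comparison.
#' @return An object of class `"coloc_stats"`: `dice`, `m1`, `m2`,
#'   `pearson`, `n_pixels`.
#' @export
overlap_stats <- function(ion, reference, tissue = NULL) {
  ref <- .as_mask_matrix(reference)
  is_cont <- is.numeric(ion) && !inherits(ion, "binary_mask")
  ion_img <- if (is_cont) ion else NULL
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(ref), ncol(ref))
  stopifnot(all(dim(ref) == dim(tissue)))
  if (sum(tissue) == 0) stop("co-localization undefined: no tissue pixels")
  if (is_cont) {
    stopifnot(all(dim(ion) == dim(ref)))
    masked <- ion
    masked[!tissue] <- NA
    vals <- masked[tissue]
    if (length(unique(vals)) < 2) {
      stop("co-localization undefined: constant ion image over tissue")
    }
    tm <- threshold_mask(matrix(vals, ncol = 1))
    ion_mask <- ion > tm$threshold & tissue
  } else {
    ion_mask <- .as_mask_matrix(ion) & tissue
  }
  ref_t <- ref & tissue
  dice <- dice_coefficient(ion_mask, ref_t)
  if (is_cont) {
    tot <- sum(ion_img[tissue])
    if (tot <= 0) stop("co-localization undefined: zero total ion intensity")
    m1 <- sum(ion_img[ref_t]) / tot
    pear <- stats::cor(ion_img[tissue], as.numeric(ref_t[tissue]))
  } else {
    if (sum(ion_mask) == 0) stop("co-localization undefined: empty ion mask")
    m1 <- sum(ion_mask & ref_t) / sum(ion_mask)
    v <- as.numeric(ion_mask[tissue])
    if (stats::sd(v) == 0 || stats::sd(as.numeric(ref_t[tissue])) == 0) {
      stop("co-localization undefined: constant mask over tissue")
    }
    pear <- stats::cor(v, as.numeric(ref_t[tissue]))
  }
  if (sum(ref_t) == 0) stop("co-localization undefined: empty reference mask")
  m2 <- sum(ref_t & ion_mask) / sum(ref_t)
  structure(list(dice = dice, m1 = m1, m2 = m2, pearson = pear,
                 n_pixels = sum(tissue)), class = "coloc_stats")
}

#' @export
print.coloc_stats <- function(x, ...) {
  cat(sprintf("<coloc_stats> Dice %.3f | M1 %.3f | M2 %.3f | Pearson %.3f (n = %d)\n",
              x$dice, x$m1, x$m2, x$pearson, x$n_pixels))
  invisible(x)
}

#' Normalized band depth of an ion distribution inside a reference mask
#'
#' For every pixel of the reference mask the Euclidean distance transform
#' gives its distance to the nearest background pixel; depths are
#' normalized per connected component as (d - 1) / (dmax - 1), so the
#' boundary ring is depth 0 and the deepest interior pixel depth 1. The
#' statistic summarises where the ion-positive pixels sit within the
#' stained region: a median depth near 0.5 means a band through the middle
#' of the region, near 0 a boundary rim.
#'
#' @param ion_mask Ion-positive mask (`binary_mask` or logical matrix).
#' @param reference Reference (e.g. hypoxia) mask, nonempty, same grid.
#' @return An object of class `"band_stats"`: `depths` (per ion-positive
#'   in-mask pixel), `median_depth`, `fraction_outside` (ion-positive
#'   pixels falling outside the reference), `n_inside`.
#' @export
band_depth <- function(ion_mask, reference) {
  ion <- .as_mask_matrix(ion_mask)
  ref <- .as_mask_matrix(reference)
  stopifnot(all(dim(ion) == dim(ref)))
  if (sum(ref) == 0) stop("band depth undefined: empty reference mask")
  d <- EBImage::distmap(matrix(as.numeric(ref), nrow(ref), ncol(ref)))
  comp <- EBImage::bwlabel(matrix(as.numeric(ref), nrow(ref), ncol(ref)))
  depth <- matrix(0, nrow(ref), ncol(ref))
  for (lab in seq_len(max(comp))) {
    sel <- comp == lab
    dmax <- max(d[sel])
    depth[sel] <- if (dmax > 1) (d[sel] - 1) / (dmax - 1) else 0
  }
  inside <- ion & ref
  if (sum(inside) == 0) {
    stop("band depth undefined: no ion-positive pixels inside the reference")
  }
  depths <- depth[inside]
  structure(list(depths = depths, median_depth = stats::median(depths),
                 fraction_outside = sum(ion & !ref) / max(sum(ion), 1),
                 n_inside = sum(inside)), class = "band_stats")
}

#' @export
print.band_stats <- function(x, ...) {
  cat(sprintf("<band_stats> median depth %.3f over %d pixels (%.1f%% outside reference)\n",
              x$median_depth, x$n_inside, 100 * x$fraction_outside))
  invisible(x)
}
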