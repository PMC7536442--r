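# Rigid section alignment: per-section rotation + translation estimated by
# normalized cross-correlation on TIC images, applied by inverse-mapping
# bilinear resampling, and stacking of aligned sections into an isotropic
# volume.

#' Construct a 2D rigid transform
#'
#' Rotation (counter-clockwise in the x-right / y-up display convention,
#' about the grid centre) followed by a translation in micrometres.
#'
#' @param angle_deg Rotation in degrees, in (-180, 180].
#' @param tx_um,ty_um Translation along columns (x) and rows (y), um.
#' @return An object of class `"rigid_transform"`.
#' @export
rigid_transform <- function(angle_deg = 0, tx_um = 0, ty_um = 0) {
  stopifnot(is.finite(angle_deg), is.finite(tx_um), is.finite(ty_um))
  a <- ((angle_deg + 180) %% 360) - 180
  if (a == -180) a <- 180
  structure(list(angle_deg = a, tx_um = tx_um, ty_um = ty_um),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> %+.3f deg, t = (%+.1f, %+.1f) um\n",
              x$angle_deg, x$tx_um, x$ty_um))
  invisible(x)
}

.rotmat <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse transform (composing the two gives the identity).
#' @export
invert_transform <- function(tf) {
  t2 <- -.rotmat(tf$angle_deg) %*% c(tf$tx_um, tf$ty_um)
  rigid_transform(-tf$angle_deg, t2[1], t2[2])
}

#' Compose two rigid transforms
#' @param first,second Transforms; `second` is applied after `first`.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(first, second) {
  t <- .rotmat(-second$angle_deg) %*% c(first$tx_um, first$ty_um) +
    c(second$tx_um, second$ty_um)
  rigid_transform(first$angle_deg + second$angle_deg, t[1], t[2])
}

# bilinear sample of image `img` at fractional (row, col) positions;
# outside the grid -> 0
.bilinear_sample <- function(img, rr, cc) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  val <- numeric(length(rr))
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  val <- at(r0, c0) * (1 - fr) * (1 - fc) +
    at(r0 + 1, c0) * fr * (1 - fc) +
    at(r0, c0 + 1) * (1 - fr) * fc +
    at(r0 + 1, c0 + 1) * fr * fc
  val
}

#' Apply a rigid transform to a section image
#'
#' Resamples by inverse mapping: bilinear interpolation for continuous
#' intensities, nearest-neighbour for labels and masks. Pixels mapping
#' outside the input grid are filled with 0.
#'
#' @param img Numeric (or logical/integer for `interpolation = "nearest"`)
#'   matrix; rows are y, columns are x.
#' @param tf A `rigid_transform`.
#' @param pitch_um Pixel pitch, used to convert the translation to pixels.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return The resampled matrix, same shape and storage mode as the input.
#' @export
apply_transform <- function(img, tf, pitch_um = 1,
                            interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.matrix(img), inherits(tf, "rigid_transform"), pitch_um > 0)
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  tx <- tf$tx_um / pitch_um; ty <- tf$ty_um / pitch_um
  # output pixel (x', y') came from input R^-1 ((x', y') - c - t) + c;
  # display y axis points down, so a CCW angle maps to -theta in index space
  Rinv <- .rotmat(tf$angle_deg)   # inverse of the index-space rotation
  gx <- rep(seq_len(nc), each = nr)
  gy <- rep(seq_len(nr), times = nc)
  dx <- gx - cx - tx; dy <- gy - cy - ty
  sx <- Rinv[1, 1] * dx + Rinv[1, 2] * dy + cx
  sy <- Rinv[2, 1] * dx + Rinv[2, 2] * dy + cy
  if (interpolation == "bilinear") {
    out <- matrix(.bilinear_sample(img + 0, sy, sx), nr, nc)
  } else {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- rep(0, length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    out <- matrix(v, nr, nc)
    storage.mode(out) <- storage.mode(img)
  }
  out
}

# integer-shifted copy of img (zero fill); s = c(dy, dx)
.shift_image <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rs) && length(cs)) out[rs, cs] <- img[rs - dy, cs - dx]
  out
}

.ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# intensity centroid (row, col) of a nonnegative image
.image_centroid <- function(img) {
  tot <- sum(img)
  if (tot <= 0) return(c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2))
  c(sum(row(img) * img), sum(col(img) * img)) / tot
}

# best integer shift (+ parabolic sub-pixel refinement) for a fixed angle,
# searched around the intensity-centroid offset so the window stays valid
# even when the cumulative shift exceeds max_shift; returns
# list(dy, dx, score)
.best_shift <- function(moved, fixed, max_shift) {
  m <- max_shift
  c0 <- round(.image_centroid(fixed) - .image_centroid(moved))
  shifts <- expand.grid(dy = c0[1] + (-m:m), dx = c0[2] + (-m:m))
  shifts <- shifts[order(shifts$dy^2 + shifts$dx^2, abs(shifts$dy),
                         abs(shifts$dx)), ]
  surf <- matrix(NA_real_, 2 * m + 1, 2 * m + 1) # [dy - c0[1] + m + 1, ...]
  best <- list(dy = c0[1], dx = c0[2], score = -Inf)
  for (i in seq_len(nrow(shifts))) {
    dy <- shifts$dy[i]; dx <- shifts$dx[i]
    sc <- .ncc(.shift_image(moved, dy, dx), fixed)
    surf[dy - c0[1] + m + 1, dx - c0[2] + m + 1] <- sc
    if (!is.na(sc) && sc > best$score) best <- list(dy = dy, dx = dx, score = sc)
  }
  # parabolic sub-pixel refinement along each axis where neighbours exist
  refine <- function(im1, i0, ip1, x0) {
    if (any(is.na(c(im1, i0, ip1)))) return(x0)
    den <- im1 - 2 * i0 + ip1
    if (den >= 0) return(x0)          # not a local max
    x0 + 0.5 * (im1 - ip1) / den
  }
  iy <- best$dy - c0[1] + m + 1; ix <- best$dx - c0[2] + m + 1
  dy <- best$dy; dx <- best$dx
  if (iy > 1 && iy < 2 * m + 1) {
    dy <- refine(surf[iy - 1, ix], surf[iy, ix], surf[iy + 1, ix], best$dy)
  }
  if (ix > 1 && ix < 2 * m + 1) {
    dx <- refine(surf[iy, ix - 1], surf[iy, ix], surf[iy, ix + 1], best$dx)
  }
  list(dy = dy, dx = dx, score = best$score)
}

#' Estimate the rigid transform aligning one TIC image onto another
#'
#' Exhaustive search over an angle grid; for each angle the moving image is
#' rotated and the best translation found by normalized cross-correlation
#' over integer shifts centred on the intensity-centroid offset between the
#' two images, with parabolic sub-pixel refinement of both the shift and
#' (in a second pass at 0.1 degree step) the angle. Deterministic:
#' angles are visited in order of |angle| and shifts in order of |shift|,
#' and only strictly better scores replace the incumbent, so ties resolve
#' to the smaller |angle|, then the smaller |shift|.
#'
#' @param moving,fixed Nonnegative TIC images of equal shape and pitch.
#' @param angle_grid_deg Candidate rotations in degrees (default -15 to 15
#'   by 0.5).
#' @param max_shift_px Maximum |translation| searched, pixels (default 5).
#' @param pitch_um Pixel pitch used to report the translation in um.
#' @param refine_step_deg Step of the local angle refinement pass
#'   (default 0.1; set NULL to skip).
#' @param polish Continuously polish (angle, shift) by Nelder-Mead on the
#'   NCC of the fully warped image (default TRUE). The grid search scores
#'   integer shifts, whose interpolation bias flattens the angle peak; the
#'   polish recovers sub-pixel, sub-tenth-degree alignment.
#' @return A `rigid_transform` with attribute `"score"` (the NCC of the
#'   best alignment). Applying it to `moving` reproduces `fixed` up to
#'   interpolation.
#' @export
estimate_rigid <- function(moving, fixed,
                           angle_grid_deg = seq(-15, 15, by = 0.5),
                           max_shift_px = 5, pitch_um = 1,
                           refine_step_deg = 0.1, polish = TRUE) {
  stopifnot(is.matrix(moving), is.matrix(fixed),
            all(dim(moving) == dim(fixed)))
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0) {
    stop("registration failed: blank image (no tissue contrast)")
  }
  search_angles <- function(angles, incumbent) {
    for (a in angles[order(abs(angles))]) {
      moved <- if (a == 0) moving else {
        apply_transform(moving, rigid_transform(a, 0, 0), pitch_um)
      }
      bs <- .best_shift(moved, fixed, max_shift_px)
      if (bs$score > incumbent$score) {
        incumbent <- list(angle = a, dy = bs$dy, dx = bs$dx, score = bs$score)
      }
    }
    incumbent
  }
  best <- search_angles(angle_grid_deg,
                        list(angle = 0, dy = 0, dx = 0, score = -Inf))
  if (!is.null(refine_step_deg) && length(angle_grid_deg) > 1) {
    coarse <- min(diff(sort(angle_grid_deg)))
    fine <- seq(best$angle - coarse, best$angle + coarse, by = refine_step_deg)
    fine <- setdiff(round(fine, 10), round(angle_grid_deg, 10))
    if (length(fine)) best <- search_angles(fine, best)
  }
  score <- best$score
  if (polish) {
    obj <- function(p) {
      warped <- apply_transform(moving, rigid_transform(p[1], p[2] * pitch_um,
                                                        p[3] * pitch_um),
                                pitch_um)
      sc <- .ncc(warped, fixed)
      if (is.na(sc)) 1 else -sc
    }
    opt <- stats::optim(c(best$angle, best$dx, best$dy), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = 300))
    if (-opt$value >= best$score) {
      best <- list(angle = opt$par[1], dx = opt$par[2], dy = opt$par[3])
      score <- -opt$value
    }
  }
  out <- rigid_transform(best$angle, best$dx * pitch_um, best$dy * pitch_um)
  attr(out, "score") <- score
  out
}

#' Chain-register a series of TIC images
#'
#' Section 0 is the reference; every later section is registered to its
#' already-aligned predecessor (adjacent sections are the most similar).
#' The translation search is anchored on the intensity-centroid offset
#' between the two images (see [estimate_rigid()]), so cumulative shifts
#' larger than the per-pair search window do not derail the chain.
#'
#' @param tic_images List of TIC images, in z order.
#' @param pitch_um Pixel pitch (um).
#' @param ... Passed to [estimate_rigid()].
#' @return List of `rigid_transform`, one per section (identity first).
#' @export
register_series <- function(tic_images, pitch_um = 1, ...) {
  n <- length(tic_images)
  stopifnot(n >= 1)
  tfs <- vector("list", n)
  tfs[[1]] <- rigid_transform(0, 0, 0)
  ref <- tic_images[[1]]
  for (i in seq_len(n - 1) + 1) {
    tfs[[i]] <- estimate_rigid(tic_images[[i]], ref, pitch_um = pitch_um, ...)
    ref <- apply_transform(tic_images[[i]], tfs[[i]], pitch_um)
  }
  tfs
}

#' Stack aligned section images into a volume
#'
#' @param images List of aligned 2D matrices (one per section, equal shape),
#'   ordered by z.
#' @param pixel_pitch_um In-plane pixel pitch (um).
#' @param z_step_um Section spacing (um). Equal in-plane pitch and z step
#'   give isotropic voxels.
#' @return An object of class `"msi_volume"`: `data` (array nz x rows x
#'   cols), `pitch_um` (dz, dy, dx), `isotropic` flag, `transforms`
#'   provenance (if supplied via attribute).
#' @export
stack_volume <- function(images, pixel_pitch_um, z_step_um,
                         transforms = NULL) {
  stopifnot(length(images) >= 1, pixel_pitch_um > 0, z_step_um > 0)
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("cannot stack: sections have mismatched shapes")
  }
  nz <- length(images)
  arr <- array(0, c(nz, dims[1, 1], dims[2, 1]))
  for (i in seq_len(nz)) arr[i, , ] <- images[[i]]
  iso <- isTRUE(all.equal(pixel_pitch_um, z_step_um))
  if (!iso) {
    warning("anisotropic voxels: z step ", z_step_um, " um vs pixel pitch ",
            pixel_pitch_um, " um")
  }
  structure(list(data = arr,
                 pitch_um = c(dz = z_step_um, dy = pixel_pitch_um,
                              dx = pixel_pitch_um),
                 isotropic = iso, transforms = transforms),
            class = "msi_volume")
}

#' @export
print.msi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<msi_volume> %d x %d x %d voxels @ (%g, %g, %g) um%s\n",
              d[1], d[2], d[3], x$pitch_um[1], x$pitch_um[2], x$pitch_um[3],
              if (x$isotropic) " (isotropic)" else ""))
  invisible(x)
}

#' Write per-section transforms to CSV
#' @param transforms List of `rigid_transform`.
#' @param path Output CSV (`section, angle_deg, tx_um, ty_um`).
#' @export
write_transforms <- function(transforms, path) {
  df <- data.frame(section = seq_along(transforms) - 1L,
                   angle_deg = vapply(transforms, `[[`, numeric(1), "angle_deg"),
                   tx_um = vapply(transforms, `[[`, numeric(1), "tx_um"),
                   ty_um = vapply(transforms, `[[`, numeric(1), "ty_um"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read per-section transforms from CSV
#' @param path CSV written by [write_transforms()].
#' @return List of `rigid_transform` in section order.
#' @export
read_transforms <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$section), ]
  lapply(seq_len(nrow(df)), function(i) {
    rigid_transform(df$angle_deg[i], df$tx_um[i], df$ty_um[i])
  })
}
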