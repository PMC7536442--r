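# Ground-truthed synthetic serial-section DESI-MSI phantom. The default
# phantom emulates a xenograft tumour imaged as 15 sections at 120 um
# steps with 120 um pixels: a viable rim carrying the PI(38:4)-like
# negative-mode signal, a hypoxic core expressing a CA-9-like fluorescence
# marker, and a thin acylcarnitine band (m/z 400/428) at intermediate
# depth inside the stained core. Every section receives a planted rigid
# misalignment, a per-pixel log-normal TIC factor, an additive half-normal
# intensity floor and ppm-scale m/z jitter, so that TIC normalisation,
# binning and registration all have real work to do.

.default_regions <- function(center, core_center, semi_tumour, semi_core,
                             band_depth) {
  list(
    viable = list(
      label = "viable",
      geometry = list(type = "ellipsoid", center = center,
                      semi = semi_tumour),
      channels = list(
        positive = data.frame(mz = c(760.5851, 782.5670),
                              intensity = c(100, 60)),
        negative = data.frame(mz = c(885.5499, 788.5447),
                              intensity = c(100, 50)))),
    hypoxic = list(
      label = "hypoxic",
      geometry = list(type = "ellipsoid", center = core_center,
                      semi = semi_core),
      channels = list(
        positive = data.frame(mz = c(756.5514, 734.5694),
                              intensity = c(90, 50)),
        negative = data.frame(mz = c(281.2486, 255.2330),
                              intensity = c(90, 60)))),
    band = list(
      label = "band",
      geometry = list(type = "band_at_depth",
                      parent = list(center = core_center, semi = semi_core),
                      depth_range = band_depth),
      channels = list(
        positive = data.frame(mz = c(400.3421, 428.3734, 369.2999),
                              intensity = c(80, 100, 40)),
        negative = data.frame(mz = c(480.3090, 564.3300),
                              intensity = c(70, 40))))
  )
}

.default_background <- function() {
  list(positive = data.frame(mz = c(59.0497, 157.0353, 301.1410),
                             intensity = c(2, 1.5, 1)),
       negative = data.frame(mz = c(89.0244, 146.9600, 311.1700),
                             intensity = c(2, 1.5, 1)))
}

#' Specify a serial-section phantom
#'
#' Defaults emulate the acquisition this package targets: 15 sections at
#' 120 um z step, 120 um in-plane pixels on a 50 x 50 grid, both
#' polarities, a 20% per-pixel TIC coefficient of variation, 5 ppm m/z
#' jitter, and per-section misalignment up to 10 degrees / 360 um
#' (section 0 is the untouched reference). Region geometry primitives are
#' `ellipsoid`, `shell` (ellipsoid minus concentric ellipsoid) and
#' `band_at_depth` (pixels of a parent ellipsoid's per-slice cross-section
#' whose normalized 2D boundary depth falls in a range).
#'
#' @param shape Grid `c(ny, nx, nz)` in voxels.
#' @param pitch_um In-plane pixel pitch (um).
#' @param z_step_um Section spacing (um).
#' @param regions Named list of region definitions (label, geometry,
#'   per-polarity signature channels); default the three-region tumour.
#' @param background_channels Per-polarity solvent peaks present on every
#'   pixel at low intensity (tissue detection must beat them).
#' @param tic_cv Coefficient of variation of the log-normal per-pixel TIC
#'   factor (default 0.2).
#' @param additive_sd Scale of the additive half-normal intensity floor
#'   (default 0.5, in raw intensity units).
#' @param mz_jitter_ppm Per-peak Gaussian m/z jitter (default 5 ppm).
#' @param rot_range_deg,trans_range_um Uniform misalignment ranges per
#'   section (default 10 degrees, 360 um).
#' @param mass_range Acquisition window in Th (default c(50, 1200)).
#' @param fluor_regions Region labels expressing the CA-9-like marker
#'   (default hypoxic core and band).
#' @param fluor_level,fluor_background,fluor_noise_sd Mean gray levels and
#'   noise of the fluorescence render.
#' @param fluor_fine_factor Fluorescence grid refinement over the MSI grid
#'   (default 4, emulating a high-resolution slide scan).
#' @param profile Render Gaussian profile spectra instead of centroided
#'   sticks (exercises the peak picker).
#' @param profile_sigma Gaussian peak width in Th for profile mode.
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   phantoms.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(ny = 50L, nx = 50L, nz = 15L),
                         pitch_um = 120, z_step_um = 120,
                         regions = NULL,
                         background_channels = .default_background(),
                         tic_cv = 0.2, additive_sd = 0.5, mz_jitter_ppm = 5,
                         rot_range_deg = 10, trans_range_um = 360,
                         mass_range = c(50, 1200),
                         fluor_regions = c("hypoxic", "band"),
                         fluor_level = 200, fluor_background = 10,
                         fluor_noise_sd = 8, fluor_fine_factor = 4L,
                         profile = FALSE, profile_sigma = 0.01,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), pitch_um > 0, z_step_um > 0,
            tic_cv >= 0, additive_sd >= 0, mz_jitter_ppm >= 0,
            is.finite(rot_range_deg), is.finite(trans_range_um),
            rot_range_deg >= 0, trans_range_um >= 0,
            fluor_fine_factor >= 1)
  if (is.null(regions)) {
    center <- c((shape[1] + 1) / 2, (shape[2] + 1) / 2, (shape[3] + 1) / 2)
    # the hypoxic core sits off-centre, as perfused rims and hypoxic cores
    # do in real xenografts; a concentric phantom would also make rotation
    # recovery ill-posed
    core_center <- center + c(0.08 * shape[1], -0.06 * shape[2], 0)
    regions <- .default_regions(
      center, core_center,
      # the tumour extends beyond the sampled z window (sections cut a
      # 1.8 mm window through a larger mass), so every section carries
      # enough tissue to register; the in-plane extent stays inside the
      # image
      semi_tumour = c(0.40 * shape[1], 0.30 * shape[2], 0.80 * shape[3]),
      semi_core = c(0.22 * shape[1], 0.18 * shape[2], 0.32 * shape[3]),
      band_depth = c(0.3, 0.7))
  }
  if (!length(regions)) stop("phantom spec needs at least one region")
  for (rg in regions) {
    for (pol in names(rg$channels)) {
      ch <- rg$channels[[pol]]
      if (any(ch$intensity < 0)) stop("channel intensities must be >= 0")
    }
    .check_geometry(rg$geometry, shape)
  }
  structure(list(shape = shape, pitch_um = pitch_um, z_step_um = z_step_um,
                 regions = regions, background_channels = background_channels,
                 tic_cv = tic_cv, additive_sd = additive_sd,
                 mz_jitter_ppm = mz_jitter_ppm,
                 rot_range_deg = rot_range_deg,
                 trans_range_um = trans_range_um, mass_range = mass_range,
                 fluor_regions = fluor_regions, fluor_level = fluor_level,
                 fluor_background = fluor_background,
                 fluor_noise_sd = fluor_noise_sd,
                 fluor_fine_factor = as.integer(fluor_fine_factor),
                 profile = profile, profile_sigma = profile_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.check_geometry <- function(g, shape) {
  # in-plane (y, x) extents must stay inside the image; the z extent may
  # overrun the sampled stack (serial sections cut a window through a
  # larger specimen) but must at least intersect it
  inside <- function(center, semi) {
    if (any(center[1:2] - semi[1:2] < 0.5 - 1e-9) ||
        any(center[1:2] + semi[1:2] > shape[1:2] + 0.5 + 1e-9)) {
      stop("region geometry extends outside the image plane")
    }
    if (center[3] + semi[3] < 0.5 - 1e-9 ||
        center[3] - semi[3] > shape[3] + 0.5 + 1e-9) {
      stop("region geometry does not intersect the sampled z range")
    }
  }
  switch(g$type,
         ellipsoid = inside(g$center, g$semi),
         shell = inside(g$center, g$semi_outer),
         band_at_depth = inside(g$parent$center, g$parent$semi),
         stop("unknown geometry type '", g$type, "'"))
}

# ellipsoid membership over the full voxel grid -> logical array
.ellipsoid_voxels <- function(shape, center, semi) {
  y <- seq_len(shape[1]); x <- seq_len(shape[2]); z <- seq_len(shape[3])
  fy <- ((y - center[1]) / semi[1])^2
  fx <- ((x - center[2]) / semi[2])^2
  fz <- ((z - center[3]) / semi[3])^2
  outer(outer(fy, fx, `+`), fz, `+`) <= 1
}

# per-slice normalized-depth band inside a parent ellipsoid
.band_voxels <- function(shape, parent, depth_range) {
  out <- array(FALSE, shape)
  ell <- .ellipsoid_voxels(shape, parent$center, parent$semi)
  for (z in seq_len(shape[3])) {
    sl <- ell[, , z]
    if (!any(sl)) next
    d <- EBImage::distmap(matrix(as.numeric(sl), shape[1], shape[2]))
    dmax <- max(d)
    if (dmax <= 1) next
    depth <- (d - 1) / (dmax - 1)
    out[, , z] <- sl & depth >= depth_range[1] & depth <= depth_range[2]
  }
  out
}

.region_voxels <- function(g, shape) {
  switch(g$type,
         ellipsoid = .ellipsoid_voxels(shape, g$center, g$semi),
         shell = .ellipsoid_voxels(shape, g$center, g$semi_outer) &
           !.ellipsoid_voxels(shape, g$center, g$semi_inner),
         band_at_depth = .band_voxels(shape, g$parent, g$depth_range))
}

.channel_key <- function(polarity, mz) sprintf("%s_%.4f", polarity, mz)

#' Build the phantom ground truth
#'
#' Deterministic in the spec's seed. Returns the voxel label volume, the
#' per-channel concentration volumes, the fluorescence volume and the
#' planted per-section rigid transforms (section 0 is the identity).
#' Regions are painted in list order, so later regions override earlier
#' ones where they overlap (the band is carved out of the hypoxic core).
#'
#' @param spec A `phantom_spec`.
#' @return An object of class `"phantom_truth"`: `label_volume` (integer
#'   array ny x nx x nz; 0 = background), `region_labels` (label of each
#'   integer code), `conc` (named list of concentration arrays, one per
#'   channel key `<polarity>_<mz>`), `channels` (registry data.frame),
#'   `fluor_volume`, `transforms` (list of `rigid_transform`), `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  labels <- array(0L, shape)
  region_labels <- vapply(spec$regions, `[[`, character(1), "label")
  masks <- list()
  for (i in seq_along(spec$regions)) {
    m <- .region_voxels(spec$regions[[i]]$geometry, shape)
    masks[[i]] <- m
    labels[m] <- i
  }
  for (i in seq_along(spec$regions)) {
    if (!any(labels == i)) {
      stop("region '", region_labels[i], "' covers no voxel")
    }
  }
  conc <- list()
  registry <- list()
  add_channel <- function(pol, mz, intensity, region, member) {
    key <- .channel_key(pol, mz)
    if (is.null(conc[[key]])) conc[[key]] <<- array(0, shape)
    conc[[key]][member] <<- conc[[key]][member] + intensity
    registry[[length(registry) + 1L]] <<-
      data.frame(polarity = pol, mz = mz, intensity = intensity,
                 region = region, key = key)
  }
  for (i in seq_along(spec$regions)) {
    rg <- spec$regions[[i]]
    member <- labels == i
    for (pol in names(rg$channels)) {
      ch <- rg$channels[[pol]]
      for (j in seq_len(nrow(ch))) {
        add_channel(pol, ch$mz[j], ch$intensity[j], rg$label, member)
      }
    }
  }
  everywhere <- array(TRUE, shape)
  for (pol in names(spec$background_channels)) {
    ch <- spec$background_channels[[pol]]
    for (j in seq_len(nrow(ch))) {
      add_channel(pol, ch$mz[j], ch$intensity[j], "background", everywhere)
    }
  }
  fluor <- array(0, shape)
  fl_codes <- which(region_labels %in% spec$fluor_regions)
  for (i in fl_codes) fluor[labels == i] <- spec$fluor_level
  transforms <- .with_seed(spec$seed, {
    tfs <- list(rigid_transform(0, 0, 0))
    for (i in seq_len(shape[3] - 1)) {
      tfs[[i + 1L]] <- rigid_transform(
        stats::runif(1, -spec$rot_range_deg, spec$rot_range_deg),
        stats::runif(1, -spec$trans_range_um, spec$trans_range_um),
        stats::runif(1, -spec$trans_range_um, spec$trans_range_um))
    }
    tfs
  })
  structure(list(label_volume = labels, region_labels = region_labels,
                 conc = conc, channels = do.call(rbind, registry),
                 fluor_volume = fluor, transforms = transforms, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d x %d voxels; regions: %s\n",
              dim(x$label_volume)[1], dim(x$label_volume)[2],
              dim(x$label_volume)[3],
              paste(x$region_labels, collapse = ", ")))
  invisible(x)
}

# render one pixel's centroided spectrum from channel values
.render_stick_spectrum <- function(mzs, values, polarity, spec) {
  keep <- values > 0
  mzv <- mzs[keep]; iv <- values[keep]
  if (length(mzv)) {
    mzv <- mzv * (1 + stats::rnorm(length(mzv)) * spec$mz_jitter_ppm * 1e-6)
    o <- order(mzv)
    mzv <- mzv[o]; iv <- iv[o]
    inr <- mzv >= spec$mass_range[1] & mzv <= spec$mass_range[2]
    mzv <- mzv[inr]; iv <- iv[inr]
  }
  mass_spectrum(mzv, iv, polarity, centroided = TRUE)
}

.render_profile_spectrum <- function(mzs, values, polarity, spec) {
  keep <- values > 0
  mzv <- mzs[keep]; iv <- values[keep]
  sg <- spec$profile_sigma
  grid <- sort(unique(unlist(lapply(mzv, function(m) {
    seq(m - 5 * sg, m + 5 * sg, by = sg / 4)
  }))))
  if (!length(grid)) grid <- seq(spec$mass_range[1], spec$mass_range[1] + 1, 0.1)
  y <- numeric(length(grid))
  for (j in seq_along(mzv)) {
    y <- y + iv[j] * exp(-(grid - mzv[j])^2 / (2 * sg^2))
  }
  inr <- grid >= spec$mass_range[1] & grid <= spec$mass_range[2]
  mass_spectrum(grid[inr], y[inr], polarity, centroided = FALSE)
}

#' Render the serial MSI sections of one polarity
#'
#' Applies each section's planted rigid transform to the tissue
#' concentration slices (solvent background stays fixed: the sprayer
#' covers the slide uniformly), multiplies by the per-pixel log-normal TIC
#' factor, adds the half-normal intensity floor, jitters m/z, clips at
#' zero and restricts to the acquisition mass range. Deterministic in the
#' spec's seed (each polarity draws from its own seeded stream).
#'
#' @param truth A `phantom_truth`.
#' @param polarity `"positive"` or `"negative"`.
#' @return List of `section_dataset`, one per z slice.
#' @export
render_sections <- function(truth, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  spec <- truth$spec
  shape <- spec$shape
  reg <- truth$channels[truth$channels$polarity == polarity, , drop = FALSE]
  reg <- reg[!duplicated(reg$key), , drop = FALSE]
  is_bg <- reg$region == "background"
  seed_off <- if (polarity == "positive") 101L else 202L
  .with_seed(spec$seed + seed_off, {
    lapply(seq_len(shape[3]), function(z) {
      tf <- truth$transforms[[z]]
      slices <- lapply(seq_len(nrow(reg)), function(j) {
        sl <- truth$conc[[reg$key[j]]][, , z]
        if (is_bg[j]) return(sl)
        if (tf$angle_deg == 0 && tf$tx_um == 0 && tf$ty_um == 0) sl
        else apply_transform(sl, tf, spec$pitch_um)
      })
      # per-pixel TIC factor (mean 1, CV = tic_cv)
      slog <- sqrt(log(1 + spec$tic_cv^2))
      ticf <- matrix(stats::rlnorm(shape[1] * shape[2],
                                   meanlog = -slog^2 / 2, sdlog = slog),
                     shape[1], shape[2])
      spectra <- vector("list", shape[1] * shape[2])
      for (r in seq_len(shape[1])) {
        for (c in seq_len(shape[2])) {
          vals <- vapply(slices, function(sl) sl[r, c], numeric(1)) *
            ticf[r, c]
          if (spec$additive_sd > 0) {
            vals <- vals + abs(stats::rnorm(length(vals), 0, spec$additive_sd))
          }
          vals <- pmax(vals, 0)
          spectra[[(r - 1) * shape[2] + c]] <-
            if (spec$profile) {
              .render_profile_spectrum(reg$mz, vals, polarity, spec)
            } else {
              .render_stick_spectrum(reg$mz, vals, polarity, spec)
            }
        }
      }
      section_dataset(spectra, shape[1], shape[2], spec$pitch_um,
                      section_index = z - 1L,
                      z_um = (z - 1) * spec$z_step_um, polarity = polarity)
    })
  })
}

#' Render the CA-9-like fluorescence image of one section
#'
#' Sampled on a grid `fluor_fine_factor` times finer than the MSI raster
#' (emulating a high-resolution scan of the adjacent thin section), with
#' Gaussian noise on top of the expressing-region gray level and the
#' background. Not misaligned: the adjacent section is the co-registered
#' ground truth the MSI data are compared against.
#'
#' @param truth A `phantom_truth`.
#' @param z 0-based section index.
#' @return Numeric matrix `(ny * f) x (nx * f)`, nonnegative gray levels.
#' @export
render_fluorescence <- function(truth, z) {
  spec <- truth$spec
  nz <- spec$shape[3]
  if (z < 0 || z >= nz) stop("section index z out of range [0, ", nz - 1, "]")
  f <- spec$fluor_fine_factor
  coarse <- truth$fluor_volume[, , z + 1L]
  fine <- coarse[rep(seq_len(nrow(coarse)), each = f),
                 rep(seq_len(ncol(coarse)), each = f)]
  img <- fine + spec$fluor_background
  if (spec$fluor_noise_sd > 0) {
    img <- .with_seed(spec$seed + 5000L + z, {
      img + matrix(stats::rnorm(length(img), 0, spec$fluor_noise_sd),
                   nrow(img), ncol(img))
    })
  }
  pmax(img, 0)
}

#' Write the phantom ground truth sidecar
#'
#' Persists the planted transforms (CSV), the channel registry (CSV) and
#' the label volume (NRRD) so a rendered phantom can be scored without the
#' in-memory truth object.
#'
#' @param truth A `phantom_truth`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transforms(truth$transforms, file.path(dir, "transforms.csv"))
  utils::write.csv(truth$channels, file.path(dir, "channels.csv"),
                   row.names = FALSE)
  vol <- aperm(truth$label_volume, c(3, 1, 2))
  export_volume(vol, file.path(dir, "labels.nrrd"), "nrrd",
                pitch_um = c(truth$spec$z_step_um, truth$spec$pitch_um,
                             truth$spec$pitch_um))
  invisible(dir)
}
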