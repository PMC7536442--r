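# Slide-level I/O helpers: tissue-object detection on a TIC snapshot
# (emulating the autoloader's object definition step) and volume export
# to NRRD or multi-page TIFF.

#' Detect tissue objects on a TIC image
#'
#' Emulates the object-definition step of an automated slide loader: the
#' TIC image is rescaled to a fixed range, log-compressed, thresholded by
#' the isodata method, and split into connected components. Components
#' smaller than `min_area` pixels (solvent spots) are dropped. The result
#' is invariant to multiplying the TIC image by any positive constant.
#'
#' @param tic_image Nonnegative matrix.
#' @param min_area Minimum component area in pixels (default 10).
#' @return List of tissue objects sorted by area (largest first); each has
#'   `bbox` (`row0, col0, row1, col1`, half-open, 0-based), `mask`
#'   (logical matrix on the full grid) and `area`. Empty list when no
#'   object is found.
#' @export
detect_tissue <- function(tic_image, min_area = 10L) {
  stopifnot(is.matrix(tic_image), all(tic_image >= 0))
  mx <- max(tic_image)
  if (mx <= 0 || length(unique(as.vector(tic_image))) < 2) return(list())
  z <- log1p(tic_image / mx * 255)   # fixed-range log compression
  tm <- threshold_mask(z)
  comp <- EBImage::bwlabel(matrix(as.numeric(tm$mask), nrow(z), ncol(z)))
  n <- max(comp)
  if (n == 0) return(list())
  objs <- list()
  for (lab in seq_len(n)) {
    sel <- comp == lab
    area <- sum(sel)
    if (area < min_area) next
    idx <- which(sel, arr.ind = TRUE)
    objs[[length(objs) + 1L]] <- list(
      bbox = c(row0 = min(idx[, 1]) - 1L, col0 = min(idx[, 2]) - 1L,
               row1 = max(idx[, 1]), col1 = max(idx[, 2])),
      mask = sel, area = area)
  }
  objs[order(vapply(objs, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' Export a volume to NRRD or multi-page TIFF
#'
#' NRRD files carry the voxel pitch in their `spacings` header field and
#' round-trip losslessly (float32 for continuous data, int32 for label
#' volumes). The TIFF writer stores one page per section and records the
#' pitch in a JSON sidecar, since baseline TIFF has no standard 3-axis
#' spacing tag.
#'
#' @param volume An `msi_volume`, or a 3D array (nz x rows x cols) with
#'   `pitch_um` supplied.
#' @param path Output file path.
#' @param format `"nrrd"` or `"tiff"`.
#' @param pitch_um Voxel pitch `(dz, dy, dx)` when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
export_volume <- function(volume, path, format = c("nrrd", "tiff"),
                          pitch_um = NULL) {
  format <- match.arg(format)
  if (inherits(volume, "msi_volume")) {
    arr <- volume$data; pitch <- volume$pitch_um
  } else {
    stopifnot(is.array(volume), length(dim(volume)) == 3)
    arr <- volume
    pitch <- if (is.null(pitch_um)) c(1, 1, 1) else pitch_um
  }
  is_label <- is.integer(arr) || all(arr == round(arr))
  if (format == "nrrd") {
    .write_nrrd(arr, path, pitch, is_label)
  } else {
    d <- dim(arr)
    pages <- lapply(seq_len(d[1]), function(i) {
      m <- arr[i, , ]
      mx <- max(abs(m), 1)
      m / mx   # tiff stores [0,1] floats; scale recorded in sidecar
    })
    scales <- vapply(seq_len(d[1]), function(i) max(abs(arr[i, , ]), 1),
                     numeric(1))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(pitch_um = pitch, page_scale = scales,
                              label = is_label),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

.write_nrrd <- function(arr, path, pitch, is_label) {
  d <- dim(arr)
  type <- if (is_label) "int32" else "float"
  # NRRD axis order is fastest-first; we write x fastest, then y, then z
  hdr <- c("NRRD0004",
           "# volume exported by desi3d",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", d[3], " ", d[2], " ", d[1]),
           paste0("spacings: ", pitch[3], " ", pitch[2], " ", pitch[1]),
           "encoding: raw",
           "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  # fastest axis x (cols), then y (rows), then z
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  if (is_label) {
    writeBin(as.integer(vals), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read an NRRD volume written by [export_volume()]
#'
#' @param path NRRD file.
#' @return List: `data` (array nz x rows x cols), `pitch_um` (dz, dy, dx).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line <- function() {
    bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (!length(b) || b == as.raw(10L)) break
      bytes <- c(bytes, b)
    }
    rawToChar(bytes)
  }
  hdr <- character(0)
  repeat {
    line <- read_line()
    if (line == "") break
    hdr <- c(hdr, line)
  }
  get_field <- function(name) {
    ln <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("^", name, ": "), "", ln[1]), " ")[[1]]
  }
  sizes <- as.integer(get_field("sizes"))
  sp <- as.numeric(get_field("spacings"))
  type <- get_field("type")
  n <- prod(sizes)
  vals <- if (type == "int32") {
    readBin(con, "integer", n, size = 4L, endian = "little")
  } else {
    readBin(con, "numeric", n, size = 4L, endian = "little")
  }
  arr <- aperm(array(vals, dim = sizes), c(3, 2, 1))
  list(data = arr, pitch_um = c(dz = sp[3], dy = sp[2], dx = sp[1]))
}
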