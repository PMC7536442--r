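# imzML 1.1 reading and writing. The format is an mzML-derived XML file
# describing per-pixel spectra whose binary arrays live in a companion
# .ibd file (16-byte UUID header, then raw little-endian arrays addressed
# by offset). Continuous mode stores the shared m/z axis once; processed
# mode stores a per-pixel m/z array. m/z is written as 64-bit float,
# intensity as 32-bit float. Pixel coordinates are 1-based in the file and
# 0-based in this package's API.

.random_uuid_bytes <- function() {
  b <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  # RFC 4122 version/variant bits
  b[7] <- as.raw(bitwOr(bitwAnd(as.integer(b[7]), 0x0F), 0x40))
  b[9] <- as.raw(bitwOr(bitwAnd(as.integer(b[9]), 0x3F), 0x80))
  b
}

.uuid_string <- function(bytes) {
  h <- format(bytes)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

.cv_param <- function(parent, cv, accession, name, value = NULL, unit = NULL) {
  node <- xml2::xml_add_child(parent, "cvParam", cvRef = cv,
                              accession = accession, name = name)
  xml2::xml_set_attr(node, "value", if (is.null(value)) "" else as.character(value))
  if (!is.null(unit)) {
    xml2::xml_set_attr(node, "unitCvRef", "UO")
    xml2::xml_set_attr(node, "unitAccession", unit$accession)
    xml2::xml_set_attr(node, "unitName", unit$name)
  }
  node
}

#' Write a section dataset to imzML + ibd
#'
#' Continuous mode is chosen automatically when every non-missing pixel
#' shares one m/z axis, processed mode otherwise. Missing pixels are
#' skipped in the file (readers flag absent coordinates); empty spectra of
#' non-missing pixels are kept as zero-length entries. The ibd MD5 is
#' recorded in the imzML so readers can verify integrity.
#'
#' @param section A `section_dataset`.
#' @param path Output path; `.imzML` is appended if absent, and the ibd
#'   written alongside.
#' @return Invisibly, a list with the `imzml` and `ibd` paths and the
#'   `mode` written.
#' @export
write_imzml <- function(section, path) {
  stopifnot(inherits(section, "section_dataset"))
  if (!grepl("\\.imzML$", path, ignore.case = TRUE)) {
    path <- paste0(path, ".imzML")
  }
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

  keep <- list()   # pixel records: row, col, spectrum
  for (r in seq_len(section$rows) - 1L) {
    for (c in seq_len(section$cols) - 1L) {
      if (section$missing[r + 1L, c + 1L]) next
      keep[[length(keep) + 1L]] <-
        list(row = r, col = c,
             s = section$spectra[[r * section$cols + c + 1L]])
    }
  }
  if (!length(keep)) stop("nothing to write: every pixel is missing")
  axes <- lapply(keep, function(p) p$s$mz)
  nonempty <- which(vapply(axes, length, integer(1)) > 0)
  continuous <- length(nonempty) > 0 &&
    all(vapply(nonempty, function(i) identical(axes[[i]], axes[[nonempty[1]]]),
               logical(1)))
  if (continuous && length(nonempty) < length(keep)) continuous <- FALSE
  mode <- if (continuous) "continuous" else "processed"

  uuid <- .random_uuid_bytes()
  con <- file(ibd_path, "wb")
  writeBin(uuid, con)
  offset <- 16
  recs <- vector("list", length(keep))
  if (continuous) {
    mz_axis <- axes[[1]]
    writeBin(as.numeric(mz_axis), con, size = 8L, endian = "little")
    mz_offset <- 16; mz_len <- length(mz_axis)
    offset <- offset + 8 * mz_len
    for (i in seq_along(keep)) {
      ints <- keep[[i]]$s$intensity
      writeBin(as.numeric(ints), con, size = 4L, endian = "little")
      recs[[i]] <- list(mz_offset = mz_offset, mz_len = mz_len,
                        int_offset = offset, int_len = length(ints))
      offset <- offset + 4 * length(ints)
    }
  } else {
    for (i in seq_along(keep)) {
      s <- keep[[i]]$s
      writeBin(as.numeric(s$mz), con, size = 8L, endian = "little")
      mzo <- offset; offset <- offset + 8 * length(s$mz)
      writeBin(as.numeric(s$intensity), con, size = 4L, endian = "little")
      recs[[i]] <- list(mz_offset = mzo, mz_len = length(s$mz),
                        int_offset = offset, int_len = length(s$intensity))
      offset <- offset + 4 * length(s$intensity)
    }
  }
  close(con)
  md5 <- unname(tools::md5sum(ibd_path))

  doc <- xml2::xml_new_root("mzML",
    xmlns = "http://psi.hupo.org/ms/mzml", version = "1.1.0")
  fdesc <- xml2::xml_add_child(doc, "fileDescription")
  fcontent <- xml2::xml_add_child(fdesc, "fileContent")
  .cv_param(fcontent, "IMS",
            if (continuous) "IMS:1000030" else "IMS:1000031", mode)
  .cv_param(fcontent, "IMS", "IMS:1000080",
            "universally unique identifier",
            paste0("{", .uuid_string(uuid), "}"))
  .cv_param(fcontent, "IMS", "IMS:1000091", "ibd MD5", toupper(md5))
  centroided <- all(vapply(keep, function(p) p$s$centroided, logical(1)))
  .cv_param(fcontent, "MS",
            if (centroided) "MS:1000127" else "MS:1000128",
            if (centroided) "centroid spectrum" else "profile spectrum")

  rpgl <- xml2::xml_add_child(doc, "referenceableParamGroupList", count = "2")
  g1 <- xml2::xml_add_child(rpgl, "referenceableParamGroup", id = "mzArray")
  .cv_param(g1, "MS", "MS:1000514", "m/z array",
            unit = list(accession = "MS:1000040", name = "m/z"))
  .cv_param(g1, "MS", "MS:1000523", "64-bit float")
  .cv_param(g1, "IMS", "IMS:1000101", "external data", "true")
  g2 <- xml2::xml_add_child(rpgl, "referenceableParamGroup",
                            id = "intensityArray")
  .cv_param(g2, "MS", "MS:1000515", "intensity array")
  .cv_param(g2, "MS", "MS:1000521", "32-bit float")
  .cv_param(g2, "IMS", "IMS:1000101", "external data", "true")

  scset <- xml2::xml_add_child(doc, "scanSettingsList", count = "1")
  sc <- xml2::xml_add_child(scset, "scanSettings", id = "scan1")
  .cv_param(sc, "IMS", "IMS:1000042", "max count of pixels x", section$cols)
  .cv_param(sc, "IMS", "IMS:1000043", "max count of pixels y", section$rows)
  .cv_param(sc, "IMS", "IMS:1000046", "pixel size (x)", section$pitch_um,
            unit = list(accession = "UO:0000017", name = "micrometer"))
  .cv_param(sc, "IMS", "IMS:1000047", "pixel size y", section$pitch_um,
            unit = list(accession = "UO:0000017", name = "micrometer"))

  run <- xml2::xml_add_child(doc, "run", id = "run1")
  slist <- xml2::xml_add_child(run, "spectrumList",
                               count = as.character(length(keep)))
  pol_acc <- if (section$polarity == "positive") "MS:1000130" else "MS:1000129"
  pol_name <- paste(section$polarity, "scan")
  for (i in seq_along(keep)) {
    p <- keep[[i]]; rec <- recs[[i]]
    sp <- xml2::xml_add_child(slist, "spectrum",
                              id = sprintf("spectrum=%d", i),
                              index = as.character(i - 1L),
                              defaultArrayLength = as.character(rec$int_len))
    .cv_param(sp, "MS", pol_acc, pol_name)
    sl <- xml2::xml_add_child(sp, "scanList", count = "1")
    scan <- xml2::xml_add_child(sl, "scan")
    .cv_param(scan, "IMS", "IMS:1000050", "position x", p$col + 1L)
    .cv_param(scan, "IMS", "IMS:1000051", "position y", p$row + 1L)
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    for (which in c("mz", "int")) {
      bda <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
      xml2::xml_add_child(bda, "referenceableParamGroupRef",
                          ref = if (which == "mz") "mzArray" else "intensityArray")
      len <- if (which == "mz") rec$mz_len else rec$int_len
      off <- if (which == "mz") rec$mz_offset else rec$int_offset
      nbytes <- if (which == "mz") 8L else 4L
      .cv_param(bda, "IMS", "IMS:1000103", "external array length", len)
      .cv_param(bda, "IMS", "IMS:1000102", "external offset", off)
      .cv_param(bda, "IMS", "IMS:1000104", "external encoded length",
                len * nbytes)
      xml2::xml_add_child(bda, "binary")
    }
  }
  xml2::write_xml(doc, path)
  invisible(list(imzml = path, ibd = ibd_path, mode = mode))
}

.xml_cv_value <- function(node, accession) {
  hit <- xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession))
  if (inherits(hit, "xml_missing")) return(NULL)
  xml2::xml_attr(hit, "value")
}

#' Read an imzML + ibd pair into a section dataset
#'
#' Both continuous and processed mode are supported. The ibd UUID must
#' match the imzML's; when an ibd MD5 is recorded it is verified and a
#' mismatch raises an integrity error. Grid positions absent from the file
#' are flagged missing (zero spectra), and coordinates are converted from
#' the file's 1-based convention to the package's 0-based one.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit alongside).
#' @param section_index,z_um Metadata for the returned section.
#' @param pitch_um Override for files missing the pixel-size CV param.
#' @return A `section_dataset`.
#' @export
read_imzml <- function(path, section_index = 0L, z_um = 0, pitch_um = NULL) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(path)) stop("imzML file not found: ", path)
  if (!file.exists(ibd_path)) stop("missing ibd file: ", ibd_path)
  doc <- xml2::read_xml(path)

  md5_decl <- .xml_cv_value(doc, "IMS:1000091")
  if (!is.null(md5_decl) && nzchar(md5_decl)) {
    md5 <- toupper(unname(tools::md5sum(ibd_path)))
    if (!identical(md5, toupper(md5_decl))) {
      stop("ibd integrity error: MD5 mismatch (file ", md5,
           ", declared ", toupper(md5_decl), ")")
    }
  }
  uuid_decl <- .xml_cv_value(doc, "IMS:1000080")
  con <- file(ibd_path, "rb")
  on.exit(close(con))
  uuid_file <- readBin(con, "raw", 16L)
  if (!is.null(uuid_decl) && nzchar(uuid_decl)) {
    u <- gsub("[{}-]", "", uuid_decl)
    if (!identical(tolower(u), paste(format(uuid_file), collapse = ""))) {
      stop("ibd integrity error: UUID mismatch between imzML and ibd")
    }
  }

  cols <- as.integer(.xml_cv_value(doc, "IMS:1000042"))
  rows <- as.integer(.xml_cv_value(doc, "IMS:1000043"))
  px <- .xml_cv_value(doc, "IMS:1000046")
  if (!is.null(px) && nzchar(px)) {
    file_pitch <- as.numeric(px)
    if (is.null(pitch_um)) pitch_um <- file_pitch
  } else if (is.null(pitch_um)) {
    stop("imzML lacks a pixel size; pass pitch_um explicitly")
  }
  centroided <- !is.null(.xml_cv_value(doc, "MS:1000127"))

  spectra_nodes <- xml2::xml_find_all(doc, ".//d1:spectrum")
  polarity <- if (length(spectra_nodes) &&
                  !is.null(.xml_cv_value(spectra_nodes[[1]], "MS:1000129"))) {
    "negative"
  } else "positive"

  empty <- mass_spectrum(numeric(0), numeric(0), polarity, centroided)
  spectra <- rep(list(empty), rows * cols)
  missing <- matrix(TRUE, rows, cols)
  for (sp in spectra_nodes) {
    x1 <- as.integer(.xml_cv_value(sp, "IMS:1000050"))
    y1 <- as.integer(.xml_cv_value(sp, "IMS:1000051"))
    r <- y1 - 1L; c <- x1 - 1L
    bdas <- xml2::xml_find_all(sp, ".//d1:binaryDataArray")
    mz <- numeric(0); ints <- numeric(0)
    for (bda in bdas) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, ".//d1:referenceableParamGroupRef"), "ref")
      len <- as.integer(.xml_cv_value(bda, "IMS:1000103"))
      off <- as.numeric(.xml_cv_value(bda, "IMS:1000102"))
      if (len > 0) {
        seek(con, off)
        if (identical(ref, "mzArray")) {
          mz <- readBin(con, "numeric", len, size = 8L, endian = "little")
        } else {
          ints <- readBin(con, "numeric", len, size = 4L, endian = "little")
        }
      }
    }
    spectra[[r * cols + c + 1L]] <- mass_spectrum(mz, pmax(ints, 0),
                                                  polarity, centroided)
    missing[r + 1L, c + 1L] <- FALSE
  }
  section_dataset(spectra, rows, cols, pitch_um, section_index, z_um,
                  polarity, missing)
}
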