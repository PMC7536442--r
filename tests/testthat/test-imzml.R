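make_grid_section <- function(continuous = TRUE) {
  axis <- c(100.5, 400.3421, 885.5499)
  spectra <- lapply(1:6, function(i) {
    if (continuous) {
      mass_spectrum(axis, c(i, 2 * i, 3 * i), "positive", centroided = TRUE)
    } else {
      # per-pixel axes of different lengths, including an empty spectrum
      n <- c(3, 5, 0, 2, 1, 4)[i]
      if (n == 0) {
        mass_spectrum(numeric(0), numeric(0), "positive", centroided = TRUE)
      } else {
        mass_spectrum(100 + seq_len(n) * i, seq_len(n), "positive",
                      centroided = TRUE)
      }
    }
  })
  section_dataset(spectra, rows = 2, cols = 3, pitch_um = 120,
                  section_index = 4L, z_um = 480)
}

test_that("continuous-mode imzML round-trips", {
  sec <- make_grid_section(continuous = TRUE)
  path <- file.path(tempdir(), "cont.imzML")
  write_imzml(sec, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("imzML$", "ibd", path)))
  xml <- paste(readLines(path, warn = FALSE), collapse = "\n")
  expect_match(xml, "IMS:1000030")   # continuous accession
  back <- read_imzml(path)
  expect_equal(back$rows, 2)
  expect_equal(back$cols, 3)
  expect_equal(back$polarity, "positive")
  expect_equal(back$pitch_um, 120)
  for (r in 0:1) for (c in 0:2) {
    a <- get_pixel(sec, r, c); b <- get_pixel(back, r, c)
    expect_equal(b$mz, a$mz, tolerance = 1e-9)
    expect_equal(b$intensity, a$intensity, tolerance = 1e-6)
  }
})

test_that("processed-mode imzML keeps per-pixel axes and empty spectra", {
  sec <- make_grid_section(continuous = FALSE)
  path <- file.path(tempdir(), "proc.imzML")
  write_imzml(sec, path)
  xml <- paste(readLines(path, warn = FALSE), collapse = "\n")
  expect_match(xml, "IMS:1000031")   # processed accession
  back <- read_imzml(path)
  lens <- vapply(0:5, function(i) {
    length(get_pixel(back, i %/% 3, i %% 3)$mz)
  }, integer(1))
  expect_equal(lens, c(3L, 5L, 0L, 2L, 1L, 4L))
  expect_equal(get_pixel(back, 0, 1)$mz, get_pixel(sec, 0, 1)$mz,
               tolerance = 1e-9)
})

test_that("ibd corruption is detected via checksum/UUID", {
  sec <- make_grid_section(TRUE)
  path <- file.path(tempdir(), "tamper.imzML")
  write_imzml(sec, path)
  ibd <- sub("imzML$", "ibd", path)
  bytes <- readBin(ibd, "raw", file.info(ibd)$size)
  bytes[length(bytes) - 3L] <- xor(bytes[length(bytes) - 3L], as.raw(0xff))
  writeBin(bytes, ibd)
  expect_error(read_imzml(path), "MD5|checksum|integrity")
  # UUID mismatch: pair the imzML with a different run's ibd whose MD5 the
  # XML is patched to accept, so only the UUID check can fire
  sec2 <- make_grid_section(TRUE)
  path2 <- file.path(tempdir(), "other.imzML")
  write_imzml(sec2, path2)
  ibd2 <- sub("imzML$", "ibd", path2)
  file.copy(ibd2, ibd, overwrite = TRUE)
  xml <- readLines(path, warn = FALSE)
  old_md5 <- toupper(unname(tools::md5sum(sub("imzML$", "ibd", path2))))
  # find the declared checksum in this file and replace it
  cur <- regmatches(xml, regexpr("[0-9a-fA-F]{32}", xml))
  declared <- unique(cur[nchar(cur) == 32])
  for (d in declared) xml <- gsub(d, old_md5, xml, fixed = TRUE)
  writeLines(xml, path)
  expect_error(read_imzml(path), "UUID|uuid")
})

test_that("missing pixels are skipped on write and flagged on read", {
  sec <- make_grid_section(TRUE)
  sec$missing[2, 3] <- TRUE
  path <- file.path(tempdir(), "missing.imzML")
  write_imzml(sec, path)
  back <- read_imzml(path)
  expect_true(back$missing[2, 3])
  expect_false(any(back$missing[1, ]))
  expect_length(get_pixel(back, 1, 2)$mz, 0)
})
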