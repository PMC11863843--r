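test_that("minimal AFFN file parses onto the declared grid", {
  p <- withr::local_tempfile(fileext = ".jdx")
  write_affn_jcamp(p, 600:604, c(0, .25, .5, .75, 1))
  raw <- read_jcampdx(p)
  expect_s3_class(raw, "raw_spectrum")
  expect_equal(raw$wavenumbers, as.numeric(600:604))
  expect_equal(raw$intensities, c(0, .25, .5, .75, 1))
  expect_identical(raw$y_units, "absorbance")
})

test_that("YUNITS header is echoed into y_units", {
  p <- withr::local_tempfile(fileext = ".jdx")
  write_affn_jcamp(p, 600:604, rep(0.9, 5), yunits = "TRANSMITTANCE")
  expect_identical(read_jcampdx(p)$y_units, "transmittance")
  p2 <- withr::local_tempfile(fileext = ".jdx")
  write_affn_jcamp(p2, 600:604, rep(0.9, 5), yunits = "ARBITRARY")
  expect_identical(read_jcampdx(p2)$y_units, "unknown")
})

test_that("write/read round trip is value-stable within 1e-6", {
  p <- withr::local_tempfile(fileext = ".jdx")
  set.seed(4)
  x <- seq(600, 4000, by = 8)
  y <- runif(length(x))
  write_jcampdx(x, y, p)
  raw <- read_jcampdx(p)
  expect_equal(raw$wavenumbers, x, tolerance = 1e-9)
  expect_lt(max(abs(raw$intensities - y)), 1e-6)
  # second round trip through own writer
  p2 <- withr::local_tempfile(fileext = ".jdx")
  write_jcampdx(raw$wavenumbers, raw$intensities, p2)
  raw2 <- read_jcampdx(p2)
  expect_lt(max(abs(raw2$intensities - y)), 1e-6)
})

test_that("descending-axis files are reordered ascending", {
  p <- withr::local_tempfile(fileext = ".jdx")
  write_affn_jcamp(p, seq(4000, 600, by = -100),
                   seq_len(35) / 35)
  raw <- read_jcampdx(p)
  expect_true(all(diff(raw$wavenumbers) > 0))
  # highest intensity was at 600 in file order
  expect_equal(raw$intensities[1], 35 / 35)
})

test_that("micrometer abscissa converts to wavenumbers", {
  p <- withr::local_tempfile(fileext = ".jdx")
  # equally spaced in micrometers: 2.5 um -> 4000 1/cm, 10 um -> 1000 1/cm
  write_affn_jcamp(p, c(2.5, 5, 7.5, 10), c(.1, .2, .3, .4),
                   xunits = "MICROMETERS")
  raw <- read_jcampdx(p)
  expect_equal(sort(raw$wavenumbers), c(1000, 4000 / 3, 2000, 4000),
               tolerance = 1e-9)
  # intensities stay attached to their points through the reorder
  expect_equal(raw$intensities[raw$wavenumbers == 4000], .1)
})

test_that("XYPOINTS pair payloads parse, in any pair separator style", {
  p <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=pairs", "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
               "##XYPOINTS=(XY..XY)",
               "700, 0.1; 650, 0.05", "800, 0.4", "750 0.2",
               "##END="), p)
  raw <- read_jcampdx(p)
  expect_equal(raw$wavenumbers, c(650, 700, 750, 800))
  expect_equal(raw$intensities, c(0.05, 0.1, 0.2, 0.4))
})

test_that("compressed dialects and malformed payloads are rejected", {
  p <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=sqz", "##FIRSTX=600", "##LASTX=604", "##NPOINTS=5",
               "##XYDATA=(X++(Y..Y))", "600 @J55K", "##END="), p)
  expect_error(read_jcampdx(p), "unsupported JCAMP dialect")

  p2 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=empty", "##END="), p2)
  expect_error(read_jcampdx(p2), "no XYDATA")

  expect_error(read_jcampdx(withr::local_tempfile()), "no such file")
})

test_that("transmittance converts to absorbance with percent heuristic", {
  mk <- function(y, units = "transmittance") {
    structure(list(wavenumbers = seq_along(y) + 599, intensities = y,
                   y_units = units, meta = list()),
              class = "raw_spectrum")
  }
  expect_equal(to_absorbance(mk(c(1, 1, 1)))$intensities, c(0, 0, 0))
  expect_equal(to_absorbance(mk(c(0.1, 1, 1)))$intensities[1], 1)
  # percent transmittance detected by max > 1.5
  expect_equal(to_absorbance(mk(c(10, 100, 100)))$intensities[1], 1)
  # absorbance passes through unchanged, and conversion is idempotent
  a <- mk(c(0.2, 0.4, 0.9), units = "absorbance")
  expect_identical(to_absorbance(a)$intensities, a$intensities)
  expect_identical(to_absorbance(to_absorbance(a)), to_absorbance(a))
})

test_that("unknown units resolve heuristically or fail loudly", {
  mk <- function(y) structure(list(wavenumbers = seq_along(y) + 599,
                                   intensities = y, y_units = "unknown",
                                   meta = list()), class = "raw_spectrum")
  # looks like percent transmittance
  expect_identical(to_absorbance(mk(c(95, 80, 99)))$y_units, "absorbance")
  # hovers near 1: fractional transmittance
  expect_equal(to_absorbance(mk(c(0.98, 0.95, 0.99)))$intensities,
               -log10(c(0.98, 0.95, 0.99)))
  # low values: already absorbance
  expect_identical(to_absorbance(mk(c(0.02, 0.2, 0.05)))$intensities,
                   c(0.02, 0.2, 0.05))
  expect_error(to_absorbance(mk(c(0.5, 0.45, 0.55))),
               "cannot resolve intensity units")
})
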