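make_raw <- function(x, y) {
  structure(list(wavenumbers = x, intensities = y, y_units = "absorbance",
                 meta = list()), class = "raw_spectrum")
}

test_that("linear interpolation hits knots, midpoints and a brute-force
          oracle", {
  raw <- make_raw(c(1000, 1002), c(0, 1))
  expect_equal(interpolate_to_grid(raw, 1001), 0.5)
  expect_equal(interpolate_to_grid(raw, c(1000, 1002)), c(0, 1))

  set.seed(42)
  x <- sort(runif(20, 600, 4000))
  y <- runif(20)
  raw <- make_raw(x, y)
  q <- runif(100, min(x), max(x))
  got <- interpolate_to_grid(raw, q)
  # brute-force two-point linear formula
  expected <- vapply(q, function(qi) {
    i <- max(which(x <= qi))
    if (x[i] == qi) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (qi - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
  expect_lt(max(abs(got - expected)), 1e-12)

  # outside the measured range -> 0
  expect_equal(interpolate_to_grid(raw, c(100, 5000)), c(0, 0))
  expect_error(interpolate_to_grid(raw, numeric(0)), "empty grid")
})

test_that("min-max normalization maps to [0,1] with degenerate case", {
  expect_equal(normalize_minmax(c(0, 2, 4)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(rep(3, 5)), rep(0, 5))
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(50)
    out <- normalize_minmax(v)
    expect_equal(range(out), c(0, 1))
  }
})

test_that("preprocess_record standardizes any coverage to the fixed grid", {
  p <- withr::local_tempfile(fileext = ".jdx")
  x <- seq(450, 3966, by = 8)
  set.seed(7)
  write_affn_jcamp(p, x, runif(length(x)))
  rec <- preprocess_record(p, "CCO", id = "s1",
                           timestamp = "2024-01-01T00:00:00")
  expect_s3_class(rec, "dataset_record")
  expect_length(rec$spectrum$intensities, 3401)
  expect_gte(min(rec$spectrum$intensities), 0)
  expect_lte(max(rec$spectrum$intensities), 1)
  expect_identical(rec$smiles, "CCO")
  expect_equal(sum(rec$labels), 3)  # alkane, methyl, alcohols

  # narrower coverage: grid cells outside the measured range are 0
  p2 <- withr::local_tempfile(fileext = ".jdx")
  x2 <- seq(650, 3800, by = 10)
  write_affn_jcamp(p2, x2, runif(length(x2)) + 0.1)
  rec2 <- preprocess_record(p2, "CCO", id = "s2")
  g <- rec2$spectrum$grid
  expect_true(all(rec2$spectrum$intensities[g < 650] == 0))
  expect_true(all(rec2$spectrum$intensities[g > 3800] == 0))
})

test_that("preprocess errors carry the record id", {
  p <- withr::local_tempfile(fileext = ".jdx")
  write_affn_jcamp(p, 600:610, runif(11))
  expect_error(preprocess_record(p, "C1CC", id = "rec_bad"), "rec_bad")
  expect_error(preprocess_record(withr::local_tempfile(), "CCO",
                                 id = "rec_missing"), "rec_missing")
})

test_that("dedup_latest keeps the newest spectrum per molecule", {
  mk <- function(id, smiles, ts) {
    structure(list(id = id, smiles = canonicalize_smiles(smiles),
                   spectrum = NULL, labels = NULL, timestamp = ts),
              class = "dataset_record")
  }
  r <- list(mk("a", "OCC", "2021-01-01"), mk("b", "CCO", "2022-01-01"),
            mk("c", "c1ccccc1", "2020-06-01"))
  out <- dedup_latest(r)
  expect_setequal(vapply(out, `[[`, "", "id"), c("b", "c"))

  # all distinct molecules: identity
  r2 <- list(mk("a", "CCO", "2021-01-01"), mk("b", "CCN", "2020-01-01"))
  expect_identical(dedup_latest(r2), r2)

  # timestamp tie: lexicographically larger id wins, deterministically
  r3 <- list(mk("a", "CCO", "2021-01-01"), mk("b", "OCC", "2021-01-01"))
  expect_identical(vapply(dedup_latest(r3), `[[`, "", "id"), "b")
  expect_identical(dedup_latest(rev(r3))[[1]]$id, "b")

  # idempotence
  expect_identical(dedup_latest(out), out)
})

test_that("slice_subset filters by any-of group membership", {
  mk <- function(id, on) {
    labels <- integer(17); names(labels) <- fg_names(); labels[on] <- 1L
    structure(list(id = id, smiles = id, spectrum = NULL, labels = labels,
                   timestamp = NA), class = "dataset_record")
  }
  r <- list(mk("nit", "nitriles"), mk("hal", "alkyl halides"),
            mk("none", "ketones"))
  out <- slice_subset(r, c("nitriles", "alkyl halides"))
  expect_setequal(vapply(out, `[[`, "", "id"), c("nit", "hal"))
  expect_length(slice_subset(r, "amides"), 0)
  expect_error(slice_subset(r, "no such group"), "unknown functional group")

  # union property on disjoint group sets
  u <- slice_subset(r, c("nitriles", "ketones"))
  a <- slice_subset(r, "nitriles")
  b <- slice_subset(r, "ketones")
  expect_setequal(vapply(u, `[[`, "", "id"),
                  c(vapply(a, `[[`, "", "id"), vapply(b, `[[`, "", "id")))
})

test_that("dataset TSV round trip preserves records", {
  g <- tiny_grid(200)
  cfg <- sim_config(n = 5, grid = g, seed = 3)
  recs <- generate_dataset(cfg)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(recs, p)
  back <- read_dataset_tsv(p)
  expect_length(back, 5)
  expect_equal(back[[2]]$spectrum$intensities,
               recs[[2]]$spectrum$intensities, tolerance = 1e-6)
  expect_identical(back[[3]]$labels, recs[[3]]$labels)
})
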