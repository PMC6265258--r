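test_that("climate tables round-trip bit-exactly and validate their contract", {
  s <- genRecentClimate(years = 1934:2013, seed = 5)
  path <- writeClimateCSV(s)
  r <- loadClimateTable(path)
  expect_identical(seriesYears(r), 1934:2013)
  expect_equal(tmeanMatrix(r), tmeanMatrix(s), tolerance = 0)
  expect_equal(precMatrix(r), precMatrix(s), tolerance = 0)

  one <- ClimateSeries(2000L, matrix(KHATANGA_TMEAN, 1), matrix(0, 1, 12))
  r1 <- loadClimateTable(writeClimateCSV(one))
  expect_length(seriesYears(r1), 1)
  expect_true(all(precMatrix(r1) == 0))

  # missing month names the (year, month) hole
  d <- utils::read.csv(path)
  d <- d[!(d$year == 1950 & d$month == 6), ]
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(d, bad, row.names = FALSE)
  expect_error(loadClimateTable(bad), "1950.*6")

  d2 <- utils::read.csv(path)
  d2 <- d2[d2$year != 1950, ]
  bad2 <- tempfile(fileext = ".csv")
  utils::write.csv(d2, bad2, row.names = FALSE)
  expect_error(loadClimateTable(bad2), "contiguous")

  d3 <- utils::read.csv(path)
  d3$prec_mm[7] <- -1
  bad3 <- tempfile(fileext = ".csv")
  utils::write.csv(d3, bad3, row.names = FALSE)
  expect_error(loadClimateTable(bad3), "negative precipitation")
})

test_that("master forcing covers the full span and keeps the overlap verbatim", {
  real <- genRecentClimate(seed = 11)
  sim <- genPaleoSeries(seed = 12)
  m <- assembleMasterForcing(real, sim, ForcingRecipe(rng_seed = 13))
  yrs <- seriesYears(m)
  expect_length(yrs, 5996)
  expect_identical(yrs[1], -3982L)
  expect_identical(yrs[length(yrs)], 2013L)
  ov <- windowYears(m, 1934, 2013)
  expect_identical(tmeanMatrix(ov), tmeanMatrix(real))
  expect_identical(precMatrix(ov), precMatrix(real))
})

test_that("every spliced window's pooled means match the simulated series", {
  # independent oracle: recompute window means by direct summation
  real <- genRecentClimate(seed = 21)
  sim <- genPaleoSeries(seed = 22)
  rec <- ForcingRecipe(rng_seed = 23)
  m <- assembleMasterForcing(real, sim, rec)
  wl <- 19L
  pre <- seq.int(-3982L, 1933L)
  tm <- tmeanMatrix(m)[seq_along(pre), , drop = FALSE]
  pr <- precMatrix(m)[seq_along(pre), , drop = FALSE]
  st <- tmeanMatrix(windowYears(sim, -3982, 1933))
  sp <- precMatrix(windowYears(sim, -3982, 1933))
  pos <- 1L
  while (pos <= length(pre)) {
    len <- min(wl, length(pre) - pos + 1L)
    idx <- pos:(pos + len - 1L)
    expect_lt(abs(mean(tm[idx, ]) - mean(st[idx, ])), 1e-9)
    expect_lt(abs(mean(pr[idx, ]) - mean(sp[idx, ])) / max(mean(sp[idx, ]), 1), 1e-9)
    pos <- pos + len
  }
  # final truncated block: 5916 = 311 * 19 + 7
  expect_identical(length(pre) %% wl, 7L)
})

test_that("identity adjustment leaves window-mean temperatures unchanged", {
  real <- constantSeries(1934:2013)
  sim <- constantSeries(-3982:2013)
  m <- assembleMasterForcing(real, sim, ForcingRecipe(rng_seed = 3))
  expect_lt(max(abs(tmeanMatrix(m) -
                    matrix(rep(KHATANGA_TMEAN, each = 5996), 5996, 12))), 1e-9)
})

test_that("the splice is seed-deterministic and seed-sensitive", {
  real <- genRecentClimate(seed = 31)
  sim <- genPaleoSeries(seed = 32)
  a <- assembleMasterForcing(real, sim, ForcingRecipe(rng_seed = 7))
  b <- assembleMasterForcing(real, sim, ForcingRecipe(rng_seed = 7))
  c <- assembleMasterForcing(real, sim, ForcingRecipe(rng_seed = 8))
  expect_identical(tmeanMatrix(a), tmeanMatrix(b))
  expect_identical(a@metadata$window_starts, b@metadata$window_starts)
  expect_false(identical(a@metadata$window_starts, c@metadata$window_starts))
  expect_true(all(precMatrix(a) >= 0))
})

test_that("assembly rejects inputs that cannot cover the recipe", {
  short_real <- genRecentClimate(years = 2000:2013, seed = 1)
  sim <- genPaleoSeries(seed = 2)
  expect_error(assembleMasterForcing(short_real, sim, ForcingRecipe()),
               "overlap")
  short_sim <- genPaleoSeries(years = 0:2013, seed = 2)
  real <- genRecentClimate(seed = 1)
  expect_error(assembleMasterForcing(real, short_sim, ForcingRecipe()),
               "target span")
})

test_that("site adjustment applies the additive/multiplicative contract", {
  m <- genRecentClimate(seed = 41)
  mm <- overlapMeans(m, 1934, 2013)
  same <- siteAdjustSeries(m, mm, mm)
  expect_equal(tmeanMatrix(same), tmeanMatrix(m), tolerance = 1e-12)
  expect_equal(precMatrix(same), precMatrix(m), tolerance = 1e-12)

  colder <- siteAdjustSeries(m, mm,
    c(tmean_c = mm[["tmean_c"]] - 2, prec_mm_yr = mm[["prec_mm_yr"]]))
  expect_equal(tmeanMatrix(colder), tmeanMatrix(m) - 2, tolerance = 1e-12)

  # elementwise recomputation oracle for the 1.5x precipitation site
  wetter <- siteAdjustSeries(m, mm,
    c(tmean_c = mm[["tmean_c"]], prec_mm_yr = 1.5 * mm[["prec_mm_yr"]]))
  ratio <- precMatrix(wetter) / precMatrix(m)
  expect_lt(max(abs(ratio - 1.5)), 1e-12)

  expect_error(
    siteAdjustSeries(m, c(tmean_c = 0, prec_mm_yr = 0),
                     c(tmean_c = 0, prec_mm_yr = 100)),
    "undefined")
})
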