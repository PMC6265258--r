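test_that("weather indices follow their definitions", {
  w0 <- deriveWeatherIndices(rep(5, 12), rep(10, 12))
  expect_identical(w0$gdd, 0)
  w1 <- deriveWeatherIndices(rep(6, 12), rep(0, 12))
  expect_identical(w1$gdd, 365) # 1 degC x 365 d, non-leap convention
  tm <- rep(0, 12)
  tm[6:8] <- c(10, 12, 14)
  expect_identical(deriveWeatherIndices(tm, rep(1, 12))$summer_temp, 12)
  expect_identical(deriveWeatherIndices(tm, rep(1, 12))$annual_prec, 12)
})

test_that("competition index matches hand computations", {
  p <- emptyPlot()
  expect_identical(competitionIndex(p, 50, 50), 0)
  p1 <- plotWithTrees(treeDF("gmelinii", 55, 50, 10))
  expect_equal(competitionIndex(p1, 50, 50), 2.0) # 10 m / 5 m
  p2 <- plotWithTrees(treeDF(rep("gmelinii", 2), c(45, 55), c(50, 50), c(10, 10)))
  expect_equal(competitionIndex(p2, 50, 50), 4.0) # symmetric additivity
  # distance floor at 0.5 m
  p3 <- plotWithTrees(treeDF("gmelinii", 50.1, 50, 10))
  expect_equal(competitionIndex(p3, 50, 50), 20)
  # a tree at the exact query point is excluded
  expect_equal(competitionIndex(p1, 55, 50), 0)
  expect_error(competitionIndex(p1, 50, 50, radius = -1), "radius")
})

test_that("growth follows the saturating degree-day and crowding penalties", {
  prm <- toyParams()
  # gdd below threshold: zero increment
  p <- plotWithTrees(treeDF("sibirica", 50, 50, 1))
  g <- growTrees(p, benignWeather(gdd = 100), prm)
  expect_identical(g@trees$height, 1)
  # half-saturation closed form: gdd - gdd_min = gdd_halfsat
  g2 <- growTrees(p, benignWeather(gdd = 300), prm)
  expect_equal(g2@trees$height, 1 + 0.4 / 2, tolerance = 1e-12)
  # extra large neighbour strictly reduces the focal increment
  crowded <- plotWithTrees(treeDF(c("sibirica", "gmelinii"), c(50, 52),
                                  c(50, 50), c(1, 20)))
  gc <- growTrees(crowded, benignWeather(gdd = 300), prm)
  expect_lt(gc@trees$height[1] - 1, g2@trees$height - 1)
  # heights capped
  tall <- plotWithTrees(treeDF("sibirica", 50, 50, 49.9))
  gt <- growTrees(tall, benignWeather(gdd = 5000), toyParams(max_height = 50))
  expect_lte(gt@trees$height, 50)
})

test_that("seed production obeys the maturity gate and the Poisson oracle", {
  prm <- toyParams()
  below <- plotWithTrees(treeDF("sibirica", 50, 50, 1.9))
  expect_identical(nrow(produceSeeds(below, benignWeather(gdd = 300), prm)@seedbank), 0L)
  expect_identical(
    nrow(produceSeeds(plotWithTrees(treeDF("sibirica", 50, 50, 10)),
                      benignWeather(gdd = 50), prm)@seedbank), 0L)
  # 10^4 trees, each Poisson(mu = 10 * (4 - 2) * 0.5) = Poisson(10)
  set.seed(91)
  n <- 10000
  big <- plotWithTrees(treeDF(rep("sibirica", n), runif(n, 0, 100),
                              runif(n, 0, 100), rep(4, n)),
                       Lx = 100, Ly = 100)
  out <- produceSeeds(big, benignWeather(gdd = 300), prm)
  mu <- 10
  se <- sqrt(mu / n)
  expect_lt(abs(nrow(out@seedbank) / n - mu), 3 * se)
  expect_true(all(out@seedbank$age == 0))
})

test_that("dispersal matches the exponential kernel and the open boundary", {
  prm <- toyParams(dispersal_mean = 1e-9)
  p <- emptyPlot(100, 100)
  p@seedbank <- seedDF(rep("sibirica", 100), rep(50, 100), rep(50, 100))
  set.seed(8)
  d <- disperseSeeds(p, prm)
  expect_lt(max(abs(d@seedbank$x - 50)), 1e-6)
  # mean displacement on a huge plot
  n <- 10000
  big <- emptyPlot(1e5, 1e5)
  big@seedbank <- seedDF(rep("sibirica", n), rep(5e4, n), rep(5e4, n))
  set.seed(9)
  moved <- disperseSeeds(big, toyParams(dispersal_mean = 30))
  disp <- sqrt((moved@seedbank$x - 5e4)^2 + (moved@seedbank$y - 5e4)^2)
  expect_lt(abs(mean(disp) - 30), 3 * 30 / sqrt(n))
  # parent on the edge loses about half its seeds off-plot
  edge <- emptyPlot(1e5, 1e5)
  edge@seedbank <- seedDF(rep("sibirica", n), rep(0, n) + 1e-9, rep(5e4, n))
  set.seed(10)
  kept <- nrow(disperseSeeds(edge, toyParams(dispersal_mean = 30))@seedbank)
  expect_lt(abs(kept / n - 0.5), 3 * sqrt(0.25 / n))
  # only age-0 seeds move
  stay <- emptyPlot(100, 100)
  stay@seedbank <- seedDF("sibirica", 50, 50, age = 1)
  set.seed(11)
  expect_identical(disperseSeeds(stay, toyParams(dispersal_mean = 30))@seedbank$x, 50)
})

test_that("establishment matches the binomial oracle and crowding penalty", {
  p0 <- emptyPlot()
  p0@seedbank <- seedDF(rep("sibirica", 100), runif(100, 0, 100), runif(100, 0, 100))
  set.seed(12)
  expect_identical(nrow(establishSeeds(p0, benignWeather(gdd = 300),
                                       toyParams(estab_prob = 0))@trees), 0L)
  # per-seed p = 0.4 * T(0.5) = 0.2 on an empty plot, no precipitation scalar
  n <- 10000
  p1 <- emptyPlot(1000, 1000)
  p1@seedbank <- seedDF(rep("sibirica", n), runif(n, 0, 1000), runif(n, 0, 1000))
  set.seed(13)
  est <- establishSeeds(p1, benignWeather(gdd = 300), toyParams(estab_prob = 0.4),
                        use_precip = FALSE)
  expect_lt(abs(nrow(est@trees) - n * 0.2), 3 * sqrt(n * 0.2 * 0.8))
  expect_identical(nrow(est@trees) + nrow(est@seedbank), as.integer(n))
  expect_true(all(est@trees$height == 0.05))
  # crowding lowers establishment frequency
  crowd <- plotWithTrees(treeDF(rep("gmelinii", 20),
                                rep(seq(46, 54, 2), 4),
                                rep(seq(46, 52, 2), each = 5), rep(15, 20)),
                         Lx = 100, Ly = 100)
  crowd@seedbank <- seedDF(rep("sibirica", 2000), runif(2000, 48, 52),
                           runif(2000, 48, 52))
  open <- emptyPlot(100, 100)
  open@seedbank <- crowd@seedbank
  set.seed(14)
  nc <- nrow(establishSeeds(crowd, benignWeather(gdd = 300),
                            toyParams(estab_prob = 0.4), use_precip = FALSE)@trees) - 20
  no <- nrow(establishSeeds(open, benignWeather(gdd = 300),
                            toyParams(estab_prob = 0.4), use_precip = FALSE)@trees)
  expect_lt(nc, no)
})

test_that("mortality/ageing obeys its limits and the binomial oracle", {
  prm <- toyParams()
  p <- plotWithTrees(treeDF(rep("sibirica", 50), runif(50, 0, 100),
                            runif(50, 0, 100), rep(5, 50), age = 10))
  set.seed(15)
  out <- mortalityAgeing(p, benignWeather(), prm)
  expect_identical(nrow(out@trees), 50L)
  expect_true(all(out@trees$age == 11))
  dead <- mortalityAgeing(p, benignWeather(), toyParams(background_mort = 1))
  expect_identical(nrow(dead@trees), 0L)
  old <- mortalityAgeing(plotWithTrees(treeDF("sibirica", 1, 1, 5, age = 1000)),
                         benignWeather(), prm)
  expect_identical(nrow(old@trees), 0L)
  # 10^4 isolated trees at background_mort 0.02
  n <- 10000
  big <- plotWithTrees(treeDF(rep("sibirica", n), runif(n, 0, 1000),
                              runif(n, 0, 1000), rep(5, n)),
                       Lx = 1000, Ly = 1000)
  set.seed(16)
  surv <- mortalityAgeing(big, benignWeather(), toyParams(background_mort = 0.02))
  deaths <- n - nrow(surv@trees)
  expect_lt(abs(deaths - 200), 3 * sqrt(n * 0.02 * 0.98))
  # seed bank mortality and residence limit
  sb <- emptyPlot()
  sb@seedbank <- seedDF(rep("sibirica", 100), runif(100, 0, 100),
                        runif(100, 0, 100), age = 0)
  set.seed(17)
  kept <- mortalityAgeing(sb, benignWeather(), toyParams(seed_mort = 0.5))
  expect_lt(nrow(kept@seedbank), 100)
  expect_true(all(kept@seedbank$age == 1))
  gone <- mortalityAgeing(sb, benignWeather(), toyParams(max_seed_age = 0))
  expect_identical(nrow(gone@seedbank), 0L)
})

test_that("seed introduction is Poisson at rate x area and species-closed", {
  p <- emptyPlot(100, 100)
  expect_identical(nrow(introduceSeeds(p, character(), 100)@seedbank), 0L)
  set.seed(18)
  tot <- replicate(400, nrow(introduceSeeds(p, "gmelinii", 100)@seedbank))
  expect_lt(abs(mean(tot) - 100), 3 * sqrt(100 / 400))
  set.seed(19)
  both <- introduceSeeds(p, c("sibirica", "gmelinii"), 100)
  expect_setequal(unique(both@seedbank$species), c("sibirica", "gmelinii"))
  solo <- introduceSeeds(p, "sibirica", 100)
  expect_false("gmelinii" %in% solo@seedbank$species)
})

test_that("a year step keeps the plot valid and an empty plot absorbing", {
  prm <- toyParams()
  w <- benignWeather(gdd = 300)
  p <- emptyPlot(50, 50)
  set.seed(20)
  p2 <- stepYear(p, w, prm, character(0), 0)
  expect_identical(nrow(p2@trees), 0L)
  expect_identical(nrow(p2@seedbank), 0L)
  expect_identical(p2@year, 1L)
  # populated run stays valid every year
  set.seed(21)
  pl <- emptyPlot(50, 50)
  for (i in 1:60) {
    pl <- stepYear(pl, w, prm, c("sibirica", "gmelinii"), 100)
    expect_true(validObject(pl, test = TRUE) == TRUE)
  }
  expect_gt(nrow(pl@trees), 0)
})

test_that("an isolated mature tree regenerates a stand within 50 years", {
  prm <- defaultSpeciesParams()
  w <- benignWeather(gdd = 650, prec = 280)
  ok <- 0L
  for (i in 1:100) {
    set.seed(1000 + i)
    pl <- plotWithTrees(treeDF("gmelinii", 50, 50, 6, age = 50), 100, 100)
    for (t in 1:50) pl <- stepYear(pl, w, prm, character(0), 0)
    tr <- pl@trees
    if (any(tr$age < 50)) ok <- ok + 1L
  }
  expect_gte(ok, 95)
})
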