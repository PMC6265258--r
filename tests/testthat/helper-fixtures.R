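# Fixtures built in code: toy climate, simple plots, easy-number species
# parameters for closed-form sub-model checks.

KHATANGA_TMEAN <- c(-32, -30, -22, -13, -1, 7, 13, 10, 3, -9, -25, -30)
KHATANGA_PREC <- c(15, 12, 12, 14, 20, 35, 45, 40, 30, 25, 18, 15)

constantSeries <- function(years, tmean = KHATANGA_TMEAN, prec = KHATANGA_PREC,
                           offset = 0, label = "const") {
  n <- length(years)
  ClimateSeries(years,
    matrix(rep(tmean + offset, each = n), n, 12),
    matrix(rep(prec, each = n), n, 12), label = label)
}

rampSeries <- function(years, base = 0, slope = 0.01) {
  n <- length(years)
  tm <- matrix(rep(KHATANGA_TMEAN, each = n), n, 12) +
    base + slope * seq_len(n)
  ClimateSeries(years, tm, matrix(rep(KHATANGA_PREC, each = n), n, 12))
}

writeClimateCSV <- function(series, path = tempfile(fileext = ".csv")) {
  writeClimateTable(series, path)
  path
}

# one-parameter-per-mechanism species set with round numbers
toyParams <- function(...) {
  override <- list(...)
  base <- list(
    height_growth_max = 0.4, gdd_min = 100, gdd_halfsat = 200,
    comp_sens_growth = 0.5, comp_sens_estab = 0.5, comp_mort_coeff = 0,
    fecundity = 10, maturity_height = 2, dispersal_mean = 5,
    estab_prob = 0.2, background_mort = 0, seed_mort = 0,
    max_seed_age = 100, max_age = 1000, max_height = 50
  )
  mk <- function(id) {
    args <- base
    for (nm in names(override)) args[[nm]] <- override[[nm]]
    do.call(SpeciesParams, c(list(species_id = id), args))
  }
  list(sibirica = mk("sibirica"), gmelinii = mk("gmelinii"))
}

plotWithTrees <- function(trees, Lx = 100, Ly = 100, year = 0L) {
  p <- emptyPlot(Lx, Ly, year)
  p@trees <- trees
  p
}

treeDF <- function(species, x, y, height, age = 50) {
  data.frame(species = species, x = x, y = y, height = height, age = age)
}

seedDF <- function(species, x, y, age = 0) {
  data.frame(species = species, x = x, y = y, age = age)
}

benignWeather <- function(gdd = 500, summer = 12, prec = 300) {
  list(gdd = gdd, summer_temp = summer, annual_prec = prec)
}
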