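# Yearly sub-models, invoked in this order within each simulated year:
# (seed introduction when the phase introduces species, then)
# growth -> seed production -> seed dispersal -> establishment ->
# mortality/ageing. All randomness goes through R's RNG so a set.seed()
# before a run makes it exactly replayable.

# per-individual lookup of a parameter field across the two species
.pfield <- function(params, field) {
  vapply(params, function(p) slot(p, field), numeric(1))
}

.tresp <- function(gdd, params) {
  vapply(params, function(p) gddResponse(gdd, p), numeric(1))
}

#' Grow all trees for one year
#'
#' Each tree's height increases by
#' `height_growth_max * T(gdd) * exp(-comp_sens_growth * NCI)` where `T` is the
#' species' saturating degree-day response ([gddResponse()]) and NCI the
#' neighbourhood competition index at the tree's own position. Heights are
#' capped at the species maximum.
#'
#' @param plot a [PlotState-class]
#' @param weather list from [deriveWeatherIndices()]
#' @param params named list of [SpeciesParams-class] (sibirica, gmelinii)
#' @param radius,dist_floor competition neighbourhood, m
#' @return the updated plot
#' @export
growTrees <- function(plot, weather, params, radius = 10, dist_floor = 0.5) {
  tr <- plot@trees
  if (!nrow(tr)) return(plot)
  nci <- competitionIndex(plot, tr$x, tr$y, radius, dist_floor)
  tv <- .tresp(weather$gdd, params)[tr$species]
  inc <- .pfield(params, "height_growth_max")[tr$species] * tv *
    exp(-.pfield(params, "comp_sens_growth")[tr$species] * nci)
  tr$height <- pmin(tr$height + inc, .pfield(params, "max_height")[tr$species])
  plot@trees <- tr
  plot
}

#' Seed production
#'
#' Every tree taller than its species' maturity height drops
#' `Poisson(fecundity * (height - maturity_height) * T(gdd))` seeds at its own
#' coordinates (age 0); dispersal moves them in the following sub-model.
#'
#' @inheritParams growTrees
#' @return the updated plot
#' @export
produceSeeds <- function(plot, weather, params) {
  tr <- plot@trees
  if (!nrow(tr)) return(plot)
  mat <- .pfield(params, "maturity_height")[tr$species]
  tv <- .tresp(weather$gdd, params)[tr$species]
  mu <- .pfield(params, "fecundity")[tr$species] * pmax(0, tr$height - mat) * tv
  n <- stats::rpois(length(mu), mu)
  keep <- n > 0L
  if (!any(keep)) return(plot)
  idx <- rep(which(keep), n[keep])
  newseeds <- data.frame(species = tr$species[idx], x = tr$x[idx],
                         y = tr$y[idx], age = 0)
  plot@seedbank <- rbind(plot@seedbank, newseeds)
  plot
}

#' Seed dispersal
#'
#' Each age-0 seed moves once: displacement distance is exponential with the
#' species' mean dispersal distance, direction uniform. Seeds landing outside
#' the plot are lost (open boundary). Older seed-bank seeds do not move again.
#'
#' @inheritParams growTrees
#' @return the updated plot
#' @export
disperseSeeds <- function(plot, params) {
  sb <- plot@seedbank
  mv <- which(sb$age == 0)
  if (!length(mv)) return(plot)
  dm <- .pfield(params, "dispersal_mean")[sb$species[mv]]
  r <- stats::rexp(length(mv), rate = 1 / dm)
  th <- stats::runif(length(mv), 0, 2 * pi)
  sb$x[mv] <- sb$x[mv] + r * cos(th)
  sb$y[mv] <- sb$y[mv] + r * sin(th)
  keep <- sb$x >= 0 & sb$x < plot@Lx & sb$y >= 0 & sb$y < plot@Ly
  plot@seedbank <- sb[keep, , drop = FALSE]
  plot
}

#' Establishment
#'
#' Each seed in the bank germinates and establishes with probability
#' `estab_prob * T(gdd) * exp(-comp_sens_estab * NCI) * w(prec)`, where the
#' optional precipitation scalar `w = clamp(annual_prec / precip_ref, 0.5, 1)`
#' couples recruitment to moisture. New recruits enter the tree layer at
#' height 0.05 m, age 0, and leave the seed bank.
#'
#' @inheritParams growTrees
#' @param use_precip logical, apply the precipitation scalar?
#' @param precip_ref reference annual precipitation, mm
#' @return the updated plot
#' @export
establishSeeds <- function(plot, weather, params, radius = 10, dist_floor = 0.5,
                           use_precip = TRUE, precip_ref = 250) {
  sb <- plot@seedbank
  if (!nrow(sb)) return(plot)
  nci <- competitionIndex(plot, sb$x, sb$y, radius, dist_floor)
  tv <- .tresp(weather$gdd, params)[sb$species]
  w <- if (use_precip) min(1, max(0.5, weather$annual_prec / precip_ref)) else 1
  p <- .pfield(params, "estab_prob")[sb$species] * tv *
    exp(-.pfield(params, "comp_sens_estab")[sb$species] * nci) * w
  est <- stats::runif(nrow(sb)) < p
  if (any(est)) {
    rec <- data.frame(species = sb$species[est], x = sb$x[est], y = sb$y[est],
                      height = 0.05, age = 0)
    plot@trees <- rbind(plot@trees, rec)
    plot@seedbank <- sb[!est, , drop = FALSE]
  }
  plot
}

#' Mortality and ageing
#'
#' Each tree dies with probability
#' `min(1, background_mort + comp_mort_coeff * NCI)`; trees at or beyond their
#' species' maximum age die deterministically. Each seed dies with probability
#' `seed_mort`. Survivors age by one year; seeds exceeding the seed-bank
#' residence limit are removed.
#'
#' @inheritParams growTrees
#' @return the updated plot
#' @export
mortalityAgeing <- function(plot, weather, params, radius = 10, dist_floor = 0.5) {
  tr <- plot@trees
  if (nrow(tr)) {
    nci <- competitionIndex(plot, tr$x, tr$y, radius, dist_floor)
    p <- pmin(1, .pfield(params, "background_mort")[tr$species] +
                .pfield(params, "comp_mort_coeff")[tr$species] * nci)
    die <- stats::runif(nrow(tr)) < p
    die <- die | tr$age >= .pfield(params, "max_age")[tr$species]
    tr <- tr[!die, , drop = FALSE]
    tr$age <- tr$age + 1
    plot@trees <- tr
  }
  sb <- plot@seedbank
  if (nrow(sb)) {
    die <- stats::runif(nrow(sb)) < .pfield(params, "seed_mort")[sb$species]
    sb <- sb[!die, , drop = FALSE]
    sb$age <- sb$age + 1
    sb <- sb[sb$age <= .pfield(params, "max_seed_age")[sb$species], , drop = FALSE]
    plot@seedbank <- sb
  }
  plot
}

#' Seed introduction (external seed rain)
#'
#' For each species in `species_set`, adds `Poisson(rate * area_ha)` seeds at
#' uniform random in-plot positions, age 0.
#'
#' @param plot a [PlotState-class]
#' @param species_set character vector, subset of c("sibirica", "gmelinii")
#' @param rate seeds/ha/yr per species
#' @return the updated plot
#' @export
introduceSeeds <- function(plot, species_set, rate = 100) {
  stopifnot(rate >= 0)
  if (!length(species_set)) return(plot)
  area_ha <- plot@Lx * plot@Ly / 1e4
  for (sp in species_set) {
    n <- stats::rpois(1, rate * area_ha)
    if (n > 0) {
      plot@seedbank <- rbind(plot@seedbank, data.frame(
        species = sp, x = stats::runif(n, 0, plot@Lx),
        y = stats::runif(n, 0, plot@Ly), age = 0
      ))
    }
  }
  plot
}

#' Advance the plot by one year
#'
#' Applies, in order: seed introduction (when `intro_species` is non-empty),
#' growth, seed production, seed dispersal, establishment, mortality/ageing;
#' then increments the plot year.
#'
#' @inheritParams establishSeeds
#' @param intro_species species receiving external seed rain this year
#' @param intro_rate seeds/ha/yr per introduced species
#' @return the updated plot
#' @export
stepYear <- function(plot, weather, params, intro_species = character(),
                     intro_rate = 100, radius = 10, dist_floor = 0.5,
                     use_precip = TRUE, precip_ref = 250) {
  plot <- introduceSeeds(plot, intro_species, intro_rate)
  plot <- growTrees(plot, weather, params, radius, dist_floor)
  plot <- produceSeeds(plot, weather, params)
  plot <- disperseSeeds(plot, params)
  plot <- establishSeeds(plot, weather, params, radius, dist_floor,
                         use_precip, precip_ref)
  plot <- mortalityAgeing(plot, weather, params, radius, dist_floor)
  plot@year <- plot@year + 1L
  plot
}
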