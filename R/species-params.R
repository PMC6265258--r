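.SPECIES_FIELDS <- c(
  "height_growth_max", "gdd_min", "gdd_halfsat", "comp_sens_growth",
  "comp_sens_estab", "comp_mort_coeff", "fecundity", "maturity_height",
  "dispersal_mean", "estab_prob", "background_mort", "seed_mort",
  "max_seed_age", "max_age", "max_height"
)

#' Construct a SpeciesParams object
#'
#' @param species_id "sibirica" or "gmelinii"
#' @param height_growth_max maximum annual height increment, m/yr
#' @param gdd_min degree-day threshold, degC day
#' @param gdd_halfsat degree-day half-saturation, degC day
#' @param comp_sens_growth growth sensitivity to competition
#' @param comp_sens_estab establishment sensitivity to competition
#' @param comp_mort_coeff mortality per unit competition index, 1/yr
#' @param fecundity seeds per metre of height above maturity per year
#' @param maturity_height seed-bearing height threshold, m
#' @param dispersal_mean mean dispersal distance, m
#' @param estab_prob per-seed annual establishment probability at optimum
#' @param background_mort baseline annual mortality probability
#' @param seed_mort annual seed-bank mortality probability
#' @param max_seed_age seed-bank residence limit, yr
#' @param max_age maximum tree age, yr
#' @param max_height height cap, m
#' @return a [SpeciesParams-class]
#' @export
SpeciesParams <- function(species_id, height_growth_max, gdd_min, gdd_halfsat,
                          comp_sens_growth, comp_sens_estab, comp_mort_coeff,
                          fecundity, maturity_height, dispersal_mean,
                          estab_prob, background_mort, seed_mort, max_seed_age,
                          max_age, max_height) {
  new("SpeciesParams",
    species_id = species_id, height_growth_max = height_growth_max,
    gdd_min = gdd_min, gdd_halfsat = gdd_halfsat,
    comp_sens_growth = comp_sens_growth, comp_sens_estab = comp_sens_estab,
    comp_mort_coeff = comp_mort_coeff, fecundity = fecundity,
    maturity_height = maturity_height, dispersal_mean = dispersal_mean,
    estab_prob = estab_prob, background_mort = background_mort,
    seed_mort = seed_mort, max_seed_age = max_seed_age, max_age = max_age,
    max_height = max_height
  )
}

#' Read a species parameter file
#'
#' YAML with one block per species; every [SpeciesParams-class] field must be
#' present in each block.
#'
#' @param path YAML file path
#' @return named list of [SpeciesParams-class], one per species block
#' @export
readSpeciesParams <- function(path) {
  y <- yaml::read_yaml(path)
  y <- y[setdiff(names(y), "version")]
  out <- lapply(names(y), function(sp) {
    block <- y[[sp]]
    miss <- setdiff(.SPECIES_FIELDS, names(block))
    if (length(miss))
      stop("species '", sp, "' missing field(s): ", paste(miss, collapse = ", "))
    do.call(SpeciesParams, c(list(species_id = sp),
                             lapply(block[.SPECIES_FIELDS], as.numeric)))
  })
  names(out) <- names(y)
  out
}

#' Shipped default species parameters
#'
#' Loads the versioned parameter file shipped with the package. The defaults
#' encode the species asymmetry the simulator rests on: Larix sibirica grows
#' and disperses faster but requires more warmth and is more sensitive to
#' crowding (establishment, growth and mortality), whereas Larix gmelinii is
#' slower but tolerates cold and dense neighbourhoods. Values are calibrated
#' so that dense stands exclude sibirica while sparse cold stands admit both
#' species.
#'
#' @return named list with elements `sibirica` and `gmelinii`
#' @export
defaultSpeciesParams <- function() {
  readSpeciesParams(system.file("extdata", "species_params.yaml",
                                package = "larch2s", mustWork = TRUE))
}
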