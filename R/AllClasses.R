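#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib larch2s, .registration = TRUE
NULL

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' ClimateSeries: contiguous years of monthly climate
#'
#' Stores, for a run of strictly consecutive calendar (or model) years, the 12
#' monthly mean temperatures (degrees C) and 12 monthly precipitation sums (mm)
#' per year, plus a free-text label (typically a site id) and a metadata list
#' used to carry provenance such as the splice recipe and chosen window starts.
#'
#' Negative years are model years before year 1 (e.g. -3982).
#'
#' @slot years integer vector of strictly consecutive years
#' @slot tmean numeric matrix, one row per year, 12 columns (monthly mean, degC)
#' @slot prec numeric matrix, one row per year, 12 columns (monthly sum, mm)
#' @slot label character(1) series label
#' @slot metadata list of provenance entries
#' @exportClass ClimateSeries
setClass("ClimateSeries",
  representation(
    years = "integer",
    tmean = "matrix",
    prec = "matrix",
    label = "character",
    metadata = "list"
  )
)

setValidity("ClimateSeries", function(object) {
  msg <- character()
  n <- length(object@years)
  if (n < 1L) msg <- c(msg, "series must contain at least one year")
  if (n > 1L && any(diff(object@years) != 1L))
    msg <- c(msg, "years must be strictly consecutive")
  for (nm in c("tmean", "prec")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != 12L)
      msg <- c(msg, sprintf("%s must be a numeric %d x 12 matrix", nm, n))
  }
  if (anyNA(object@tmean) || anyNA(object@prec))
    msg <- c(msg, "climate values must not contain NA")
  if (length(msg) == 0L) {
    if (any(object@prec < 0)) msg <- c(msg, "precipitation must be >= 0")
    if (any(object@tmean < -70 | object@tmean > 45))
      msg <- c(msg, "monthly mean temperature outside [-70, 45] degC")
  }
  if (length(object@label) != 1L) msg <- c(msg, "label must be character(1)")
  if (length(msg)) msg else TRUE
})

#' Construct a ClimateSeries
#'
#' @param years integer vector of consecutive years
#' @param tmean numeric matrix (years x 12) of monthly mean temperature, degC
#' @param prec numeric matrix (years x 12) of monthly precipitation sum, mm
#' @param label series label
#' @param metadata optional list of provenance entries
#' @return a [ClimateSeries-class] object
#' @export
ClimateSeries <- function(years, tmean, prec, label = "series", metadata = list()) {
  new("ClimateSeries",
    years = as.integer(years),
    tmean = as.matrix(tmean), prec = as.matrix(prec),
    label = as.character(label), metadata = metadata
  )
}

#' ForcingRecipe: how to splice recent windows onto a paleo series
#'
#' Describes the bootstrap splice that builds the master forcing: fixed-length
#' windows of the recent ("real") series are drawn at random, concatenated to
#' cover the pre-overlap span, and each block's pooled window mean is adjusted
#' to the corresponding window of the simulated paleo series (additive for
#' temperature; multiplicative or additive for precipitation, floored).
#' The overlap years are then appended verbatim from the real series.
#'
#' @slot window_len integer window length in years (default 19)
#' @slot target_start integer first year of the assembled series (default -3982)
#' @slot splice_end integer last spliced year (default 1933)
#' @slot overlap_start,overlap_end integer overlap span covered verbatim by the
#'   real series (defaults 1934 and 2013); must immediately follow splice_end
#' @slot temp_adjust "additive" (the only mode for temperature)
#' @slot prec_adjust "multiplicative" or "additive"
#' @slot prec_floor numeric lower bound applied to adjusted precipitation, mm
#' @slot rng_seed integer seed governing all randomness of the splice
#' @exportClass ForcingRecipe
setClass("ForcingRecipe",
  representation(
    window_len = "integer", target_start = "integer", splice_end = "integer",
    overlap_start = "integer", overlap_end = "integer",
    temp_adjust = "character", prec_adjust = "character",
    prec_floor = "numeric", rng_seed = "integer"
  )
)

setValidity("ForcingRecipe", function(object) {
  msg <- character()
  if (object@window_len < 1L) msg <- c(msg, "window_len must be >= 1")
  if (object@target_start > object@splice_end)
    msg <- c(msg, "target_start must be <= splice_end")
  if (object@overlap_start != object@splice_end + 1L)
    msg <- c(msg, "overlap must immediately follow splice_end")
  if (object@overlap_end < object@overlap_start)
    msg <- c(msg, "overlap_end must be >= overlap_start")
  if (!identical(object@temp_adjust, "additive"))
    msg <- c(msg, "temp_adjust must be 'additive'")
  if (!object@prec_adjust %in% c("multiplicative", "additive"))
    msg <- c(msg, "prec_adjust must be 'multiplicative' or 'additive'")
  if (object@prec_floor < 0) msg <- c(msg, "prec_floor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ForcingRecipe
#'
#' Defaults reproduce the published splice: 19-year windows drawn from
#' 1934-2013 cover -3982..1933, and 1934-2013 is taken verbatim.
#'
#' @param window_len window length, years
#' @param target_start first assembled year
#' @param splice_end last spliced year
#' @param overlap_start,overlap_end span taken verbatim from the real series
#' @param temp_adjust temperature adjustment mode, only "additive"
#' @param prec_adjust precipitation adjustment mode
#' @param prec_floor lower bound for adjusted precipitation, mm
#' @param rng_seed integer seed for the window draw
#' @return a [ForcingRecipe-class]
#' @export
ForcingRecipe <- function(window_len = 19, target_start = -3982,
                          splice_end = 1933, overlap_start = 1934,
                          overlap_end = 2013, temp_adjust = "additive",
                          prec_adjust = "multiplicative", prec_floor = 0,
                          rng_seed = 1L) {
  new("ForcingRecipe",
    window_len = as.integer(window_len), target_start = as.integer(target_start),
    splice_end = as.integer(splice_end), overlap_start = as.integer(overlap_start),
    overlap_end = as.integer(overlap_end), temp_adjust = temp_adjust,
    prec_adjust = prec_adjust, prec_floor = prec_floor,
    rng_seed = as.integer(rng_seed)
  )
}

#' SpeciesParams: per-species vital-rate parameters
#'
#' One set of rates per larch species controlling the growth, seed production,
#' dispersal, establishment and mortality sub-models. Shipped defaults (see
#' [defaultSpeciesParams()]) encode the asymmetry between the fast-growing,
#' competition- and cold-sensitive Larix sibirica and the slower but hardier
#' Larix gmelinii.
#'
#' @slot species_id "sibirica" or "gmelinii"
#' @slot height_growth_max maximum annual height increment, m/yr
#' @slot gdd_min growing-degree-day threshold (degC day, base 5) below which
#'   growth, seed ripening and establishment shut down
#' @slot gdd_halfsat half-saturation of the degree-day response, degC day
#' @slot comp_sens_growth growth reduction per unit competition index
#' @slot comp_sens_estab establishment reduction per unit competition index
#' @slot comp_mort_coeff added mortality per unit competition index, 1/yr
#' @slot fecundity seeds per metre of height above maturity per year (at full
#'   degree-day response)
#' @slot maturity_height height above which trees set seed, m
#' @slot dispersal_mean mean of the exponential dispersal kernel, m
#' @slot estab_prob per-seed annual establishment probability at optimum
#' @slot background_mort baseline annual mortality probability
#' @slot seed_mort annual seed-bank mortality probability
#' @slot max_seed_age seed-bank residence limit, yr
#' @slot max_age maximum tree age, yr
#' @slot max_height height cap, m
#' @exportClass SpeciesParams
setClass("SpeciesParams",
  representation(
    species_id = "character",
    height_growth_max = "numeric", gdd_min = "numeric", gdd_halfsat = "numeric",
    comp_sens_growth = "numeric", comp_sens_estab = "numeric",
    comp_mort_coeff = "numeric", fecundity = "numeric",
    maturity_height = "numeric", dispersal_mean = "numeric",
    estab_prob = "numeric", background_mort = "numeric", seed_mort = "numeric",
    max_seed_age = "numeric", max_age = "numeric", max_height = "numeric"
  )
)

setValidity("SpeciesParams", function(object) {
  msg <- character()
  if (!object@species_id %in% c("sibirica", "gmelinii"))
    msg <- c(msg, "species_id must be 'sibirica' or 'gmelinii'")
  probs <- c(estab_prob = object@estab_prob,
             background_mort = object@background_mort,
             seed_mort = object@seed_mort)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) msg <- c(msg, paste0(bad, " must be in [0, 1]"))
  rates <- c("height_growth_max", "gdd_min", "gdd_halfsat", "comp_sens_growth",
             "comp_sens_estab", "comp_mort_coeff", "fecundity",
             "maturity_height", "dispersal_mean", "max_seed_age", "max_age",
             "max_height")
  for (nm in rates) if (slot(object, nm) < 0) msg <- c(msg, paste0(nm, " must be >= 0"))
  if (length(msg)) msg else TRUE
})

#' PlotState: a spatially explicit stand of trees and a seed bank
#'
#' Individual trees and seed-bank items on a rectangular plot with open
#' (absorbing) boundaries; seeds dispersing beyond the edge are lost.
#'
#' @slot Lx,Ly plot extent, m (default 100 x 100 m = 1 ha)
#' @slot trees data.frame with columns species, x, y, height (m), age (yr)
#' @slot seedbank data.frame with columns species, x, y, age (yr)
#' @slot year integer current year
#' @exportClass PlotState
setClass("PlotState",
  representation(
    Lx = "numeric", Ly = "numeric",
    trees = "data.frame", seedbank = "data.frame", year = "integer"
  )
)

setValidity("PlotState", function(object) {
  msg <- character()
  if (object@Lx <= 0 || object@Ly <= 0) msg <- c(msg, "plot extent must be positive")
  tr <- object@trees
  sb <- object@seedbank
  if (!all(c("species", "x", "y", "height", "age") %in% names(tr)))
    msg <- c(msg, "trees must have columns species, x, y, height, age")
  if (!all(c("species", "x", "y", "age") %in% names(sb)))
    msg <- c(msg, "seedbank must have columns species, x, y, age")
  if (length(msg) == 0L) {
    inplot <- function(d) all(d$x >= 0 & d$x < object@Lx & d$y >= 0 & d$y < object@Ly)
    if (nrow(tr) && !inplot(tr)) msg <- c(msg, "tree coordinates outside plot")
    if (nrow(sb) && !inplot(sb)) msg <- c(msg, "seed coordinates outside plot")
    if (nrow(tr) && any(tr$height <= 0)) msg <- c(msg, "tree heights must be > 0")
    if (nrow(tr) && any(tr$age < 0)) msg <- c(msg, "tree ages must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' ScenarioSpec: one simulation experiment
#'
#' A simulation consists of a stabilisation phase of `stab_years` steps, during
#' which whole weather years are resampled at random from the first 30 years
#' of the forcing, followed by a simulation phase stepping through the forcing
#' year by year. Seeds of the phase's species set rain onto the plot at
#' `introduction_rate` each year.
#'
#' @slot forcing a [ClimateSeries-class] driving the simulation phase
#' @slot stab_years length of the stabilisation phase, yr (default 1000)
#' @slot stab_species character vector of species introduced during stabilisation
#' @slot sim_species character vector of species introduced during simulation
#' @slot introduction_rate seed rain, seeds/ha/yr per introduced species
#' @slot replicates number of independent replicates
#' @slot seed integer root seed (one RNG stream per replicate is derived)
#' @slot Lx,Ly plot extent, m
#' @slot density_height_cutoff trees at or above this height count towards
#'   stand density, m (default 1.3, breast height)
#' @slot use_precip logical, couple establishment to annual precipitation
#' @slot precip_ref reference annual precipitation for the establishment
#'   scalar, mm
#' @slot abort_cap abort a replicate when the live-tree count exceeds this cap
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(
    forcing = "ClimateSeries",
    stab_years = "integer", stab_species = "character",
    sim_species = "character", introduction_rate = "numeric",
    replicates = "integer", seed = "integer",
    Lx = "numeric", Ly = "numeric", density_height_cutoff = "numeric",
    use_precip = "logical", precip_ref = "numeric", abort_cap = "numeric"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (object@stab_years < 0L) msg <- c(msg, "stab_years must be >= 0")
  ok <- c("sibirica", "gmelinii")
  if (!all(object@stab_species %in% ok) || !all(object@sim_species %in% ok))
    msg <- c(msg, "species sets must be subsets of {sibirica, gmelinii}")
  if (object@introduction_rate < 0) msg <- c(msg, "introduction_rate must be >= 0")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@Lx <= 0 || object@Ly <= 0) msg <- c(msg, "plot extent must be positive")
  if (object@density_height_cutoff < 0) msg <- c(msg, "density cutoff must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ScenarioSpec
#'
#' @param forcing a [ClimateSeries-class]
#' @param stab_years stabilisation length, yr
#' @param stab_species species introduced during stabilisation
#' @param sim_species species introduced during the simulation phase
#' @param introduction_rate seeds/ha/yr per introduced species
#' @param replicates number of replicates
#' @param seed integer root seed
#' @param Lx,Ly plot extent, m
#' @param density_height_cutoff density counting cutoff, m
#' @param use_precip couple establishment to annual precipitation?
#' @param precip_ref reference annual precipitation, mm
#' @param abort_cap live-tree count triggering replicate abort
#' @return a [ScenarioSpec-class]
#' @export
ScenarioSpec <- function(forcing, stab_years = 1000, stab_species = character(),
                         sim_species = character(), introduction_rate = 100,
                         replicates = 1, seed = 1L, Lx = 100, Ly = 100,
                         density_height_cutoff = 1.3, use_precip = TRUE,
                         precip_ref = 250, abort_cap = 1e6) {
  new("ScenarioSpec",
    forcing = forcing, stab_years = as.integer(stab_years),
    stab_species = stab_species, sim_species = sim_species,
    introduction_rate = introduction_rate, replicates = as.integer(replicates),
    seed = as.integer(seed), Lx = Lx, Ly = Ly,
    density_height_cutoff = density_height_cutoff, use_precip = use_precip,
    precip_ref = precip_ref, abort_cap = abort_cap
  )
}

#' ScenarioResult: recorded output of a simulation experiment
#'
#' @slot series long data.frame (replicate, phase, year, species, density,
#'   fraction, seedbank, trees, summer_temp); density in trees/ha counting
#'   trees at or above the scenario's height cutoff, `trees` the raw live
#'   individual count per species regardless of height
#' @slot emergence data.frame (replicate, birth_year) of sibirica recruits
#'   confirmed to have survived at least 10 years, birth year in sim-phase time
#' @slot aborted logical per replicate
#' @slot spec the [ScenarioSpec-class] that produced the result
#' @exportClass ScenarioResult
setClass("ScenarioResult",
  representation(
    series = "data.frame", emergence = "data.frame",
    aborted = "logical", spec = "ScenarioSpec"
  )
)

#' AmpliconReference: the two-variant diagnostic amplicon
#'
#' The 61-nt primer-trimmed mitochondrial nad4 fragment in its two allelic
#' states, differing at exactly one position (the locus's variable site 1433).
#' The base at that position assigns a read to the "L. sibirica" or the
#' "L. gmelinii" mitochondrial lineage.
#'
#' @slot sequences named character vector of the two variant sequences
#'   (names are the variant ids)
#' @slot position 1-based diagnostic position within the trimmed amplicon
#' @slot alleles named character vector mapping base -> variant id
#' @exportClass AmpliconReference
setClass("AmpliconReference",
  representation(sequences = "character", position = "integer",
                 alleles = "character")
)

setValidity("AmpliconReference", function(object) {
  msg <- character()
  if (length(object@sequences) != 2L)
    msg <- c(msg, "reference must hold exactly 2 variant sequences")
  w <- unique(nchar(object@sequences))
  if (length(w) != 1L || w != 61L)
    msg <- c(msg, "variant sequences must both be 61 nt")
  if (object@position < 1L || object@position > 61L)
    msg <- c(msg, "diagnostic position must lie within the amplicon")
  if (length(object@alleles) != 2L ||
      length(unique(names(object@alleles))) != 2L ||
      length(unique(object@alleles)) != 2L)
    msg <- c(msg, "allele map must pair 2 distinct bases with 2 distinct variants")
  if (length(msg)) msg else TRUE
})

#' SampleVariantProfile: per-sample variant counts and dominance call
#'
#' @slot sample_id character(1)
#' @slot depth_cm,age_calbp numeric(1), NA when unknown
#' @slot counts named integer (sibirica, gmelinii, unassigned)
#' @slot proportions named numeric over assigned reads (NA when none assigned)
#' @slot call one of "sibirica", "gmelinii", "mixed", "none"
#' @exportClass SampleVariantProfile
setClass("SampleVariantProfile",
  representation(
    sample_id = "character", depth_cm = "numeric", age_calbp = "numeric",
    counts = "integer", proportions = "numeric", call = "character"
  )
)

setValidity("SampleVariantProfile", function(object) {
  msg <- character()
  need <- c("sibirica", "gmelinii", "unassigned")
  if (!identical(sort(names(object@counts)), sort(need)))
    msg <- c(msg, "counts must be named sibirica, gmelinii, unassigned")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be >= 0")
  if (!object@call %in% c("sibirica", "gmelinii", "mixed", "none"))
    msg <- c(msg, "invalid dominance call")
  assigned <- sum(object@counts[c("sibirica", "gmelinii")])
  if (assigned > 0L && abs(sum(object@proportions) - 1) > 1e-9)
    msg <- c(msg, "proportions must sum to 1 over assigned reads")
  if (length(msg)) msg else TRUE
})

#' TaxaTable: samples x taxa counts with core metadata
#'
#' A `SummarizedExperiment` with taxa as rows (rowData column `genus`) and
#' sediment samples as columns (colData columns `depth_cm`, `age_calbp`,
#' `proxy` with proxy one of "DNA" or "pollen"), holding a single
#' non-negative `counts` assay.
#'
#' @exportClass TaxaTable
setClass("TaxaTable", contains = "SummarizedExperiment")

setValidity("TaxaTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "TaxaTable requires a 'counts' assay")
  else if (any(SummarizedExperiment::assay(object, "counts") < 0))
    msg <- c(msg, "counts must be >= 0")
  if (!"genus" %in% names(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain 'genus'")
  cd <- names(SummarizedExperiment::colData(object))
  if (!all(c("depth_cm", "age_calbp", "proxy") %in% cd))
    msg <- c(msg, "colData must contain depth_cm, age_calbp, proxy")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "taxon ids must be unique")
  if (length(msg)) msg else TRUE
})

#' OrdinationResult: first-component summary of a PCA
#'
#' @slot scores named numeric, PC1 score per sample (sign-oriented)
#' @slot var_explained numeric, proportion of variance per component
#' @slot loadings numeric matrix, taxa x components
#' @exportClass OrdinationResult
setClass("OrdinationResult",
  representation(scores = "numeric", var_explained = "numeric",
                 loadings = "matrix")
)

setValidity("OrdinationResult", function(object) {
  msg <- character()
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  v <- object@var_explained
  if (any(v < -1e-12 | v > 1 + 1e-12)) msg <- c(msg, "variance proportions must be in [0,1]")
  if (is.unsorted(rev(v), strictly = FALSE) && any(diff(v) > 1e-9))
    msg <- c(msg, "variance proportions must be non-increasing")
  if (length(msg)) msg else TRUE
})
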