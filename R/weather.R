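#' Derive annual weather indices from one year of monthly climate
#'
#' Converts 12 monthly temperature means and precipitation sums into the three
#' drivers the stand sub-models use: growing degree days above a 5 degC base
#' (monthly mean exceedance times days in month, non-leap convention), the
#' June-August mean temperature, and the annual precipitation sum.
#'
#' @param tmean numeric(12) monthly mean temperatures, degC
#' @param prec numeric(12) monthly precipitation sums, mm
#' @return list with elements `gdd` (degC day), `summer_temp` (degC),
#'   `annual_prec` (mm)
#' @export
deriveWeatherIndices <- function(tmean, prec) {
  stopifnot(length(tmean) == 12L, length(prec) == 12L)
  list(
    gdd = sum(pmax(0, tmean - 5) * .MONTH_DAYS),
    summer_temp = mean(tmean[6:8]),
    annual_prec = sum(prec)
  )
}

#' Saturating growing-degree-day response
#'
#' `T(gdd) = max(0, gdd - gdd_min) / (max(0, gdd - gdd_min) + gdd_halfsat)`,
#' in [0, 1); zero at or below the species threshold, one half when the excess
#' equals the half-saturation constant.
#'
#' @param gdd growing degree days, degC day
#' @param params a [SpeciesParams-class]
#' @return dimensionless response in [0, 1)
#' @export
gddResponse <- function(gdd, params) {
  ex <- max(0, gdd - params@gdd_min)
  ex / (ex + params@gdd_halfsat)
}
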