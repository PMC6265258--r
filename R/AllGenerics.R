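#' @rdname ClimateSeries-class
#' @param object,x a ClimateSeries
#' @export
setGeneric("seriesYears", function(x) standardGeneric("seriesYears"))

#' @rdname ClimateSeries-class
#' @export
setGeneric("tmeanMatrix", function(x) standardGeneric("tmeanMatrix"))

#' @rdname ClimateSeries-class
#' @export
setGeneric("precMatrix", function(x) standardGeneric("precMatrix"))

#' @rdname ClimateSeries-class
#' @export
setGeneric("seriesLabel", function(x) standardGeneric("seriesLabel"))

#' @rdname ClimateSeries-class
#' @param from,to first and last year of the window (inclusive)
#' @export
setGeneric("windowYears", function(x, from, to) standardGeneric("windowYears"))

setMethod("seriesYears", "ClimateSeries", function(x) x@years)
setMethod("tmeanMatrix", "ClimateSeries", function(x) x@tmean)
setMethod("precMatrix", "ClimateSeries", function(x) x@prec)
setMethod("seriesLabel", "ClimateSeries", function(x) x@label)

setMethod("windowYears", "ClimateSeries", function(x, from, to) {
  idx <- match(seq.int(from, to), x@years)
  if (anyNA(idx))
    stop(sprintf("series '%s' does not cover years %d..%d", x@label, from, to))
  ClimateSeries(seq.int(from, to),
    x@tmean[idx, , drop = FALSE], x@prec[idx, , drop = FALSE],
    label = x@label, metadata = x@metadata
  )
})

setMethod("show", "ClimateSeries", function(object) {
  yr <- range(object@years)
  cat(sprintf(
    "ClimateSeries '%s': %d years (%d..%d)\n  annual tmean %.2f degC, annual prec %.0f mm\n",
    object@label, length(object@years), yr[1], yr[2],
    mean(object@tmean), mean(rowSums(object@prec))
  ))
})

setMethod("show", "SpeciesParams", function(object) {
  cat(sprintf("SpeciesParams '%s'\n", object@species_id))
  nm <- setdiff(slotNames(object), "species_id")
  vals <- vapply(nm, function(s) slot(object, s), numeric(1))
  cat(paste0("  ", format(nm), " : ", format(vals, digits = 4), "\n"), sep = "")
})

setMethod("show", "PlotState", function(object) {
  cat(sprintf(
    "PlotState %.0f x %.0f m, year %d: %d trees (%d sibirica / %d gmelinii), %d seeds\n",
    object@Lx, object@Ly, object@year, nrow(object@trees),
    sum(object@trees$species == "sibirica"),
    sum(object@trees$species == "gmelinii"), nrow(object@seedbank)
  ))
})

setMethod("show", "SampleVariantProfile", function(object) {
  cat(sprintf(
    "SampleVariantProfile '%s': sibirica %d, gmelinii %d, unassigned %d -> %s\n",
    object@sample_id, object@counts[["sibirica"]], object@counts[["gmelinii"]],
    object@counts[["unassigned"]], object@call
  ))
})

setMethod("show", "ScenarioResult", function(object) {
  cat(sprintf(
    "ScenarioResult: %d replicate(s), %d recorded years, %d aborted\n",
    length(object@aborted),
    length(unique(object@series$year[object@series$phase == "simulation"])),
    sum(object@aborted)
  ))
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf(
    "OrdinationResult: %d samples, PC1 explains %.1f%% of variance\n",
    length(object@scores), 100 * object@var_explained[1]
  ))
})

#' Accessors for simulation results
#'
#' @param x a ScenarioResult
#' @return `standSeries` returns the long per-year data.frame; `emergenceEvents`
#'   the confirmed sibirica recruit birth years; `abortedReplicates` a logical
#'   vector.
#' @export
setGeneric("standSeries", function(x) standardGeneric("standSeries"))
#' @rdname standSeries
#' @export
setGeneric("emergenceEvents", function(x) standardGeneric("emergenceEvents"))
#' @rdname standSeries
#' @export
setGeneric("abortedReplicates", function(x) standardGeneric("abortedReplicates"))

setMethod("standSeries", "ScenarioResult", function(x) x@series)
setMethod("emergenceEvents", "ScenarioResult", function(x) x@emergence)
setMethod("abortedReplicates", "ScenarioResult", function(x) x@aborted)

#' Accessors for ordination results
#'
#' @param x an OrdinationResult
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))
#' @rdname pcScores
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))
#' @rdname pcScores
#' @export
setGeneric("taxonLoadings", function(x) standardGeneric("taxonLoadings"))

setMethod("pcScores", "OrdinationResult", function(x) x@scores)
setMethod("varExplained", "OrdinationResult", function(x) x@var_explained)
setMethod("taxonLoadings", "OrdinationResult", function(x) x@loadings)

#' Accessors for variant profiles
#'
#' @param x a SampleVariantProfile
#' @export
setGeneric("variantCounts", function(x) standardGeneric("variantCounts"))
#' @rdname variantCounts
#' @export
setGeneric("variantProportions", function(x) standardGeneric("variantProportions"))
#' @rdname variantCounts
#' @export
setGeneric("dominanceCall", function(x) standardGeneric("dominanceCall"))

setMethod("variantCounts", "SampleVariantProfile", function(x) x@counts)
setMethod("variantProportions", "SampleVariantProfile", function(x) x@proportions)
setMethod("dominanceCall", "SampleVariantProfile", function(x) x@call)
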