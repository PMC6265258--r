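#' Read a monthly climate table
#'
#' Reads a long-format CSV with one row per (year, month): columns `year`,
#' `month` (1-12), `tmean_c` (monthly mean temperature, degC) and `prec_mm`
#' (monthly precipitation sum, mm). Every year must carry all 12 months and
#' years must be contiguous. Values are preserved exactly.
#'
#' @param path CSV file path (UTF-8, header required)
#' @param dialect named character vector remapping non-standard column names,
#'   e.g. `c(tmean_c = "temp")` if the file calls the temperature column "temp"
#' @param label series label; defaults to the file name
#' @return a [ClimateSeries-class]
#' @export
loadClimateTable <- function(path, dialect = character(), label = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (std in names(dialect)) {
    i <- match(dialect[[std]], names(d))
    if (!is.na(i)) names(d)[i] <- std
  }
  need <- c("year", "month", "tmean_c", "prec_mm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("climate table missing column(s): ", paste(miss, collapse = ", "))
  if (any(d$prec_mm < 0)) {
    bad <- d[which(d$prec_mm < 0)[1], ]
    stop(sprintf("negative precipitation at year %d month %d", bad$year, bad$month))
  }
  years <- sort(unique(d$year))
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years are not contiguous: gap after ", years[which(diff(years) != 1L)[1]])
  tm <- matrix(NA_real_, length(years), 12L)
  pr <- matrix(NA_real_, length(years), 12L)
  ri <- match(d$year, years)
  if (any(d$month < 1 | d$month > 12)) stop("month values must be in 1..12")
  tm[cbind(ri, d$month)] <- d$tmean_c
  pr[cbind(ri, d$month)] <- d$prec_mm
  if (anyNA(tm)) {
    hole <- which(is.na(tm), arr.ind = TRUE)[1, ]
    stop(sprintf("missing month: year %d, month %d", years[hole[1]], hole[2]))
  }
  if (is.null(label)) label <- basename(path)
  ClimateSeries(years, tm, pr, label = label)
}

#' Write a ClimateSeries as a monthly climate table
#'
#' Writes the same long CSV dialect [loadClimateTable()] reads, and optionally
#' a JSON sidecar with the series metadata (splice recipe, seed and chosen
#' window start-years when present) for exact replay.
#'
#' @param x a [ClimateSeries-class]
#' @param path output CSV path
#' @param sidecar logical; write `<path>.json` with the series metadata?
#' @return `path`, invisibly
#' @export
writeClimateTable <- function(x, path, sidecar = FALSE) {
  stopifnot(is(x, "ClimateSeries"))
  n <- length(x@years)
  d <- data.frame(
    year = rep(x@years, each = 12L),
    month = rep(1:12, times = n),
    # 17 significant digits: doubles survive the text round-trip bit-exactly
    tmean_c = sprintf("%.17g", as.vector(t(x@tmean))),
    prec_mm = sprintf("%.17g", as.vector(t(x@prec)))
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- c(list(label = x@label), x@metadata)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
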