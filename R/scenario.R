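#' Run a simulation scenario
#'
#' Each replicate starts from an empty plot, runs `stab_years` stabilisation
#' steps in which whole weather years are resampled uniformly (with
#' replacement) from the first 30 forcing years and the stabilisation species
#' receive seed rain, and then steps once per forcing year with the simulation
#' species introduced. Stand density (trees at or above the height cutoff,
#' per ha), composition, seed-bank size and summer temperature are recorded
#' per year of the simulation phase (and optionally of the stabilisation
#' phase).
#'
#' Sibirica establishment events are tracked for the emergence summary: a
#' recruit is confirmed when it reaches age 10, and its birth year (confirmed
#' year minus 10) is recorded.
#'
#' Replicates whose live-tree count exceeds `abort_cap` are flagged aborted
#' and stop stepping; their partial series is kept.
#'
#' @param spec a [ScenarioSpec-class]
#' @param params named list of [SpeciesParams-class]; defaults to
#'   [defaultSpeciesParams()]
#' @param record_stab logical, also record the stabilisation phase?
#' @return a [ScenarioResult-class]
#' @export
runScenario <- function(spec, params = defaultSpeciesParams(),
                        record_stab = FALSE) {
  stopifnot(is(spec, "ScenarioSpec"))
  fyears <- seriesYears(spec@forcing)
  n_sim <- length(fyears)
  if (n_sim < 1L) stop("forcing must cover at least one year")
  tm <- tmeanMatrix(spec@forcing)
  pr <- precMatrix(spec@forcing)
  wx <- lapply(seq_len(n_sim), function(i) deriveWeatherIndices(tm[i, ], pr[i, ]))
  n_pool <- min(30L, n_sim)

  set.seed(spec@seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, spec@replicates)

  all_series <- vector("list", spec@replicates)
  all_emerg <- vector("list", spec@replicates)
  aborted <- logical(spec@replicates)

  for (r in seq_len(spec@replicates)) {
    set.seed(rep_seeds[r])
    plot <- emptyPlot(spec@Lx, spec@Ly, year = fyears[1] - spec@stab_years - 1L)
    n_rec <- n_sim + if (record_stab) spec@stab_years else 0L
    rec <- matrix(NA_real_, n_rec, 8L) # dens x2, seedbank x2, trees x2, summer, year
    phase <- character(n_rec)
    births <- numeric(0)
    k <- 0L

    record <- function(plot, w, yr, ph) {
      dens <- standDensity(plot, spec@density_height_cutoff)
      c(dens[["sibirica"]], dens[["gmelinii"]],
        sum(plot@seedbank$species == "sibirica"),
        sum(plot@seedbank$species == "gmelinii"),
        sum(plot@trees$species == "sibirica"),
        sum(plot@trees$species == "gmelinii"), w$summer_temp, yr)
    }

    run_phase <- function(n_steps, widx, intro, years, ph, log_it) {
      for (i in seq_len(n_steps)) {
        w <- wx[[widx[i]]]
        plot <<- stepYear(plot, w, params, intro, spec@introduction_rate,
                          use_precip = spec@use_precip,
                          precip_ref = spec@precip_ref)
        confirmed <- plot@trees$species == "sibirica" & plot@trees$age == 10
        if (any(confirmed)) births <<- c(births, rep(years[i] - 10, sum(confirmed)))
        if (log_it) {
          k <<- k + 1L
          rec[k, ] <<- record(plot, w, years[i], ph)
          phase[k] <<- ph
        }
        if (nrow(plot@trees) > spec@abort_cap) return(TRUE)
      }
      FALSE
    }

    ab <- FALSE
    if (spec@stab_years > 0L) {
      stab_idx <- sample.int(n_pool, spec@stab_years, replace = TRUE)
      stab_years_lab <- seq.int(fyears[1] - spec@stab_years, fyears[1] - 1L)
      ab <- run_phase(spec@stab_years, stab_idx, spec@stab_species,
                      stab_years_lab, "stabilisation", record_stab)
    }
    if (!ab)
      ab <- run_phase(n_sim, seq_len(n_sim), spec@sim_species, fyears,
                      "simulation", TRUE)
    aborted[r] <- ab

    rec <- rec[seq_len(k), , drop = FALSE]
    total <- rec[, 1] + rec[, 2]
    all_series[[r]] <- data.frame(
      replicate = rep(r, 2L * k), phase = phase[seq_len(k)], year = rec[, 8],
      species = rep(c("sibirica", "gmelinii"), each = k),
      density = c(rec[, 1], rec[, 2]),
      fraction = c(ifelse(total > 0, rec[, 1] / total, NA_real_),
                   ifelse(total > 0, rec[, 2] / total, NA_real_)),
      seedbank = c(rec[, 3], rec[, 4]),
      trees = c(rec[, 5], rec[, 6]),
      summer_temp = rec[, 7], row.names = NULL
    )
    all_emerg[[r]] <- if (length(births))
      data.frame(replicate = r, birth_year = births) else
      data.frame(replicate = integer(), birth_year = numeric())
  }

  new("ScenarioResult",
    series = do.call(rbind, all_series),
    emergence = do.call(rbind, all_emerg),
    aborted = aborted, spec = spec
  )
}
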