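.BOTH <- c("sibirica", "gmelinii")

.species_set <- function(x) {
  if (identical(x, "both")) .BOTH else x
}

#' Default study sites
#'
#' Three sites spanning the treeline ecotone, defined relative to the master
#' grid cell by an overlap-period temperature offset (degC) and precipitation
#' factor: the southern taiga site CH06 (warm), the northern ecotone site
#' CH12, and the tundra site "site4" north of the treeline (cold).
#'
#' @return data.frame with columns label, t_offset, p_factor
#' @export
defaultSites <- function() {
  data.frame(
    label = c("CH06", "CH12", "site4"),
    t_offset = c(1.5, -1.3, -1.8),
    p_factor = c(1.10, 0.95, 0.90)
  )
}

#' Derive per-site forcings from a master series
#'
#' Applies [siteAdjustSeries()] for each site row, with site overlap means
#' defined as the master overlap means shifted by `t_offset` and scaled by
#' `p_factor`.
#'
#' @param master master [ClimateSeries-class]
#' @param sites data.frame as [defaultSites()]
#' @param overlap_from,overlap_to overlap span for the means
#' @return named list of [ClimateSeries-class]
#' @export
siteForcings <- function(master, sites = defaultSites(),
                         overlap_from = 1934, overlap_to = 2013) {
  mm <- overlapMeans(master, overlap_from, overlap_to)
  out <- lapply(seq_len(nrow(sites)), function(i) {
    sm <- c(tmean_c = mm[["tmean_c"]] + sites$t_offset[i],
            prec_mm_yr = mm[["prec_mm_yr"]] * sites$p_factor[i])
    siteAdjustSeries(master, mm, sm, label = sites$label[i])
  })
  names(out) <- sites$label
  out
}

#' Run the 3 x 3 seed-introduction matrix at one or more sites
#'
#' For every combination of stabilisation-phase and simulation-phase seed
#' introduction (sibirica only, gmelinii only, both), runs the scenario and
#' summarises, per replicate, the mean stand density and composition per
#' species over the final `final_window` simulated years. Replicates whose
#' tree count exceeds the abort cap are flagged `aborted`; other cells are
#' unaffected.
#'
#' @param forcings named list of [ClimateSeries-class], one per site
#' @param params species parameters, default [defaultSpeciesParams()]
#' @param stab_years stabilisation length, yr
#' @param replicates replicates per cell
#' @param seed root seed
#' @param Lx,Ly plot extent, m
#' @param introduction_rate seeds/ha/yr per introduced species
#' @param final_window years averaged for the cell summary (default 100,
#'   truncated to the simulation length)
#' @param density_height_cutoff density cutoff, m
#' @param abort_cap replicate abort threshold, trees
#' @return data.frame with one row per site x cell x replicate x species
#' @export
runSpatialMatrix <- function(forcings, params = defaultSpeciesParams(),
                             stab_years = 1000, replicates = 3, seed = 1L,
                             Lx = 50, Ly = 50, introduction_rate = 100,
                             final_window = 100, density_height_cutoff = 1.3,
                             abort_cap = 1e6) {
  combos <- expand.grid(stab = c("sibirica", "gmelinii", "both"),
                        sim = c("sibirica", "gmelinii", "both"),
                        stringsAsFactors = FALSE)
  out <- list()
  cell_seed <- seed
  for (site in names(forcings)) {
    for (i in seq_len(nrow(combos))) {
      cell_seed <- cell_seed + 1L
      sc <- ScenarioSpec(
        forcing = forcings[[site]], stab_years = stab_years,
        stab_species = .species_set(combos$stab[i]),
        sim_species = .species_set(combos$sim[i]),
        introduction_rate = introduction_rate, replicates = replicates,
        seed = cell_seed, Lx = Lx, Ly = Ly,
        density_height_cutoff = density_height_cutoff, abort_cap = abort_cap
      )
      res <- runScenario(sc, params)
      ser <- standSeries(res)
      ser <- ser[ser$phase == "simulation", ]
      if (nrow(ser)) {
        last <- max(ser$year) - min(final_window, length(unique(ser$year))) + 1
        ser <- ser[ser$year >= last, ]
      }
      agg <- expand.grid(replicate = seq_len(replicates),
                         species = c("sibirica", "gmelinii"),
                         stringsAsFactors = FALSE)
      stat <- function(col) vapply(seq_len(nrow(agg)), function(j) {
        v <- ser[[col]][ser$replicate == agg$replicate[j] &
                        ser$species == agg$species[j]]
        if (length(v)) mean(v, na.rm = TRUE) else NA_real_
      }, numeric(1))
      agg$density <- stat("density")
      agg$fraction <- stat("fraction")
      agg$site <- site
      agg$stab_species <- combos$stab[i]
      agg$sim_species <- combos$sim[i]
      agg$aborted <- abortedReplicates(res)[agg$replicate]
      out[[length(out) + 1L]] <- agg
    }
  }
  res <- do.call(rbind, out)
  res$fraction[is.nan(res$fraction)] <- NA_real_
  res[, c("site", "stab_species", "sim_species", "replicate", "species",
          "density", "fraction", "aborted")]
}

#' Summarise sibirica emergence for one scenario result
#'
#' Dominance onset is the first simulation year in which gmelinii makes up at
#' least `dom_frac` of the stand density and total density is at least
#' `min_total` trees/ha. The emergence event is the first confirmed sibirica
#' recruit (survived >= 10 yr) born after that onset; the summary reports the
#' total stand density in its birth year.
#'
#' @param result a [ScenarioResult-class]
#' @param dom_frac gmelinii dominance fraction defining the onset (default 0.9)
#' @param min_total minimum total density at onset, trees/ha (default 10)
#' @return data.frame with one row per replicate: onset_year, emergence_year,
#'   emergence_density (NA when no emergence)
#' @export
emergenceSummary <- function(result, dom_frac = 0.9, min_total = 10) {
  ser <- standSeries(result)
  ser <- ser[ser$phase == "simulation", ]
  em <- emergenceEvents(result)
  reps <- sort(unique(ser$replicate))
  rows <- lapply(reps, function(r) {
    s <- ser[ser$replicate == r, ]
    wide <- merge(
      s[s$species == "sibirica", c("year", "density")],
      s[s$species == "gmelinii", c("year", "density")],
      by = "year", suffixes = c("_sib", "_gme")
    )
    wide <- wide[order(wide$year), ]
    total <- wide$density_sib + wide$density_gme
    onset_i <- which(total >= min_total &
                     wide$density_gme / pmax(total, 1e-12) >= dom_frac)[1]
    onset <- if (is.na(onset_i)) NA_real_ else wide$year[onset_i]
    births <- sort(em$birth_year[em$replicate == r])
    births <- births[births >= min(wide$year)]
    if (!is.na(onset)) births <- births[births > onset]
    if (is.na(onset) || !length(births)) {
      return(data.frame(replicate = r, onset_year = onset,
                        emergence_year = NA_real_,
                        emergence_density = NA_real_))
    }
    ey <- births[1]
    data.frame(replicate = r, onset_year = onset, emergence_year = ey,
               emergence_density = total[match(ey, wide$year)])
  })
  do.call(rbind, rows)
}

#' Run the temporal experiment at one or more sites
#'
#' For each site forcing, runs a mixed-introduction scenario (both species
#' introduced in both phases, so new introductions can follow die-out events)
#' and computes the sibirica emergence summary.
#'
#' @param forcings named list of per-site [ClimateSeries-class]
#' @param params species parameters
#' @param truncate_years keep only the final `truncate_years` forcing years
#'   (NULL = full span); default 2000, the reduced desk scale
#' @param stab_years stabilisation length, yr
#' @param replicates replicates per site
#' @param seed root seed
#' @param Lx,Ly plot extent, m (default 50 x 50 m = 0.25 ha)
#' @param introduction_rate seeds/ha/yr per species
#' @param density_height_cutoff density cutoff, m
#' @return list with `results` (named list of [ScenarioResult-class]) and
#'   `emergence` (data.frame site x replicate summary)
#' @export
runTemporalExperiment <- function(forcings, params = defaultSpeciesParams(),
                                  truncate_years = 2000, stab_years = 1000,
                                  replicates = 3, seed = 1L, Lx = 50, Ly = 50,
                                  introduction_rate = 100,
                                  density_height_cutoff = 1.3) {
  results <- list()
  summaries <- list()
  site_seed <- seed
  if (replicates < 1) {
    return(list(results = list(),
                emergence = data.frame(site = character(),
                                       replicate = integer(),
                                       onset_year = numeric(),
                                       emergence_year = numeric(),
                                       emergence_density = numeric())))
  }
  for (site in names(forcings)) {
    site_seed <- site_seed + 1L
    f <- forcings[[site]]
    if (!is.null(truncate_years)) {
      yrs <- seriesYears(f)
      if (length(yrs) > truncate_years)
        f <- windowYears(f, yrs[length(yrs)] - truncate_years + 1L,
                         yrs[length(yrs)])
    }
    sc <- ScenarioSpec(
      forcing = f, stab_years = stab_years, stab_species = .BOTH,
      sim_species = .BOTH, introduction_rate = introduction_rate,
      replicates = replicates, seed = site_seed, Lx = Lx, Ly = Ly,
      density_height_cutoff = density_height_cutoff
    )
    res <- runScenario(sc, params)
    es <- emergenceSummary(res)
    es$site <- site
    results[[site]] <- res
    summaries[[site]] <- es[, c("site", "replicate", "onset_year",
                                "emergence_year", "emergence_density")]
  }
  list(results = results, emergence = do.call(rbind, summaries))
}

#' Write experiment outputs with a replayable manifest
#'
#' Writes each result data.frame as a TSV (atomically: to a temporary file in
#' the target directory, then renamed) plus a JSON manifest recording the
#' config snapshot, package version, seeds, timestamps and MD5 checksums of
#' the written files. Errors before any partial write if the directory is not
#' writable.
#'
#' @param results named list of data.frames
#' @param outdir output directory (created if absent)
#' @param config arbitrary config snapshot stored in the manifest
#' @param seed the root seed used
#' @return invisible character vector of written file paths
#' @export
writeOutputs <- function(results, outdir, config = list(), seed = NA_integer_) {
  stopifnot(is.list(results), all(nzchar(names(results))))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2L) != 0L)
    stop("output directory not writable: ", outdir)
  paths <- character(0)
  for (nm in names(results)) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    tmp <- tempfile(tmpdir = outdir, fileext = ".tsv.tmp")
    utils::write.table(results[[nm]], tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.rename(tmp, path)
    paths <- c(paths, path)
  }
  manifest <- list(
    package = "larch2s",
    version = as.character(utils::packageVersion("larch2s")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config,
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) list(md5 = unname(tools::md5sum(p))))
  )
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, mpath))
}

#' Verify a run manifest against its files
#'
#' Recomputes MD5 checksums of the files the manifest lists and errors on any
#' mismatch or missing file (integrity gate for replays).
#'
#' @param manifest_path path to a manifest.json written by [writeOutputs()]
#' @return TRUE, invisibly, when all checksums match
#' @export
verifyManifest <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  for (nm in names(m$files)) {
    p <- file.path(dir, nm)
    if (!file.exists(p)) stop("manifest file missing: ", nm)
    md5 <- unname(tools::md5sum(p))
    if (!identical(md5, m$files[[nm]]$md5))
      stop("checksum mismatch for ", nm)
  }
  invisible(TRUE)
}
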