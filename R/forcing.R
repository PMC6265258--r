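#' Assemble the master forcing by bootstrap-splicing recent climate windows
#'
#' Covers the pre-overlap span (`target_start..splice_end`) with fixed-length
#' blocks drawn uniformly at random (with replacement, seeded) from the recent
#' ("real") series, then appends the overlap years verbatim from the real
#' series. Each spliced block is adjusted so that its pooled window mean
#' matches the corresponding window of the simulated paleo series: an additive
#' offset on all monthly temperatures, and (by default) a single multiplicative
#' factor on all monthly precipitation values, floored at `prec_floor`.
#'
#' When the pre-overlap span is not a multiple of the window length, the final
#' block is truncated to the remaining years and adjusted against the same
#' truncated span of the simulated series.
#'
#' @param real recent [ClimateSeries-class]; must cover the recipe's overlap
#' @param simulated paleo [ClimateSeries-class]; must cover
#'   `target_start..overlap_end`
#' @param recipe a [ForcingRecipe-class]
#' @return a [ClimateSeries-class] spanning `target_start..overlap_end`, with
#'   `metadata$recipe` and `metadata$window_starts` recording the draw
#' @export
assembleMasterForcing <- function(real, simulated, recipe = ForcingRecipe()) {
  stopifnot(is(real, "ClimateSeries"), is(simulated, "ClimateSeries"),
            is(recipe, "ForcingRecipe"))
  wl <- recipe@window_len
  ov <- seq.int(recipe@overlap_start, recipe@overlap_end)
  if (!all(ov %in% real@years))
    stop("real series does not cover the overlap years ",
         recipe@overlap_start, "..", recipe@overlap_end)
  if (recipe@target_start < simulated@years[1] ||
      recipe@overlap_end > simulated@years[length(simulated@years)])
    stop("simulated series does not cover the target span ",
         recipe@target_start, "..", recipe@overlap_end)
  n_real_ov <- length(ov)
  if (n_real_ov < wl)
    stop("real overlap span shorter than one window (", wl, " years)")

  pre_years <- seq.int(recipe@target_start, recipe@splice_end)
  n_pre <- length(pre_years)
  n_blocks <- ceiling(n_pre / wl)
  admissible <- ov[seq_len(n_real_ov - wl + 1L)] # window start years in real

  set.seed(recipe@rng_seed)
  starts <- sample(admissible, n_blocks, replace = TRUE)

  tm <- matrix(NA_real_, n_pre, 12L)
  pr <- matrix(NA_real_, n_pre, 12L)
  ridx <- function(s, len) match(seq.int(s, s + len - 1L), real@years)
  sidx <- function(s, len) match(seq.int(s, s + len - 1L), simulated@years)

  pos <- 1L
  for (b in seq_len(n_blocks)) {
    len <- min(wl, n_pre - pos + 1L)
    ri <- ridx(starts[b], len)
    si <- sidx(pre_years[pos], len)
    bt <- real@tmean[ri, , drop = FALSE]
    bp <- real@prec[ri, , drop = FALSE]
    st <- simulated@tmean[si, , drop = FALSE]
    sp <- simulated@prec[si, , drop = FALSE]
    # pooled ("total") window means over all months
    bt <- bt + (mean(st) - mean(bt))
    if (recipe@prec_adjust == "multiplicative") {
      mb <- mean(bp)
      ms <- mean(sp)
      if (mb == 0 && ms > 0)
        stop("window starting ", starts[b],
             " has zero real precipitation; multiplicative adjustment undefined")
      bp <- if (mb > 0) bp * (ms / mb) else bp
    } else {
      bp <- bp + (mean(sp) - mean(bp))
    }
    bp <- pmax(bp, recipe@prec_floor)
    tm[pos:(pos + len - 1L), ] <- bt
    pr[pos:(pos + len - 1L), ] <- bp
    pos <- pos + len
  }

  ro <- match(ov, real@years)
  out_years <- c(pre_years, ov)
  out_t <- rbind(tm, real@tmean[ro, , drop = FALSE])
  out_p <- rbind(pr, real@prec[ro, , drop = FALSE])
  ClimateSeries(out_years, out_t, out_p,
    label = paste0(real@label, "+spliced"),
    metadata = list(
      recipe = list(
        window_len = wl, target_start = recipe@target_start,
        splice_end = recipe@splice_end, overlap_start = recipe@overlap_start,
        overlap_end = recipe@overlap_end, temp_adjust = recipe@temp_adjust,
        prec_adjust = recipe@prec_adjust, prec_floor = recipe@prec_floor,
        rng_seed = recipe@rng_seed
      ),
      window_starts = starts
    )
  )
}

#' Overlap-period means of a climate series
#'
#' @param x a [ClimateSeries-class]
#' @param from,to overlap span (inclusive); defaults 1934 and 2013
#' @return named numeric: `tmean_c` (all-month mean, degC) and `prec_mm_yr`
#'   (mean annual precipitation sum, mm/yr)
#' @export
overlapMeans <- function(x, from = 1934, to = 2013) {
  w <- windowYears(x, from, to)
  c(tmean_c = mean(w@tmean), prec_mm_yr = mean(rowSums(w@prec)))
}

#' Derive a site-specific forcing from the master series
#'
#' Shifts every monthly temperature additively by the site-minus-master mean
#' difference over the overlap years, and scales every monthly precipitation
#' value by the site/master overlap-mean ratio (floored at `prec_floor`). The
#' output spans the same years as the master.
#'
#' @param master master [ClimateSeries-class]
#' @param master_overlap_means,site_overlap_means named numerics as returned by
#'   [overlapMeans()] (`tmean_c`, `prec_mm_yr`), computed over the overlap only
#' @param prec_floor lower bound for scaled precipitation, mm
#' @param label label of the derived series
#' @return a [ClimateSeries-class]
#' @export
siteAdjustSeries <- function(master, master_overlap_means, site_overlap_means,
                             prec_floor = 0, label = "site") {
  stopifnot(is(master, "ClimateSeries"))
  dt <- site_overlap_means[["tmean_c"]] - master_overlap_means[["tmean_c"]]
  mp <- master_overlap_means[["prec_mm_yr"]]
  sp <- site_overlap_means[["prec_mm_yr"]]
  if (mp == 0 && sp != 0)
    stop("master overlap precipitation mean is 0; precipitation ratio undefined")
  fac <- if (mp == 0) 1 else sp / mp
  ClimateSeries(master@years, master@tmean + dt,
    pmax(master@prec * fac, prec_floor),
    label = label,
    metadata = c(master@metadata,
                 list(site_adjust = list(dt = dt, prec_factor = fac)))
  )
}
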