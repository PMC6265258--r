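.empty_trees <- function() {
  data.frame(species = character(), x = numeric(), y = numeric(),
             height = numeric(), age = numeric())
}

.empty_seeds <- function() {
  data.frame(species = character(), x = numeric(), y = numeric(),
             age = numeric())
}

#' Create an empty plot
#'
#' @param Lx,Ly plot extent, m (default 100 x 100 m = 1 ha)
#' @param year starting year
#' @return a [PlotState-class] with no trees and no seeds
#' @export
emptyPlot <- function(Lx = 100, Ly = 100, year = 0L) {
  new("PlotState", Lx = Lx, Ly = Ly, trees = .empty_trees(),
      seedbank = .empty_seeds(), year = as.integer(year))
}

#' Neighbourhood competition index
#'
#' For each query point, the sum over all trees within `radius` of
#' `height_j / max(dist_j, dist_floor)`; trees at exactly the query point are
#' excluded, so a tree queried at its own coordinates does not compete with
#' itself. Deterministic given the plot.
#'
#' @param plot a [PlotState-class]
#' @param x,y query coordinates, m (vectors of equal length)
#' @param radius neighbourhood radius, m (default 10)
#' @param dist_floor distance floor avoiding singularities, m (default 0.5)
#' @return numeric vector of competition indices, one per query point
#' @export
competitionIndex <- function(plot, x, y, radius = 10, dist_floor = 0.5) {
  if (radius <= 0) stop("radius must be > 0")
  tr <- plot@trees
  cpp_nci(tr$x, tr$y, tr$height, x, y, radius, dist_floor)
}

#' Stand density per species
#'
#' Counts trees at or above `height_cutoff` per species, divided by the plot
#' area in hectares.
#'
#' @param plot a [PlotState-class]
#' @param height_cutoff counting cutoff, m (default 1.3, breast height)
#' @return named numeric (sibirica, gmelinii), trees/ha
#' @export
standDensity <- function(plot, height_cutoff = 1.3) {
  stopifnot(height_cutoff >= 0)
  area_ha <- plot@Lx * plot@Ly / 1e4
  tr <- plot@trees
  qual <- tr$height >= height_cutoff
  c(
    sibirica = sum(qual & tr$species == "sibirica") / area_ha,
    gmelinii = sum(qual & tr$species == "gmelinii") / area_ha
  )
}
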