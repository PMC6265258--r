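#' Default taxon response set for the coupled table generator
#'
#' A small treeline-to-tundra community: each taxon has a genus, a baseline
#' log-abundance (`intercept`) and a response (`slope`) to the latent
#' vegetation-turnover gradient, with forest taxa (Larix, Alnus) responding
#' positively and tundra taxa negatively.
#'
#' @return data.frame with columns taxon, genus, intercept, slope
#' @export
defaultTaxaResponses <- function() {
  data.frame(
    taxon = c("Larix gmelinii", "Alnus viridis", "Betula nana",
              "Betula pendula", "Salix polaris", "Vaccinium vitis-idaea",
              "Dryas octopetala", "Poaceae undiff.", "Cyperaceae undiff.",
              "Artemisia borealis"),
    genus = c("Larix", "Alnus", "Betula", "Betula", "Salix", "Vaccinium",
              "Dryas", "Poaceae", "Cyperaceae", "Artemisia"),
    intercept = c(1.2, 0.2, 1.0, 0.1, 0.6, 0.2, -0.4, 0.5, 0.6, -0.6),
    slope = c(1.4, 0.8, 0.1, 0.2, -0.4, -0.3, -1.0, -0.5, -0.7, -1.1)
  )
}

#' Generate coupled DNA and pollen taxa tables with a known latent gradient
#'
#' Per-sample taxon probabilities are a softmax of `intercept + slope * g_i`
#' over taxa, where `g` is the shared latent vegetation-turnover gradient.
#' Each proxy draws counts multinomially at its own depth, after adding
#' independent proxy-specific jitter to the taxon responses (the same jitter
#' for all samples of a proxy, emulating taxon-specific recording biases).
#'
#' @param n_samples number of sediment samples (default 20)
#' @param responses data.frame as [defaultTaxaResponses()]
#' @param gradient numeric latent gradient per sample; default a smooth
#'   decline from 1.5 to -1.5 (forest to tundra downcore-to-top reversed)
#' @param jitter_sd SD of the per-proxy slope/intercept jitter (default 0.15)
#' @param depth_dna,depth_pollen counts per sample for each proxy (defaults
#'   5000 reads and 300 pollen grains)
#' @param seed integer seed
#' @return list with `dna` and `pollen` ([TaxaTable-class]) and `gradient`
#'   (named numeric truth)
#' @export
genCoupledTaxaTables <- function(n_samples = 20,
                                 responses = defaultTaxaResponses(),
                                 gradient = NULL, jitter_sd = 0.15,
                                 depth_dna = 5000, depth_pollen = 300,
                                 seed = 1L) {
  if (n_samples < 3) stop("need at least 3 samples")
  stopifnot(depth_dna >= 1, depth_pollen >= 1)
  set.seed(seed)
  if (is.null(gradient)) gradient <- seq(1.5, -1.5, length.out = n_samples)
  stopifnot(all(is.finite(gradient)), length(gradient) == n_samples)
  ids <- sprintf("S%02d", seq_len(n_samples))
  names(gradient) <- ids
  ages <- seq(0, 7000, length.out = n_samples)
  depths <- seq(0, 120, length.out = n_samples)

  draw <- function(depth, proxy) {
    slope <- responses$slope +
      if (jitter_sd > 0) stats::rnorm(nrow(responses), 0, jitter_sd) else 0
    inter <- responses$intercept +
      if (jitter_sd > 0) stats::rnorm(nrow(responses), 0, jitter_sd) else 0
    counts <- sapply(seq_len(n_samples), function(i) {
      eta <- inter + slope * gradient[i]
      p <- exp(eta - max(eta))
      stats::rmultinom(1, size = depth, prob = p / sum(p))[, 1]
    })
    rownames(counts) <- responses$taxon
    colnames(counts) <- ids
    TaxaTable(counts, genus = responses$genus, depth_cm = depths,
              age_calbp = ages, proxy = proxy)
  }

  list(dna = draw(depth_dna, "DNA"), pollen = draw(depth_pollen, "pollen"),
       gradient = gradient)
}
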