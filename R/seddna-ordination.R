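#' Construct a TaxaTable
#'
#' @param counts numeric matrix, taxa (rows) x samples (columns), non-negative
#' @param genus character vector of genus per taxon; defaults to the first
#'   whitespace-separated word of the taxon name
#' @param depth_cm,age_calbp numeric per-sample metadata (NA allowed)
#' @param proxy per-sample proxy, "DNA" or "pollen" (recycled)
#' @return a [TaxaTable-class]
#' @export
TaxaTable <- function(counts, genus = NULL, depth_cm = NA_real_,
                      age_calbp = NA_real_, proxy = "DNA") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have taxon rownames")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  if (is.null(genus)) genus <- sub("\\s.*$", "", rownames(counts))
  ns <- ncol(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(genus = genus),
    colData = S4Vectors::DataFrame(
      depth_cm = rep_len(depth_cm, ns),
      age_calbp = rep_len(age_calbp, ns),
      proxy = rep_len(proxy, ns),
      row.names = colnames(counts)
    )
  )
  new("TaxaTable", se)
}

#' Read a taxa table from TSV
#'
#' Samples as rows, taxa as columns; metadata columns `sample_id`, `depth_cm`,
#' `age_calbp`, `proxy` precede the taxon columns.
#'
#' @param path TSV path
#' @param genus optional named character vector mapping taxon -> genus;
#'   defaults to the first word of each taxon name
#' @return a [TaxaTable-class]
#' @export
readTaxaTable <- function(path, genus = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("sample_id", "depth_cm", "age_calbp", "proxy")
  miss <- setdiff(meta, names(d))
  if (length(miss)) stop("taxa table missing column(s): ", paste(miss, collapse = ", "))
  taxa <- setdiff(names(d), meta)
  counts <- t(as.matrix(d[, taxa, drop = FALSE]))
  colnames(counts) <- d$sample_id
  g <- if (is.null(genus)) NULL else unname(genus[taxa])
  TaxaTable(counts, genus = g, depth_cm = d$depth_cm,
            age_calbp = d$age_calbp, proxy = d$proxy)
}

#' Write a taxa table as TSV
#'
#' @param x a [TaxaTable-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeTaxaTable <- function(x, path) {
  counts <- SummarizedExperiment::assay(x, "counts")
  cd <- SummarizedExperiment::colData(x)
  d <- data.frame(
    sample_id = colnames(counts), depth_cm = cd$depth_cm,
    age_calbp = cd$age_calbp, proxy = cd$proxy,
    t(counts), check.names = FALSE
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Prepare a taxa table for ordination
#'
#' Aggregates counts to genus level, converts to per-sample percentages,
#' retains only dominant genera present at a minimum of `min_pct` percent in
#' at least `min_samples` samples, and square-root transforms the retained
#' percentage matrix.
#'
#' @param x a [TaxaTable-class]
#' @param min_pct abundance threshold, percent (default 0.5)
#' @param min_samples number of samples that must reach `min_pct` (default 2)
#' @return numeric matrix, samples (rows) x retained genera (columns), of
#'   square-rooted percentages
#' @export
prepareTaxaTable <- function(x, min_pct = 0.5, min_samples = 2) {
  stopifnot(is(x, "TaxaTable"))
  counts <- SummarizedExperiment::assay(x, "counts")
  genus <- SummarizedExperiment::rowData(x)$genus
  agg <- rowsum(counts, genus) # genera x samples
  tot <- colSums(agg)
  if (any(tot == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(agg)[tot == 0], collapse = ", "))
  pct <- sweep(agg, 2, tot, "/") * 100
  keep <- rowSums(pct >= min_pct) >= min_samples
  if (!any(keep)) stop("no taxa pass the abundance filter")
  sqrt(t(pct[keep, , drop = FALSE]))
}

#' First principal component of a prepared taxa matrix
#'
#' PCA on the column-centred (not scaled) matrix via singular value
#' decomposition. The PC1 sign is oriented so that `orient_taxon`'s loading is
#' non-negative ("more larch" points the same way across proxies); when that
#' taxon is absent the largest-magnitude PC1 loading is made positive.
#'
#' @param mat samples x taxa matrix, e.g. from [prepareTaxaTable()]
#' @param orient_taxon taxon fixing the PC1 sign (default "Larix")
#' @param scale. logical, scale columns to unit variance? (default FALSE)
#' @return an [OrdinationResult-class]
#' @export
pcaFirstComponent <- function(mat, orient_taxon = "Larix", scale. = FALSE) {
  if (nrow(mat) < 3) stop("need at least 3 samples")
  if (ncol(mat) < 2) stop("need at least 2 taxa")
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  flip <- if (orient_taxon %in% rownames(pc$rotation)) {
    pc$rotation[orient_taxon, 1] < 0
  } else {
    pc$rotation[which.max(abs(pc$rotation[, 1])), 1] < 0
  }
  if (flip) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  new("OrdinationResult",
    scores = stats::setNames(pc$x[, 1], rownames(mat)),
    var_explained = ve, loadings = pc$rotation
  )
}

#' Compare DNA and pollen PC1 series
#'
#' Matches samples by name, computes Pearson and Spearman correlations of the
#' (sign-oriented) PC1 scores, and returns the paired stratigraphic series.
#'
#' @param dna,pollen [OrdinationResult-class] objects or named numeric score
#'   vectors
#' @return list with `pearson`, `spearman` and `paired` (data.frame sample,
#'   dna, pollen)
#' @export
compareProxies <- function(dna, pollen) {
  sd1 <- if (is(dna, "OrdinationResult")) pcScores(dna) else dna
  sd2 <- if (is(pollen, "OrdinationResult")) pcScores(pollen) else pollen
  common <- intersect(names(sd1), names(sd2))
  if (length(common) < 3) stop("need at least 3 matched sample pairs")
  a <- sd1[common]
  b <- sd2[common]
  list(
    pearson = stats::cor(a, b, method = "pearson"),
    spearman = stats::cor(a, b, method = "spearman"),
    paired = data.frame(sample = common, dna = unname(a), pollen = unname(b))
  )
}
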