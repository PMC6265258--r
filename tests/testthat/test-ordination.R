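toyTable <- function(counts, genus = NULL, proxy = "DNA") {
  TaxaTable(counts, genus = genus, depth_cm = seq_len(ncol(counts)),
            age_calbp = 100 * seq_len(ncol(counts)), proxy = proxy)
}

test_that("taxa preparation aggregates genera and applies the 0.5%/2 filter", {
  # 20 samples; taxon A sits at 0.4% everywhere, B at 0.6% in exactly 2
  n <- 20
  base <- matrix(0, 4, n,
                 dimnames = list(c("Larix gmelinii", "Betula nana",
                                   "RareA sp.", "RareB sp."), sprintf("S%02d", 1:n)))
  base["Larix gmelinii", ] <- 600
  base["Betula nana", ] <- 396
  base["RareA sp.", ] <- 4       # 0.4% of 1000
  base["RareB sp.", ] <- 0
  base["RareB sp.", 1:2] <- 6    # 0.6% in exactly two samples
  base["Betula nana", 1:2] <- 394
  tt <- toyTable(base)
  m <- prepareTaxaTable(tt, min_pct = 0.5, min_samples = 2)
  expect_false("RareA" %in% colnames(m))
  expect_true("RareB" %in% colnames(m))
  expect_setequal(colnames(m), c("Larix", "Betula", "RareB"))
  # square root of percentages: 16% -> 4
  c2 <- matrix(c(16, 84, 16, 84, 16, 84), 2, 3,
               dimnames = list(c("A x", "B y"), c("s1", "s2", "s3")))
  m2 <- prepareTaxaTable(toyTable(c2), min_pct = 0.5, min_samples = 2)
  expect_equal(unname(m2[, "A"]), rep(4, 3))
  # genus aggregation sums congeneric species
  c3 <- matrix(c(10, 10, 80, 10, 10, 80, 10, 10, 80), 3, 3,
               dimnames = list(c("Betula nana", "Betula pendula", "Larix sp."),
                               c("s1", "s2", "s3")))
  m3 <- prepareTaxaTable(toyTable(c3), min_pct = 0.5, min_samples = 2)
  expect_equal(unname(m3[, "Betula"]), rep(sqrt(20), 3))
  # zero-count sample is named in the error
  c4 <- c2
  c4[, 2] <- 0
  expect_error(prepareTaxaTable(toyTable(c4)), "s2")
})

test_that("taxa preparation is idempotent on its retained-taxon set", {
  tabs <- genCoupledTaxaTables(seed = 9)
  m1 <- prepareTaxaTable(tabs$dna)
  # re-filtering the retained percentage matrix keeps the same taxa
  pct <- (m1^2)
  tt2 <- toyTable(t(pct))
  m2 <- prepareTaxaTable(tt2, min_pct = 0.5, min_samples = 2)
  expect_setequal(colnames(m2), colnames(m1))
})

test_that("PC1 behaves on degenerate, permuted and duplicated inputs", {
  # rank-1 matrix: PC1 explains essentially all variance
  g <- seq(-2, 2, length.out = 10)
  m <- outer(g, c(1, 2, 3))
  dimnames(m) <- list(paste0("s", 1:10), c("Larix", "Betula", "Salix"))
  r <- pcaFirstComponent(m)
  expect_gte(varExplained(r)[1], 0.999)
  expect_gte(taxonLoadings(r)["Larix", 1], 0)
  # column permutation leaves oriented scores unchanged
  r2 <- pcaFirstComponent(m[, c(3, 1, 2)])
  expect_equal(pcScores(r2), pcScores(r), tolerance = 1e-10)
  # duplicating every sample preserves the per-sample score pattern
  md <- rbind(m, m)
  rownames(md) <- c(rownames(m), paste0(rownames(m), "b"))
  rd <- pcaFirstComponent(md)
  expect_equal(unname(pcScores(rd)[1:10]), unname(pcScores(rd)[11:20]),
               tolerance = 1e-10)
  expect_equal(cor(pcScores(rd)[1:10], pcScores(r)), 1, tolerance = 1e-9)
  expect_error(pcaFirstComponent(m[1:2, ]), "3 samples")
  expect_error(pcaFirstComponent(m[, 1, drop = FALSE]), "2 taxa")
})

test_that("PC1 agrees with an independent ordination engine", {
  skip_if_not_installed("vegan")
  tabs <- genCoupledTaxaTables(seed = 10)
  m <- prepareTaxaTable(tabs$dna)
  ours <- pcScores(pcaFirstComponent(m))
  rda_scores <- vegan::scores(vegan::rda(m), display = "sites",
                              choices = 1)[, 1]
  expect_gte(abs(cor(ours, rda_scores)), 0.999999)
  ve <- varExplained(pcaFirstComponent(m))[1]
  ev <- vegan::rda(m)$CA$eig
  expect_equal(ve, unname(ev[1] / sum(ev)), tolerance = 1e-10)
})

test_that("PC1 recovers the latent gradient and couples the two proxies", {
  tabs <- genCoupledTaxaTables(seed = 11)
  dna <- pcaFirstComponent(prepareTaxaTable(tabs$dna))
  pol <- pcaFirstComponent(prepareTaxaTable(tabs$pollen))
  expect_gte(abs(cor(pcScores(dna), tabs$gradient)), 0.9)
  expect_gte(abs(cor(pcScores(pol), tabs$gradient)), 0.9)
  cmp <- compareProxies(dna, pol)
  expect_gte(cmp$pearson, 0.8)
  expect_identical(nrow(cmp$paired), 20L)
})

test_that("proxy comparison handles trivial and degenerate inputs", {
  s <- stats::setNames(as.numeric(1:5), paste0("s", 1:5))
  expect_equal(compareProxies(s, s)$pearson, 1)
  expect_equal(compareProxies(s, -s)$pearson, -1)
  expect_error(compareProxies(s[1:2], s[1:2]), "3 matched")
})

test_that("taxa tables round-trip through TSV", {
  tabs <- genCoupledTaxaTables(seed = 12)
  path <- tempfile(fileext = ".tsv")
  writeTaxaTable(tabs$dna, path)
  back <- readTaxaTable(path)
  expect_identical(
    SummarizedExperiment::assay(back, "counts"),
    SummarizedExperiment::assay(tabs$dna, "counts"))
  expect_identical(SummarizedExperiment::colData(back)$proxy,
                   SummarizedExperiment::colData(tabs$dna)$proxy)
})
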