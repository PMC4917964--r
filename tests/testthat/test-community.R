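test_that("singleton exclusion drops total-count-<=1 taxa only", {
  counts <- rbind(S1 = c(1, 2, 0, 0), S2 = c(0, 0, 1, 0))
  tab <- otu_table(counts, paste0("k__B; c__C", 1:4))
  out <- exclude_singletons(tab)
  expect_equal(colnames(out$counts), "OTU2")  # count-2 taxon retained
  empty <- otu_table(matrix(0, 2, 0), character(0))
  expect_equal(ncol(exclude_singletons(empty)$counts), 0L)
})

test_that("rarefaction conserves depth, never exceeds originals, is seeded", {
  tab <- toy_otu()
  r <- rarefy(tab, depth = 10, seed = 3)
  expect_equal(unname(library_sizes(r)), rep(10, 3))
  expect_true(all(r$counts <= tab$counts))
  expect_identical(r$counts, rarefy(tab, depth = 10, seed = 3)$counts)
  expect_false(identical(r$counts, rarefy(tab, depth = 10, seed = 4)$counts))
  # depth equal to every library size is the identity
  even <- otu_table(rbind(S1 = c(3, 7), S2 = c(6, 4)), c("k__A", "k__B"))
  expect_equal(rarefy(even, depth = 10, seed = 1)$counts, even$counts)
  expect_error(rarefy(tab, depth = 16), "exceeds")
})

test_that("rarefied marginals follow the hypergeometric expectation", {
  # sample (5,5) rarefied to 4: E[count of taxon 1] = 4 * 5/10 = 2
  tab <- otu_table(matrix(c(5, 5), nrow = 1), c("k__A", "k__B"))
  draws <- vapply(1:3000, function(s) rarefy(tab, depth = 4, seed = s)$counts[1, 1],
                  numeric(1))
  se <- sqrt(4 * 0.5 * 0.5 * (10 - 4) / (10 - 1) / 3000)
  expect_lt(abs(mean(draws) - 2), 4 * se)
})

test_that("relative abundance normalizes rows and rejects empty samples", {
  tab <- otu_table(rbind(S1 = c(2, 2), S2 = c(39, 61)), c("k__A", "k__B"))
  p <- relative_abundance(tab)
  expect_equal(p["S1", ], c(OTU1 = 0.5, OTU2 = 0.5))
  expect_equal(p["S2", ], c(OTU1 = 0.39, OTU2 = 0.61))
  scaled <- otu_table(rbind(S1 = c(20, 20), S2 = c(390, 610)), c("k__A", "k__B"))
  expect_equal(relative_abundance(scaled), p)
  bad <- otu_table(rbind(S1 = c(1, 1), S2 = c(0, 0)), c("k__A", "k__B"))
  expect_error(relative_abundance(bad), "zero-sum")
})

test_that("rank aggregation conserves totals and buckets missing ranks", {
  tab <- toy_otu()
  agg <- aggregate_rank(tab, "class")
  expect_equal(sum(agg$counts), sum(tab$counts))
  expect_equal(unname(agg$counts[, "Sphingobacteria"]),
               unname(tab$counts[, 1] + tab$counts[, 2]))
  expect_true("unclassified" %in% colnames(agg$counts))
  expect_equal(taxonomy_rank("k__Bacteria; p__X; c__Y", "class"), "Y")
  expect_equal(taxonomy_rank("k__Bacteria", "class"), "unclassified")
})

test_that("Shannon index has the entropy properties", {
  expect_equal(shannon(c(0, 12, 0)), 0)
  expect_equal(shannon(rep(5, 4), base = 2), 2)
  expect_equal(shannon(c(2, 2), base = 2), 1)
  # permutation invariance and the uniform maximum at log_base(K)
  x <- c(8, 1, 3, 2, 6)
  expect_equal(shannon(x), shannon(rev(x)))
  expect_lt(shannon(x, base = 2), log2(5))
  expect_equal(shannon(x, base = 2) * log(2), shannon(x, base = exp(1)))
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("PCA matches a brute-force eigendecomposition up to sign", {
  set.seed(23)
  mat <- matrix(rnorm(24), nrow = 6)
  ord <- pca_ordination(mat)
  # oracle: eigendecomposition of the covariance of the centred matrix
  cen <- scale(mat, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(cen), symmetric = TRUE)
  scores_oracle <- cen %*% eig$vectors
  for (k in seq_len(ncol(mat))) {
    expect_equal(abs(ord$scores[, k]), abs(scores_oracle[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(ord$explained, eig$values / sum(eig$values), tolerance = 1e-10)
  # trace conservation: component variances sum to total variance
  expect_equal(sum(ord$sdev^2), sum(apply(mat, 2, var)), tolerance = 1e-10)
  # orthogonal scores
  cp <- crossprod(ord$scores)
  expect_equal(cp[lower.tri(cp)], rep(0, sum(lower.tri(cp))), tolerance = 1e-8)
})

test_that("PCA degenerate geometries behave as expected", {
  collinear <- cbind(1:5, 2 * (1:5))
  ord <- pca_ordination(collinear)
  expect_equal(ord$explained[1], 1, tolerance = 1e-12)
  # a constant feature contributes zero variance
  with_const <- cbind(matrix(rnorm(10), 5), 7)
  expect_equal(sum(pca_ordination(with_const)$sdev^2),
               sum(pca_ordination(with_const[, 1:2])$sdev^2), tolerance = 1e-12)
  expect_error(pca_ordination(matrix(1:4, nrow = 1)), "2 samples")
})

test_that("one-way ANOVA reproduces the hand-computed F and its null", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_by_location(vals, grp)
  expect_equal(res$F, 3)  # SSB=6, SSW=6, df=(2,6)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  same <- anova_by_location(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(same$F, 0)
  expect_error(anova_by_location(1:5, c("a", "a", "b", "b", "c")), ">= 2 samples")
  degen <- anova_by_location(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
})

test_that("ANOVA p agrees with a permutation null on small data", {
  set.seed(31)
  vals <- rnorm(12)
  grp <- rep(c("a", "b", "c"), each = 4)
  obs <- anova_by_location(vals, grp)
  nperm <- 4000
  perm_f <- replicate(nperm, anova_by_location(vals, sample(grp))$F)
  p_perm <- mean(perm_f >= obs$F)
  expect_lt(abs(p_perm - obs$p), 4 * sqrt(obs$p * (1 - obs$p) / nperm) + 0.02)
})

test_that("taxon-geochemistry correlations recover couplings and flag constants", {
  set.seed(37)
  n <- 30
  doc <- rlnorm(n, 1, 0.4)
  prop1 <- 0.2 + 0.05 * scale(log(doc))[, 1] + rnorm(n, sd = 0.01)
  prop2 <- runif(n, 0.1, 0.3)
  props <- cbind(coupled = prop1, independent = prop2)
  geo <- data.frame(DOC = doc, flat = rep(1.5, n))
  res <- taxon_geochem_correlations(props, geo)
  expect_gt(res$r[res$taxon == "coupled" & res$variable == "DOC"], 0.5)
  expect_false(res$defined[res$variable == "flat"][1])
  adj <- taxon_geochem_correlations(props, geo, adjust = TRUE)
  expect_true("p_adj" %in% names(adj))
  expect_true(all(adj$p_adj >= adj$p, na.rm = TRUE))
  # average |r| of independent pairs stays small over repeats
  rs <- replicate(50, {
    p <- cbind(t1 = runif(20))
    g <- data.frame(v = rnorm(20))
    taxon_geochem_correlations(p, g)$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})
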