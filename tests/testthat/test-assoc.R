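test_that("PCA separates simulated clusters and respects permutations", {
  sim <- simulateDataset(simulationConfig(nBreeds = 2, nPerBreed = 20,
                                          nSnpsNeutral = 300,
                                          nSnpsAdaptive = 0, fst = 0.3,
                                          seed = 61))
  g <- sim$genotypes
  pc <- structurePca(g, k = 2)
  s1 <- pc$scores[breeds(g) == "BR01", 1]
  s2 <- pc$scores[breeds(g) == "BR02", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))   # zero overlap
  expect_equal(unname(colMeans(pc$scores)), c(0, 0), tolerance = 1e-10)
  perm <- sample(nIndividuals(g))
  pc2 <- structurePca(g[perm, ], k = 2)
  for (a in 1:2)
    expect_true(max(abs(pc2$scores[, a] - pc$scores[perm, a])) < 1e-8 ||
                  max(abs(pc2$scores[, a] + pc$scores[perm, a])) < 1e-8)
})

test_that("broken-stick selection keeps few components for unstructured data", {
  set.seed(62)
  g <- makeGeno(matrix(rbinom(100 * 200, 2, 0.5), 100, 200))
  pc <- structurePca(g, k = "auto")
  expect_equal(pc$method, "broken-stick")
  expect_lte(pc$k, 5)      # pure noise: nothing far above the broken stick
  expect_gte(pc$k, 2)      # floor of two components
})

test_that("genotype indicators follow carrier counts and degeneracy rules", {
  calls <- matrix(c(rep(0L, 10), rep(1L, 10), rep(2L, 10)), ncol = 1)
  g <- makeGeno(calls, breeds = rep("B", 30))
  ind <- genotypeIndicators(g)
  expect_length(ind[[1]], 3)
  expect_equal(vapply(ind[[1]], `[[`, "", "label"), c("AA", "AG", "GG"))
  # monomorphic locus: its single observed genotype is constant -> skipped
  gm <- makeGeno(matrix(0L, 30, 1), breeds = rep("B", 30))
  expect_length(genotypeIndicators(gm)[[1]], 0)
  # no heterozygotes: two indicators survive
  gh <- makeGeno(matrix(c(rep(0L, 15), rep(2L, 15)), ncol = 1),
                 breeds = rep("B", 30))
  expect_length(genotypeIndicators(gh)[[1]], 2)
  # rare genotype below the carrier floor is dropped, leaving only the
  # common homozygote's indicator at this two-genotype locus
  gr <- makeGeno(matrix(c(rep(0L, 27), rep(1L, 3)), ncol = 1),
                 breeds = rep("B", 30))
  expect_length(genotypeIndicators(gr)[[1]], 1)
  expect_equal(genotypeIndicators(gr)[[1]][[1]]$label, "AA")
})

test_that("the likelihood-ratio statistic vanishes under nested collinearity", {
  set.seed(63)
  n <- 200
  S <- matrix(rnorm(2 * n), n, 2)
  y <- rbinom(n, 1, plogis(S[, 1]))
  res <- lrtAssociation(y, x = S[, 1], S = S)   # x duplicates PC1
  expect_lt(res$G, 1e-6)
  expect_equal(res$p_value, 1, tolerance = 1e-3)
})

test_that("a strong environmental effect is detected at extreme significance", {
  set.seed(64)
  n <- 500
  S <- matrix(rnorm(3 * n), n, 3)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 * S[, 1] + 1.5 * x))
  res <- lrtAssociation(y, x, S)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$effect_sign, 1)
  expect_true(res$converged)
})

test_that("the statistic is invariant to affine rescaling of x and PC shifts", {
  set.seed(65)
  n <- 300
  S <- matrix(rnorm(2 * n), n, 2)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * x - 0.2 * S[, 2]))
  g1 <- lrtAssociation(y, x, S)$G
  g2 <- lrtAssociation(y, 3.7 * x - 11, S)$G
  g3 <- lrtAssociation(y, x, S + 5)$G
  expect_equal(g1, g2, tolerance = 1e-6)
  expect_equal(g1, g3, tolerance = 1e-6)
})

test_that("constant responses are rejected", {
  expect_error(lrtAssociation(rep(1L, 50), rnorm(50), matrix(rnorm(50))),
               "degenerate response")
})

test_that("Benjamini-Hochberg matches hand computations and the oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(66)
  for (rep in 1:10) {
    p <- runif(sample(5:80, 1))^2
    q <- bhAdjust(p)
    expect_lt(max(abs(q - bhBruteForce(p))), 1e-12)
    expect_lt(max(abs(q - p.adjust(p, "BH"))), 1e-12)
    expect_true(all(q >= p))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("gene annotation honors the half-open interval convention", {
  lociTab <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                        chromosome = "1",
                        position_bp = c(101L, 200L, 201L, 500L),
                        allele_a = "A", allele_b = "G",
                        stringsAsFactors = FALSE)
  genes <- data.frame(chromosome = "1", start = 100L, end = 200L,
                      name = "GENE1", stringsAsFactors = FALSE)
  res <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                    stringsAsFactors = FALSE)
  out <- annotateHits(res, lociTab, genes)
  expect_equal(out$gene, c("GENE1", "GENE1", NA, NA))
  # empty gene table: no annotation, no error
  out2 <- annotateHits(res, lociTab, genes[0, ])
  expect_true(all(is.na(out2$gene)))
  # malformed interval
  expect_error(annotateHits(res, lociTab,
                            data.frame(chromosome = "1", start = 5L,
                                       end = 5L, name = "X")),
               "malformed")
  # overlapping genes are comma-joined
  genes2 <- rbind(genes, data.frame(chromosome = "1", start = 90L,
                                    end = 300L, name = "GENE2"))
  out3 <- annotateHits(res, lociTab, genes2)
  expect_equal(out3$gene[1], "GENE1,GENE2")
})

test_that("the association scan finds planted clines and labels genotypes", {
  cfg <- simulationConfig(nBreeds = 10, nPerBreed = 25, nSnpsNeutral = 400,
                          nSnpsAdaptive = 8, fst = 0.005, nClusters = 4,
                          fstBetween = 0.05, clineAlpha = 0.25,
                          clineBeta = 0.5, seed = 67)
  sim <- simulateDataset(cfg)
  res <- runAssociation(sim$genotypes, sim$env, k = 3)
  expect_true(all(res$G >= -1e-8))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(res$genotype %in% c("AA", "AG", "GG")))
  sig <- tapply(res$q_value < 0.05, res$snp_id, any)
  ad <- grepl("^adap", names(sig))
  expect_gt(mean(sig[ad]), 0.5)
  expect_lt(mean(sig[!ad]), 0.1)
})

test_that("per-variable and pooled BH families are both available", {
  cfg <- simulationConfig(nBreeds = 6, nPerBreed = 15, nSnpsNeutral = 30,
                          nSnpsAdaptive = 0, seed = 68)
  sim <- simulateDataset(cfg)
  env2 <- rbind(sim$env,
                transform(sim$env, variable = "ELEV", value = rev(value)))
  resPool <- runAssociation(sim$genotypes, env2,
                            variables = c("BIO3", "ELEV"), k = 2)
  resPer <- runAssociation(sim$genotypes, env2,
                           variables = c("BIO3", "ELEV"), k = 2,
                           bhFamily = "per_variable")
  expect_setequal(unique(resPool$variable), c("BIO3", "ELEV"))
  for (v in c("BIO3", "ELEV")) {
    i <- resPer$variable == v
    expect_equal(resPer$q_value[i], bhAdjust(resPer$p_value[i]))
  }
  expect_equal(resPool$q_value, bhAdjust(resPool$p_value))
})
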