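test_that("call-rate and MAF failures are removed and attributed", {
  set.seed(1)
  calls <- matrix(rbinom(200, 2, 0.4), 20, 10)
  calls[1:3, 4] <- NA            # SNP 4: call rate 85%
  calls[, 7] <- 0L               # SNP 7: monomorphic, MAF 0
  g <- makeGeno(calls)
  res <- filterCallRateMaf(g, qcParams())
  expect_setequal(res$report$id, c("snp0004", "snp0007"))
  expect_equal(res$report$stage[res$report$id == "snp0004"], "snp_call_rate")
  expect_equal(res$report$stage[res$report$id == "snp0007"], "snp_maf")
  expect_equal(nLoci(res$genotypes), 8)
  expect_equal(nIndividuals(res$genotypes), 20)
})

test_that("a fixture with three planted failures yields exactly that report", {
  set.seed(2)
  n <- 200
  calls <- matrix(rbinom(n * 60, 2, 0.5), n, 60)
  calls[1:5, 5] <- NA                        # snp0005 call rate 195/200 < .98
  calls[, 12] <- c(2L, rep(0L, n - 1))       # snp0012 MAF 1/200 < .05
  calls[3, setdiff(1:36, 12)] <- NA          # ind003 call rate ~ 40%
  g <- makeGeno(calls)
  res <- filterCallRateMaf(g, qcParams())
  expect_setequal(res$report$id, c("snp0005", "snp0012", "ind003"))
  expect_equal(nrow(res$report), 3)
  expect_equal(nIndividuals(g) - nIndividuals(res$genotypes) +
                 nLoci(g) - nLoci(res$genotypes), 3)
})

test_that("an empty panel after filtering is an error", {
  g <- makeGeno(matrix(0L, 5, 3))   # all monomorphic
  expect_error(filterCallRateMaf(g), "all loci removed")
})

test_that("LD pruning drops the later of a duplicated pair and keeps independents", {
  set.seed(3)
  calls <- matrix(rbinom(400, 2, 0.5), 40, 10)
  calls[, 6] <- calls[, 2]    # r^2 = 1 within a 50-SNP window
  g <- makeGeno(calls)
  kept <- ldPrune(g, qcParams())
  expect_false("snp0006" %in% kept)
  expect_true("snp0002" %in% kept)
  # independent simulated SNPs: nothing else pruned
  set.seed(4)
  g2 <- makeGeno(matrix(rbinom(3000, 2, 0.5), 100, 30))
  expect_equal(ldPrune(g2, qcParams()), loci(g2)$snp_id)
})

test_that("windowed prune agrees with the full pairwise oracle on small panels", {
  set.seed(5)
  for (rep in 1:3) {
    base <- rbinom(60, 2, 0.5)
    calls <- sapply(1:12, function(j) {
      flip <- runif(60) < 0.15
      ifelse(flip, rbinom(60, 2, 0.5), base)     # chain of correlated SNPs
    })
    g <- makeGeno(calls)
    kept <- ldPrune(g, qcParams(ldWindowSnps = 12, ldStepSnps = 1))
    oracle <- loci(g)$snp_id[ldPruneBruteForce(calls, 0.2)]
    expect_equal(kept, oracle)
  }
})

test_that("duplicated individuals lose the higher-missingness copy", {
  set.seed(6)
  calls <- matrix(rbinom(3600, 2, 0.5), 6, 600)
  calls[2, ] <- calls[1, ]          # identical twins rows 1/2
  calls[2, 1:4] <- NA               # row 2 has the higher missingness
  # the opposing-homozygote bar scales with panel size: ~75 expected for
  # unrelated pairs on this 600-SNP fixture, so flag only near-zero counts
  g <- makeGeno(calls)
  res <- removeDuplicatesRelatives(g, qcParams(opposingHomMax = 10))
  expect_true("ind002" %in% res$report$id[res$report$stage == "duplicate"])
  expect_false("ind001" %in% res$report$id)
  expect_equal(nIndividuals(res$genotypes), 5)
})

test_that("the relative occurring in multiple flagged pairs is the one removed", {
  # A shares a genome with B and with C; B and C unrelated. Build A as a
  # 'parent' of both so A-B and A-C have zero opposing homozygotes.
  set.seed(7)
  L <- 2000   # large enough that unrelated pairs clear the opposing-hom bar
  p <- runif(L, 0.2, 0.8)
  A <- rbinom(L, 2, p)
  child <- function(par) {
    fromPar <- ifelse(par == 1, rbinom(L, 1, 0.5), par / 2)
    fromPop <- rbinom(L, 1, p)
    as.integer(fromPar + fromPop)
  }
  B <- child(A); C <- child(A)
  others <- t(replicate(4, rbinom(L, 2, p)))
  calls <- rbind(A, B, C, others)
  g <- makeGeno(calls)
  # B and C are half-sibs through A (about half the unrelated
  # opposing-homozygote count); a bar of 50 flags only the parental pairs
  res <- removeDuplicatesRelatives(g, qcParams(opposingHomMax = 50))
  rel <- res$report[res$report$stage == "relatedness", ]
  expect_equal(rel$id, "ind001")             # A occurs in both pairs
  expect_equal(nIndividuals(res$genotypes), 6)
})

test_that("unrelated panels pass the duplicate/relative stage untouched", {
  set.seed(8)
  p <- runif(3000, 0.2, 0.8)
  calls <- t(replicate(12, rbinom(3000, 2, p)))
  g <- makeGeno(calls)
  res <- removeDuplicatesRelatives(g, qcParams())
  expect_equal(nrow(res$report), 0)
  expect_equal(nIndividuals(res$genotypes), 12)
})

test_that("pi-hat separates duplicates, parent-offspring and unrelated pairs", {
  set.seed(9)
  L <- 2000
  p <- runif(L, 0.2, 0.8)
  pop <- t(replicate(10, rbinom(L, 2, p)))
  par1 <- pop[1, ]
  off <- ifelse(par1 == 1, rbinom(L, 1, 0.5), par1 / 2) + rbinom(L, 1, p)
  calls <- rbind(pop, off, pop[3, ])        # row 11 = child of 1, 12 = dup of 3
  g <- makeGeno(calls)
  ibd <- pairwiseIbd(g)
  pick <- function(a, b)
    ibd$pi_hat[(ibd$id_a == a & ibd$id_b == b) | (ibd$id_a == b & ibd$id_b == a)]
  expect_gt(pick("ind001", "ind011"), 0.4)   # parent-offspring ~ 0.5
  expect_lt(pick("ind001", "ind011"), 0.6)
  expect_gt(pick("ind003", "ind012"), 0.9)   # duplicate ~ 1
  unrel <- ibd$pi_hat[ibd$id_a %in% c("ind004", "ind005", "ind006") &
                        ibd$id_b %in% c("ind004", "ind005", "ind006")]
  expect_true(all(unrel < 0.15))
})

test_that("kinship filtering removes one of each close pair and spares the rest", {
  set.seed(10)
  L <- 2000
  p <- runif(L, 0.2, 0.8)
  pop <- t(replicate(8, rbinom(L, 2, p)))
  off <- ifelse(pop[1, ] == 1, rbinom(L, 1, 0.5), pop[1, ] / 2) + rbinom(L, 1, p)
  g <- makeGeno(rbind(pop, off, pop[2, ]))   # one PO pair + one duplicate
  res <- kinshipFilterSecondDegree(g, qcParams())
  expect_equal(nrow(res$report), 2)
  expect_equal(nIndividuals(res$genotypes), 8)
  # no offending pair remains
  left <- pairwiseIbd(res$genotypes)
  expect_true(all(left$pi_hat <= 0.25))
  # an unrelated panel is unchanged
  res2 <- kinshipFilterSecondDegree(makeGeno(pop), qcParams())
  expect_equal(nIndividuals(res2$genotypes), 8)
})

test_that("representative subsampling preserves small breeds and diversity", {
  sim <- simulateDataset(simulationConfig(nBreeds = 2, nPerBreed = c(24, 60),
                                          nSnpsNeutral = 300,
                                          nSnpsAdaptive = 0, seed = 12))
  g <- sim$genotypes
  out <- representativeSubsample(g, maxN = 30, seed = 1)
  expect_equal(as.integer(table(breeds(out))), c(24L, 30L))
  # expected heterozygosity of the kept subset stays close to the full breed
  hetOf <- function(gg, b) {
    fr <- alleleFrequencies(gg)
    mean(2 * fr$p[fr$group == b] * (1 - fr$p[fr$group == b]), na.rm = TRUE)
  }
  expect_lt(abs(hetOf(out, "BR02") - hetOf(g, "BR02")) / hetOf(g, "BR02"),
            0.05)
})

test_that("farthest-point subsampling reaches both halves of a split breed", {
  set.seed(13)
  L <- 200
  pA <- runif(L, 0.05, 0.3); pB <- runif(L, 0.7, 0.95)
  calls <- rbind(t(replicate(40, rbinom(L, 2, pA))),
                 t(replicate(40, rbinom(L, 2, pB))))
  g <- makeGeno(calls)                     # one breed, two hidden clusters
  out <- representativeSubsample(g, maxN = 30, seed = 2)
  kept <- match(individuals(out)$sample_id, individuals(g)$sample_id)
  expect_gt(sum(kept <= 40), 0)
  expect_gt(sum(kept > 40), 0)
})

test_that("removal reports account for every individual removed", {
  set.seed(14)
  calls <- matrix(rbinom(2000, 2, 0.5), 10, 200)
  calls[2, ] <- calls[1, ]
  g <- makeGeno(calls)
  res <- removeDuplicatesRelatives(g, qcParams())
  expect_equal(nIndividuals(g) - nIndividuals(res$genotypes),
               nrow(res$report))
})
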