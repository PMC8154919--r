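test_that("Köppen group assignment follows the class maps", {
  kop <- assignKoppenGroups(koppenClasses())
  row <- function(b) kop[kop$breed == b, ]
  expect_equal(row("GIR")$hot_group, "HOT")      # Csa
  expect_equal(row("GIR")$dry_group, "DRY")
  expect_equal(row("VAL")$hot_group, "NOTHOT")   # EF polar tundra
  expect_equal(row("VAL")$dry_group, "NOTDRY")
  expect_equal(row("MON")$hot_group, "HOT")      # Cfa
  expect_equal(row("MON")$dry_group, "NOTDRY")
  expect_equal(row("GAR")$dry_group, "DRY")      # BSk steppe
  expect_error(
    assignKoppenGroups(data.frame(breed = "ZZZ", current_class = "Xyz")),
    "Xyz.*ZZZ")
})

test_that("class-change summaries reproduce the panel bookkeeping", {
  kop <- koppenClasses()
  s <- koppenChangeSummary(kop)
  expect_equal(s$nUnchanged, 11L)
  expect_equal(unname(s$currentMacroClass["Temperate"]), 21L)
  expect_equal(unname(s$currentMacroClass["Cold"]), 8L)
  expect_equal(unname(s$currentMacroClass["Arid"]), 2L)
  expect_equal(unname(s$currentMacroClass["Polar"]), 1L)
  expect_equal(unname(s$unchangedByClass["Csa"]), 9L)
  expect_true(all(c("GAR", "NVE") %in% s$unchangedBreeds))
  empty <- koppenChangeSummary(kop[0, ])
  expect_equal(empty$nUnchanged, 0L)
  expect_length(empty$currentMacroClass, 0)
})

test_that("the two-group ANOVA matches hand computation and the t-squared identity", {
  an <- groupAnova(c(0.1, 0.2, 0.8, 0.9), c("a", "a", "b", "b"))
  expect_equal(an$F, 98, tolerance = 1e-12)
  expect_equal(an$df, c(1, 2))
  # identical group means -> F = 0, p = 1
  an0 <- groupAnova(c(0.1, 0.2, 0.1, 0.2), c("a", "a", "b", "b"))
  expect_equal(an0$F, 0, tolerance = 1e-12)
  expect_equal(an0$p, 1)
  # F equals the squared pooled-variance t statistic
  set.seed(71)
  for (rep in 1:5) {
    v <- rnorm(12); grp <- rep(c("x", "y"), each = 6)
    tt <- t.test(v ~ grp, var.equal = TRUE)
    expect_equal(groupAnova(v, grp)$F, unname(tt$statistic^2),
                 tolerance = 1e-10)
  }
  expect_error(groupAnova(c(1, 2, 3), c("a", "a", "b")), "at least two")
})

test_that("the climate regression recovers noiseless and noisy slopes", {
  x <- seq(-1, 1, length.out = 10)
  y <- 0.3278 * x + 0.45
  fit <- suppressWarnings(climateRegression(x, y))   # exact fit warns in lm
  expect_equal(fit$b, 0.3278, tolerance = 1e-12)
  expect_lt(fit$p, 1e-10)
  expect_equal(fit$intercept, 0.45, tolerance = 1e-12)
  expect_error(climateRegression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(climateRegression(1:2, 1:2), "three breeds")
})

test_that("the slope test holds its size under the null", {
  set.seed(72)
  reject <- mean(replicate(400, {
    x <- rnorm(12)
    climateRegression(x, runif(12, 0.2, 0.8))$p < 0.05
  }))
  expect_gt(reject, 0.02)
  expect_lt(reject, 0.09)
})

test_that("projection reproduces the published worked example", {
  # reference values are printed to 4 decimals; agree to that precision
  dry <- projectFrequencies(0.4296, 0.3278, -0.1253, group = "DRY")
  expect_lt(abs(dry$p_future - 0.3885), 1e-4)
  expect_lt(abs(dry$GG_future - 0.1509), 1e-4)
  notdry <- projectFrequencies(0.6109, 0.3278, -0.0935, group = "NOTDRY")
  expect_lt(abs(notdry$p_future - 0.5802), 1e-4)
  expect_lt(abs(notdry$GG_future - 0.3366), 1e-4)
})

test_that("projection is Hardy-Weinberg consistent, monotone and clamped", {
  pr <- projectFrequencies(0.3, 0.5, 0)
  expect_equal(pr$p_future, pr$p_current)
  expect_equal(pr$AA_future + pr$AG_future + pr$GG_future, 1,
               tolerance = 1e-9)
  expect_equal(pr$AA_current + pr$AG_current + pr$GG_current, 1,
               tolerance = 1e-9)
  # monotone in delta for b > 0
  ps <- vapply(c(-0.5, 0, 0.5), function(d)
    projectFrequencies(0.5, 0.4, d)$p_future, 0)
  expect_true(all(diff(ps) > 0))
  # clamping at the boundary
  hi <- projectFrequencies(0.9, 1, 0.5)
  expect_equal(hi$p_future, 1)
  expect_true(hi$clamped)
  lo <- projectFrequencies(0.1, 1, -0.5)
  expect_equal(lo$p_future, 0)
  expect_true(lo$clamped)
})

test_that("published genotype triples are Hardy-Weinberg self-consistent", {
  tab <- projectedGenotypeTable()
  for (r in seq_len(nrow(tab))) {
    for (epoch in c("current", "future")) {
      aa <- tab[[paste0("AA_", epoch)]][r]
      gg <- tab[[paste0("GG_", epoch)]][r]
      ag <- tab[[paste0("AG_", epoch)]][r]
      p <- gg + ag / 2                       # focal-allele frequency
      # entries are printed at 2 decimals; allow that rounding to propagate
      expect_lt(abs((1 - p)^2 - aa), 0.015)
      expect_lt(abs(2 * p * (1 - p) - ag), 0.015)
      expect_lt(abs(p^2 - gg), 0.015)
    }
  }
})

test_that("the ARL13B rows rebuild from the published allele frequencies", {
  tab <- projectedGenotypeTable()
  arl <- tab[tab$snp_id == "snp32991-scaffold385-133908", ]
  dry <- projectFrequencies(0.4296, 0.3278, -0.1253, group = "DRY")
  expect_equal(round(c(dry$AA_current, dry$GG_current, dry$AG_current), 2),
               unlist(arl[arl$group == "DRY", c("AA_current", "GG_current",
                                                "AG_current")]),
               ignore_attr = TRUE)
  expect_equal(round(c(dry$AA_future, dry$GG_future, dry$AG_future), 2),
               unlist(arl[arl$group == "DRY", c("AA_future", "GG_future",
                                                "AG_future")]),
               ignore_attr = TRUE)
})

test_that("the Köppen-group pipeline screens, regresses and projects", {
  set.seed(73)
  breeds <- sprintf("B%02d", 1:12)
  kop <- data.frame(breed = breeds,
                    current_class = rep(c("Csa", "Dfb"), each = 6),
                    future_class = "Csa", stringsAsFactors = FALSE)
  kop <- assignKoppenGroups(kop)
  env <- rbind(
    data.frame(breed = breeds, variable = "BIO3", epoch = "current",
               value = seq(0, 1, length.out = 12)),
    data.frame(breed = breeds, variable = "BIO3", epoch = "future",
               value = seq(0, 1, length.out = 12) - 0.12))
  # SNP 'assoc1': frequency tracks BIO3 (dry group lives at low BIO3)
  freq <- rbind(
    data.frame(group = breeds, snp_id = "assoc1",
               p = 0.2 + 0.5 * seq(0, 1, length.out = 12) +
                 rnorm(12, 0, 0.01), n = 30),
    data.frame(group = breeds, snp_id = "flat1",
               p = 0.5 + rnorm(12, 0, 0.02), n = 30))
  out <- projectKoppenGroups(freq, kop, env, "BIO3", grouping = "dry_group")
  expect_true("assoc1" %in% out$projection$snp_id)
  expect_false("flat1" %in% out$projection$snp_id)
  pr <- out$projection[out$projection$snp_id == "assoc1", ]
  expect_setequal(pr$group, c("DRY", "NOTDRY"))
  # delta < 0 and b > 0: projected frequencies fall in both groups
  expect_true(all(pr$p_future < pr$p_current))
})
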