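#' Quality-control thresholds
#'
#' Bundles the thresholds of the genotype QC cascade. Defaults follow the
#' common SNP-array practice for multi-breed panels: retain SNPs with call
#' rate > 98% and MAF > 5%, individuals with call rate > 95%, prune pairs of
#' loci with squared genotype correlation above 0.2 inside a 50-SNP window
#' advancing by 5, drop duplicated individuals (identity-by-state > 99%),
#' treat pairs with fewer than 100 opposing homozygotes as close relatives,
#' subsample breeds to at most 30 individuals, and cut kinship above the
#' second-degree midpoint pi-hat of 0.25.
#'
#' @param snpCallRateMin,indCallRateMin,mafMin,ldR2Max,ldWindowSnps,
#'   ldStepSnps,dupIbsMin,opposingHomMax,maxPerBreed,kinshipMax thresholds;
#'   see Description.
#' @return list of class `qc_params`.
#' @export
qcParams <- function(snpCallRateMin = 0.98, indCallRateMin = 0.95,
                     mafMin = 0.05, ldR2Max = 0.2,
                     ldWindowSnps = 50L, ldStepSnps = 5L,
                     dupIbsMin = 0.99, opposingHomMax = 100L,
                     maxPerBreed = 30L, kinshipMax = 0.25) {
  p <- list(snpCallRateMin = snpCallRateMin, indCallRateMin = indCallRateMin,
            mafMin = mafMin, ldR2Max = ldR2Max,
            ldWindowSnps = as.integer(ldWindowSnps),
            ldStepSnps = as.integer(ldStepSnps),
            dupIbsMin = dupIbsMin, opposingHomMax = as.integer(opposingHomMax),
            maxPerBreed = as.integer(maxPerBreed), kinshipMax = kinshipMax)
  stopifnot(p$snpCallRateMin >= 0, p$snpCallRateMin <= 1,
            p$mafMin >= 0, p$mafMin < 0.5,
            p$ldR2Max > 0, p$ldR2Max <= 1,
            p$kinshipMax > 0, p$kinshipMax < 1)
  class(p) <- "qc_params"
  p
}

emptyRemovalReport <- function() {
  data.frame(id = character(), stage = character(), reason = character(),
             statistic = numeric(), stringsAsFactors = FALSE)
}

removalRows <- function(id, stage, reason, statistic) {
  n <- length(id)
  data.frame(id = id, stage = rep_len(stage, n), reason = rep_len(reason, n),
             statistic = rep_len(statistic, length.out = n),
             stringsAsFactors = FALSE)
}

#' Call-rate and MAF filter
#'
#' First removes loci with call rate at or below `snpCallRateMin` or MAF at
#' or below `mafMin` (computed on the full panel), then individuals whose
#' call rate over the retained loci is at or below `indCallRateMin`. Every
#' removal is attributed in the report.
#'
#' @param g a [GenotypeData-class] object.
#' @param params a [qcParams()] list.
#' @return list with `genotypes` (filtered) and `report` (data.frame
#'   `id`, `stage`, `reason`, `statistic`).
#' @export
filterCallRateMaf <- function(g, params = qcParams()) {
  if (nLoci(g) == 0 || nIndividuals(g) == 0) stop("empty genotype matrix")
  cl <- genotypeCalls(g)
  snpCr <- colMeans(!is.na(cl))
  n <- colSums(!is.na(cl))
  p <- colSums(cl, na.rm = TRUE) / (2 * pmax(n, 1))
  maf <- pmin(p, 1 - p)
  dropCr <- snpCr <= params$snpCallRateMin
  dropMaf <- !dropCr & (n == 0 | maf <= params$mafMin)
  report <- rbind(
    removalRows(loci(g)$snp_id[dropCr], "snp_call_rate",
                "call rate below threshold", snpCr[dropCr]),
    removalRows(loci(g)$snp_id[dropMaf], "snp_maf",
                "minor allele frequency below threshold", maf[dropMaf]))
  keepSnp <- !(dropCr | dropMaf)
  if (!any(keepSnp)) stop("all loci removed by call-rate/MAF filter")
  g2 <- g[, which(keepSnp)]
  indCr <- rowMeans(!is.na(genotypeCalls(g2)))
  dropInd <- indCr <= params$indCallRateMin
  if (any(dropInd)) {
    report <- rbind(report, removalRows(
      individuals(g2)$sample_id[dropInd], "ind_call_rate",
      "individual call rate below threshold", indCr[dropInd]))
    g2 <- g2[which(!dropInd), ]
  }
  rownames(report) <- NULL
  list(genotypes = g2, report = rbind(emptyRemovalReport(), report))
}

#' Linkage-disequilibrium pruning
#'
#' Sliding-window prune of correlated loci, in the spirit of PLINK's
#' `--indep-pairwise`: within each window of `ldWindowSnps` loci (advancing
#' by `ldStepSnps`, per chromosome in map order), any pair of retained loci
#' with squared Pearson genotype correlation strictly above `ldR2Max` loses
#' the later locus in map order. Deterministic.
#'
#' @inheritParams filterCallRateMaf
#' @return character vector of retained snp_ids.
#' @export
ldPrune <- function(g, params = qcParams()) {
  cl <- genotypeCalls(g)
  loc <- loci(g)
  keep <- rep(TRUE, nLoci(g))
  for (chr in unique(loc$chromosome)) {
    idx <- which(loc$chromosome == chr)
    idx <- idx[order(loc$position_bp[idx])]
    m <- length(idx)
    if (m < 2) next
    starts <- seq(1L, m, by = params$ldStepSnps)
    for (s in starts) {
      win <- idx[s:min(m, s + params$ldWindowSnps - 1L)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(
        stats::cor(cl[, win, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      for (a in seq_len(length(win) - 1L)) {
        if (!keep[win[a]]) next
        for (b in (a + 1L):length(win)) {
          if (!keep[win[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > params$ldR2Max)
            keep[win[b]] <- FALSE
        }
      }
    }
  }
  loc$snp_id[keep]
}

pairIndices <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(2:n, function(k) k:n))
  cbind(i = i, j = j)
}

#' Opposing-homozygote counts between all pairs
#'
#' Number of loci where one individual is homozygous for one allele and the
#' other homozygous for the other; zero for parent-offspring pairs barring
#' genotyping error, and proportional to panel size for unrelated pairs.
#'
#' @param g a [GenotypeData-class] object.
#' @return symmetric integer matrix.
#' @export
opposingHomozygotes <- function(g) {
  cl <- genotypeCalls(g)
  I0 <- (!is.na(cl)) & cl == 0L
  I2 <- (!is.na(cl)) & cl == 2L
  storage.mode(I0) <- "numeric"; storage.mode(I2) <- "numeric"
  m <- I0 %*% t(I2)
  m <- m + t(m)
  dimnames(m) <- list(individuals(g)$sample_id, individuals(g)$sample_id)
  m
}

#' Remove duplicated and closely related individuals
#'
#' Two passes. Duplicates: pairs with identity-by-state similarity above
#' `dupIbsMin` lose the member with the higher missing rate. Relatives:
#' pairs with fewer than `opposingHomMax` opposing homozygotes are flagged,
#' and individuals are removed by the rule "the animal occurring in multiple
#' flagged pairs, else the one with the higher missingness", applied
#' iteratively until no flagged pair remains.
#'
#' @inheritParams filterCallRateMaf
#' @return list with `genotypes` and `report`.
#' @export
removeDuplicatesRelatives <- function(g, params = qcParams()) {
  report <- emptyRemovalReport()
  ids <- individuals(g)$sample_id
  miss <- missingRate(g)
  n <- nIndividuals(g)
  drop <- rep(FALSE, n)
  if (n >= 2) {
    ibsSim <- 1 - ibsDistance(g)
    pr <- pairIndices(n)
    dup <- pr[ibsSim[pr] > params$dupIbsMin, , drop = FALSE]
    for (r in seq_len(nrow(dup))) {
      i <- dup[r, 1]; j <- dup[r, 2]
      if (drop[i] || drop[j]) next
      victim <- if (miss[j] >= miss[i]) j else i
      drop[victim] <- TRUE
      report <- rbind(report, data.frame(
        id = ids[victim], stage = "duplicate",
        reason = "identity-by-state above duplicate threshold",
        statistic = ibsSim[i, j], stringsAsFactors = FALSE))
    }
    oh <- opposingHomozygotes(g)
    repeat {
      alive <- which(!drop)
      if (length(alive) < 2) break
      pa <- pairIndices(length(alive))
      ai <- alive[pa[, 1]]; aj <- alive[pa[, 2]]
      flag <- oh[cbind(ai, aj)] < params$opposingHomMax
      if (!any(flag)) break
      inPairs <- table(c(ai[flag], aj[flag]))
      top <- as.integer(names(inPairs)[inPairs == max(inPairs)])
      victim <- if (max(inPairs) > 1) {
        top[1]
      } else {
        # all flags are isolated pairs: drop the higher-missingness member
        i <- ai[flag][1]; j <- aj[flag][1]
        if (miss[j] >= miss[i]) j else i
      }
      drop[victim] <- TRUE
      report <- rbind(report, data.frame(
        id = ids[victim], stage = "relatedness",
        reason = "opposing-homozygote count below relatedness threshold",
        statistic = min(oh[victim, alive[alive != victim]]),
        stringsAsFactors = FALSE))
    }
  }
  list(genotypes = g[which(!drop), ], report = report)
}

#' Method-of-moments pairwise identity-by-descent estimates
#'
#' PLINK-style estimator: observed identity-by-state class counts are
#' compared with their expectations under IBD states 0/1/2 given panel
#' allele frequencies, yielding P(IBD=0), P(IBD=1), P(IBD=2) and
#' `pi-hat = P(IBD=1)/2 + P(IBD=2)` per pair. Probabilities are clamped to
#' \[0,1\] and renormalized.
#'
#' @param g a [GenotypeData-class] object.
#' @return data.frame with columns `id_a`, `id_b`, `z0`, `z1`, `z2`,
#'   `pi_hat`.
#' @export
pairwiseIbd <- function(g) {
  cl <- genotypeCalls(g)
  n <- nIndividuals(g)
  if (n < 2) stop("need at least two individuals")
  ok <- !is.na(cl)
  nn <- colSums(ok)
  p <- colSums(cl, na.rm = TRUE) / (2 * pmax(nn, 1))
  use <- nn > 0 & p > 0 & p < 1
  cl <- cl[, use, drop = FALSE]; ok <- ok[, use, drop = FALSE]
  p <- p[use]; q <- 1 - p
  # per-locus expected IBS-class probabilities given IBD state
  e0.ibd0 <- 2 * p^2 * q^2
  e1.ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2.ibd0 <- 1 - e0.ibd0 - e1.ibd0
  e1.ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2.ibd1 <- 1 - e1.ibd1
  I0 <- ok & cl == 0L; I1 <- ok & cl == 1L; I2 <- ok & cl == 2L
  storage.mode(I0) <- "numeric"; storage.mode(I1) <- "numeric"
  storage.mode(I2) <- "numeric"
  OK <- ok; storage.mode(OK) <- "numeric"
  ibs0 <- I0 %*% t(I2); ibs0 <- ibs0 + t(ibs0)
  joint <- OK %*% t(OK)
  ibs2 <- (I0 %*% t(I0) + I1 %*% t(I1) + I2 %*% t(I2))
  ibs1 <- joint - ibs0 - ibs2
  # expectations are per-locus sums; pairwise missingness ignored (dense
  # panels) so scale by the fraction of jointly observed loci
  E0 <- sum(e0.ibd0); E1.0 <- sum(e1.ibd0); E2.0 <- sum(e2.ibd0)
  E1.1 <- sum(e1.ibd1); E2.1 <- sum(e2.ibd1)
  L <- length(p)
  pr <- pairIndices(n)
  sc <- joint[pr] / L
  z0 <- ibs0[pr] / (E0 * sc)
  z1 <- (ibs1[pr] - z0 * E1.0 * sc) / (E1.1 * sc)
  # E[IBS2 | IBD2] = 1 at every locus, so the denominator is the joint count
  z2 <- (ibs2[pr] - z0 * E2.0 * sc - z1 * E2.1 * sc) / (sc * L)
  z0 <- pmin(pmax(z0, 0), 1); z1 <- pmin(pmax(z1, 0), 1)
  z2 <- pmin(pmax(z2, 0), 1)
  tot <- z0 + z1 + z2
  z0 <- z0 / tot; z1 <- z1 / tot; z2 <- z2 / tot
  ids <- individuals(g)$sample_id
  data.frame(id_a = ids[pr[, 1]], id_b = ids[pr[, 2]],
             z0 = z0, z1 = z1, z2 = z2, pi_hat = z1 / 2 + z2,
             stringsAsFactors = FALSE)
}

#' Kinship filter at second-degree relatedness
#'
#' Greedily removes individuals until no pair exceeds `kinshipMax` in
#' pi-hat (default 0.25, the conventional midpoint separating second- from
#' third-degree relatives). At each step the individual involved in the most
#' offending pairs is removed (ties broken by higher missingness, then
#' input order).
#'
#' @inheritParams filterCallRateMaf
#' @return list with `genotypes` and `report`.
#' @export
kinshipFilterSecondDegree <- function(g, params = qcParams()) {
  report <- emptyRemovalReport()
  if (nIndividuals(g) < 2)
    return(list(genotypes = g, report = report))
  ibd <- pairwiseIbd(g)
  ids <- individuals(g)$sample_id
  miss <- missingRate(g); names(miss) <- ids
  drop <- character()
  repeat {
    off <- ibd[!(ibd$id_a %in% drop) & !(ibd$id_b %in% drop) &
                 ibd$pi_hat > params$kinshipMax, ]
    if (nrow(off) == 0) break
    cnt <- table(c(off$id_a, off$id_b))
    top <- names(cnt)[cnt == max(cnt)]
    victim <- top[order(-miss[top], match(top, ids))][1]
    drop <- c(drop, victim)
    report <- rbind(report, data.frame(
      id = victim, stage = "kinship",
      reason = "pi-hat above second-degree threshold",
      statistic = max(off$pi_hat[off$id_a == victim | off$id_b == victim]),
      stringsAsFactors = FALSE))
  }
  keep <- which(!(ids %in% drop))
  list(genotypes = g[keep, ], report = report)
}

#' Representative within-breed subsampling
#'
#' Reduces each breed exceeding `maxN` individuals to exactly `maxN`,
#' keeping a subset chosen by farthest-point traversal on the within-breed
#' identity-by-state distance matrix: starting from a seeded random
#' individual, each step adds the individual farthest (in minimum distance)
#' from those already kept. This preserves the spread of within-breed
#' diversity. Breeds at or below `maxN` are untouched.
#'
#' @param g a [GenotypeData-class] object.
#' @param maxN maximum individuals per breed (>= 2).
#' @param seed integer seed for the traversal start.
#' @return a [GenotypeData-class] with at most `maxN` individuals per breed.
#' @export
representativeSubsample <- function(g, maxN = 30L, seed = 1L) {
  stopifnot(maxN >= 2)
  br <- breeds(g)
  keep <- logical(nIndividuals(g))
  set.seed(seed)
  for (b in unique(br)) {
    idx <- which(br == b)
    if (length(idx) <= maxN) {
      keep[idx] <- TRUE
      next
    }
    d <- ibsDistance(g[idx, ])
    sel <- sample.int(length(idx), 1L)
    minD <- d[, sel]
    while (length(sel) < maxN) {
      cand <- which.max(replace(minD, sel, -Inf))
      sel <- c(sel, cand)
      minD <- pmin(minD, d[, cand])
    }
    keep[idx[sel]] <- TRUE
  }
  g[which(keep), ]
}
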