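#' Simulation settings for structured multi-breed genotypes
#'
#' Bundles the parameters of [simulateDataset()]. Defaults describe a
#' moderately differentiated set of local breeds sampled along a single
#' environmental gradient: breed allele frequencies at neutral loci drift
#' around an ancestral frequency under the Balding-Nichols model with
#' differentiation `fst`, while "adaptive" loci follow a linear cline in the
#' environmental variable. Genotypes are drawn under Hardy-Weinberg within
#' breed and emitted phased, so identity-by-descent segments can be planted
#' by copying haplotype stretches verbatim between designated pairs.
#'
#' @param nBreeds number of breeds.
#' @param nPerBreed individuals per breed (recycled to `nBreeds`).
#' @param nSnpsNeutral,nSnpsAdaptive neutral and cline-following locus counts.
#' @param fst Balding-Nichols differentiation parameter, in (0, 1). With
#'   clusters this is the within-cluster (breed-level) drift.
#' @param nClusters optional number of ancestral clusters (`NULL`, the
#'   default, for a single panmictic ancestor). Breeds are assigned
#'   round-robin to clusters; cluster allele frequencies drift from the
#'   ancestor with parameter `fstBetween` and breeds then drift from their
#'   cluster with parameter `fst`. This emulates panels whose breeds fall
#'   into a few deep historical groups with shallow differentiation inside
#'   each group.
#' @param fstBetween cluster-level drift parameter (used when `nClusters`
#'   is set).
#' @param envName name of the environmental variable.
#' @param env per-breed current value of the variable; default an equally
#'   spaced 0..1 gradient (a stylized north-south cline).
#' @param envFuture per-breed future value; default `env - 0.1`, a uniform
#'   shift toward the low end of the gradient.
#' @param clineAlpha intercept of the adaptive cline (allele frequency at
#'   `env = 0`).
#' @param clineBeta slope of the adaptive cline (frequency change per unit
#'   of the variable). Cline frequencies are clamped to \[0.02, 0.98\] so
#'   planted loci stay polymorphic under a 5% MAF filter.
#' @param ibdPlan optional data.frame with columns `breed_a`, `breed_b`,
#'   `n_pairs`, `length_bp`: plant `n_pairs` identical haplotype segments of
#'   the given physical length between the two breeds.
#' @param missingRate fraction of calls masked at random (default 0).
#' @param snpSpacingBp physical distance between adjacent loci on the single
#'   simulated chromosome.
#' @param seed integer seed; the same configuration and seed give a
#'   bit-identical dataset.
#' @return a list of class `simulation_config`.
#' @export
simulationConfig <- function(nBreeds = 10, nPerBreed = 30,
                             nSnpsNeutral = 500, nSnpsAdaptive = 20,
                             fst = 0.05, nClusters = NULL, fstBetween = 0.05,
                             envName = "BIO3",
                             env = NULL, envFuture = NULL,
                             clineAlpha = 0.3, clineBeta = 0.4,
                             ibdPlan = NULL, missingRate = 0,
                             snpSpacingBp = 10000L, seed = 1L) {
  if (nBreeds < 1 || nSnpsNeutral + nSnpsAdaptive < 1)
    stop("counts must be positive")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  nPerBreed <- rep_len(nPerBreed, nBreeds)
  if (is.null(env)) {
    env <- if (nBreeds == 1) 0.5 else seq(0, 1, length.out = nBreeds)
  }
  if (is.null(envFuture)) envFuture <- env - 0.1
  stopifnot(length(env) == nBreeds, length(envFuture) == nBreeds)
  if (!is.null(nClusters) && (fstBetween <= 0 || fstBetween >= 1))
    stop("fstBetween must lie in (0, 1)")
  cfg <- list(nBreeds = nBreeds, nPerBreed = nPerBreed,
              nSnpsNeutral = nSnpsNeutral, nSnpsAdaptive = nSnpsAdaptive,
              fst = fst, nClusters = nClusters, fstBetween = fstBetween,
              envName = envName, env = env, envFuture = envFuture,
              clineAlpha = clineAlpha, clineBeta = clineBeta,
              ibdPlan = ibdPlan, missingRate = missingRate,
              snpSpacingBp = as.integer(snpSpacingBp), seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a structured multi-breed genotype dataset
#'
#' Draws breed allele frequencies under the Balding-Nichols model
#' (Beta with mean the ancestral frequency and variance
#' `fst * p * (1 - p)`), overlays adaptive loci whose breed frequencies are
#' `clamp(alpha + beta * env_breed, 0.02, 0.98)`, samples two haplotype
#' alleles per individual per locus (hence Hardy-Weinberg genotypes within
#' breed), plants identical haplotype segments between designated breed
#' pairs, and returns the phased genotypes together with the environmental
#' table and a truth record.
#'
#' @param cfg a [simulationConfig()] list.
#' @return list with elements:
#'   \describe{
#'     \item{genotypes}{a phased [GenotypeData-class];}
#'     \item{env}{long data.frame (`breed`, `variable`, `epoch`, `value`)
#'       with current and future epochs;}
#'     \item{truth}{list with `adaptive_snps`, `cline_alpha`, `cline_beta`,
#'       `breed_freqs` (breeds x loci matrix of generating frequencies) and
#'       `ibd_segments` (planted segments, same columns as
#'       [readIbdSegments()]).}
#'   }
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  nB <- cfg$nBreeds
  nS <- cfg$nSnpsNeutral + cfg$nSnpsAdaptive
  breedCodes <- sprintf("BR%02d", seq_len(nB))
  nInd <- sum(cfg$nPerBreed)
  breedOf <- rep(breedCodes, cfg$nPerBreed)

  positions <- as.integer(seq_len(nS)) * cfg$snpSpacingBp
  chromLen <- positions[nS]
  if (!is.null(cfg$ibdPlan) && any(cfg$ibdPlan$length_bp > chromLen))
    stop("infeasible ibd plan: segment longer than the simulated chromosome")

  # breed frequencies: neutral Balding-Nichols (optionally hierarchical:
  # ancestor -> cluster -> breed), adaptive linear cline
  p0 <- stats::runif(cfg$nSnpsNeutral, 0.1, 0.9)
  freqs <- matrix(NA_real_, nB, nS)
  bnDraw <- function(p, F) {
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  if (cfg$nSnpsNeutral > 0) {
    if (is.null(cfg$nClusters)) {
      for (k in seq_len(nB))
        freqs[k, seq_len(cfg$nSnpsNeutral)] <- bnDraw(p0, cfg$fst)
    } else {
      clusterOf <- (seq_len(nB) - 1L) %% cfg$nClusters + 1L
      pc <- matrix(NA_real_, cfg$nClusters, cfg$nSnpsNeutral)
      for (cI in seq_len(cfg$nClusters))
        pc[cI, ] <- bnDraw(p0, cfg$fstBetween)
      for (k in seq_len(nB))
        freqs[k, seq_len(cfg$nSnpsNeutral)] <- bnDraw(pc[clusterOf[k], ], cfg$fst)
    }
  }
  if (cfg$nSnpsAdaptive > 0) {
    idxA <- cfg$nSnpsNeutral + seq_len(cfg$nSnpsAdaptive)
    for (k in seq_len(nB)) {
      p <- cfg$clineAlpha + cfg$clineBeta * cfg$env[k]
      freqs[k, idxA] <- pmin(pmax(p, 0.02), 0.98)
    }
  }

  hap1 <- matrix(0L, nInd, nS)
  hap2 <- matrix(0L, nInd, nS)
  for (k in seq_len(nB)) {
    rows <- which(breedOf == breedCodes[k])
    pk <- freqs[k, ]
    nk <- length(rows)
    hap1[rows, ] <- matrix(stats::rbinom(nk * nS, 1L, rep(pk, each = nk)), nk, nS)
    hap2[rows, ] <- matrix(stats::rbinom(nk * nS, 1L, rep(pk, each = nk)), nk, nS)
  }

  sampleIds <- paste0(breedOf, "_", sequence(cfg$nPerBreed))

  # plant identity-by-descent segments: copy a haplotype stretch verbatim
  planted <- NULL
  if (!is.null(cfg$ibdPlan)) {
    recs <- list()
    for (r in seq_len(nrow(cfg$ibdPlan))) {
      pl <- cfg$ibdPlan[r, ]
      ia <- which(breedOf == pl$breed_a)
      ib <- which(breedOf == pl$breed_b)
      if (!length(ia) || !length(ib))
        stop("ibd plan names an unknown breed: ", pl$breed_a, "/", pl$breed_b)
      nSeg <- ceiling(pl$length_bp / cfg$snpSpacingBp)
      if (nSeg > nS) stop("infeasible ibd plan: segment longer than the simulated chromosome")
      start <- sample.int(nS - nSeg + 1L, 1L)
      idx <- start:(start + nSeg - 1L)
      for (t in seq_len(pl$n_pairs)) {
        # cycle donors and recipients so each plant lands on a fresh
        # recipient haplotype while n_pairs <= 2 * n_recipients
        sa <- ia[(t - 1L) %% length(ia) + 1L]
        sb <- ib[(t - 1L) %% length(ib) + 1L]
        ha <- ((t - 1L) %/% length(ib)) %% 2L + 1L
        src <- if (ha == 1L) hap1 else hap2
        if (ha == 1L) hap1[sb, idx] <- src[sa, idx] else hap2[sb, idx] <- src[sa, idx]
        recs[[length(recs) + 1L]] <- data.frame(
          sample_a = sampleIds[sa], hap_a = ha,
          sample_b = sampleIds[sb], hap_b = ha,
          chromosome = "1",
          start_bp = positions[idx[1]], end_bp = positions[idx[nSeg]],
          stringsAsFactors = FALSE)
      }
    }
    planted <- do.call(rbind, recs)
  }

  calls <- hap1 + hap2
  if (cfg$missingRate > 0) {
    mask <- stats::runif(length(calls)) < cfg$missingRate
    calls[mask] <- NA_integer_
  }

  snpIds <- c(sprintf("neut%05d", seq_len(cfg$nSnpsNeutral)),
              sprintf("adap%05d", seq_len(cfg$nSnpsAdaptive)))
  snpIds <- snpIds[order(c(seq_len(cfg$nSnpsNeutral),
                           cfg$nSnpsNeutral + seq_len(cfg$nSnpsAdaptive)))]
  loc <- data.frame(snp_id = snpIds, chromosome = "1",
                    position_bp = positions,
                    allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  ind <- data.frame(sample_id = sampleIds, breed = breedOf,
                    latitude = rep(46 - 8 * cfg$env, cfg$nPerBreed),
                    longitude = rep(seq(8, 16, length.out = nB), cfg$nPerBreed),
                    stringsAsFactors = FALSE)
  g <- GenotypeData(calls = calls, individuals = ind, loci = loc,
                    haplotypes = list(hap1 = hap1, hap2 = hap2))

  env <- rbind(
    data.frame(breed = breedCodes, variable = cfg$envName,
               epoch = "current", value = cfg$env, stringsAsFactors = FALSE),
    data.frame(breed = breedCodes, variable = cfg$envName,
               epoch = "future", value = cfg$envFuture, stringsAsFactors = FALSE))

  dimnames(freqs) <- list(breedCodes, snpIds)
  truth <- list(
    adaptive_snps = snpIds[grepl("^adap", snpIds)],
    cline_alpha = cfg$clineAlpha, cline_beta = cfg$clineBeta,
    breed_freqs = freqs, ibd_segments = planted, seed = cfg$seed)

  list(genotypes = g, env = env, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the PLINK PED/MAP pair, a phased-haplotype table, the environmental
#' table (TSV) and the truth record (JSON) into a directory.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, "genotypes.ped"),
             map = file.path(dir, "genotypes.map"),
             hap = file.path(dir, "haplotypes.tsv"),
             env = file.path(dir, "environment.tsv"),
             truth = file.path(dir, "truth.json"))
  writePlinkText(sim$genotypes, paths["ped"], paths["map"])
  h <- haplotypes(sim$genotypes)
  hapTab <- data.frame(sample_id = rep(individuals(sim$genotypes)$sample_id, each = 2),
                       hap = rep(1:2, nIndividuals(sim$genotypes)))
  alle <- matrix(NA_integer_, nrow(hapTab), nLoci(sim$genotypes))
  alle[seq(1, nrow(hapTab), 2), ] <- h$hap1
  alle[seq(2, nrow(hapTab), 2), ] <- h$hap2
  utils::write.table(cbind(hapTab, alle), paths["hap"], quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$env, paths["env"], quote = FALSE, sep = "\t",
                     row.names = FALSE)
  truth <- sim$truth
  truth$breed_freqs <- NULL  # bulky; regenerable from the seed
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}

#' Weir-Cockerham fixation index over loci
#'
#' Multi-population Weir-Cockerham theta estimator, averaged over loci as
#' ratio-of-sums. Used to check that simulated datasets realize the
#' differentiation they were configured with.
#'
#' @param g a [GenotypeData-class] object.
#' @param lociIdx optional locus subset (indices or snp_ids).
#' @return scalar FST estimate.
#' @export
wcFst <- function(g, lociIdx = NULL) {
  cl <- genotypeCalls(g)
  if (!is.null(lociIdx)) {
    if (is.character(lociIdx)) lociIdx <- match(lociIdx, loci(g)$snp_id)
    cl <- cl[, lociIdx, drop = FALSE]
  }
  pop <- factor(breeds(g))
  r <- nlevels(pop)
  numSum <- 0; denSum <- 0
  for (j in seq_len(ncol(cl))) {
    x <- cl[, j]
    ok <- !is.na(x)
    ni <- tapply(ok, pop, sum)
    if (any(ni < 2)) next
    pi <- tapply(ifelse(ok, x, 0), pop, sum) / (2 * ni)
    hi <- tapply(ok & x == 1, pop, sum) / ni   # observed het share
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    numSum <- numSum + a
    denSum <- denSum + a + b + cc
  }
  numSum / denSum
}
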