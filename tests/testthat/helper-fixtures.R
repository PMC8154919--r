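# Small in-code fixture builders shared across the suite.

# GenotypeData from a bare call matrix; one chromosome, 10 kb spacing.
makeGeno <- function(calls, breeds = rep("BRD", nrow(calls)),
                     haplotypes = list(), spacingBp = 10000L) {
  n <- nrow(calls); m <- ncol(calls)
  GenotypeData(
    calls = calls,
    individuals = data.frame(sample_id = sprintf("ind%03d", seq_len(n)),
                             breed = breeds, stringsAsFactors = FALSE),
    loci = data.frame(snp_id = sprintf("snp%04d", seq_len(m)),
                      chromosome = "1",
                      position_bp = seq_len(m) * spacingBp,
                      allele_a = "A", allele_b = "G",
                      stringsAsFactors = FALSE),
    haplotypes = haplotypes)
}

# Genotypes sampled under Hardy-Weinberg from per-individual locus freqs.
sampleHw <- function(freqRows) {
  matrix(stats::rbinom(length(freqRows), 2L, freqRows),
         nrow(freqRows), ncol(freqRows))
}

# Reference implementations used as independent oracles ------------------

# Benjamini-Hochberg by the literal step-up definition.
bhBruteForce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)        # rank of p[i]
    q[i] <- min(1, min(p[o][j:m] * m / (j:m)))
  }
  q
}

# Reynolds theta summed locus by locus over both alleles.
reynoldsBruteForce <- function(p1, p2) {
  num <- 0; den <- 0
  for (l in seq_along(p1)) {
    a1 <- c(p1[l], 1 - p1[l]); a2 <- c(p2[l], 1 - p2[l])
    num <- num + sum((a1 - a2)^2)
    den <- den + 2 * (1 - sum(a1 * a2))
  }
  num / den
}

# Full pairwise LD scan in map order (oracle for the windowed prune).
ldPruneBruteForce <- function(calls, r2max) {
  m <- ncol(calls)
  keep <- rep(TRUE, m)
  for (i in seq_len(m - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):m) {
      if (!keep[j]) next
      r2 <- suppressWarnings(
        stats::cor(calls[, i], calls[, j], use = "pairwise.complete.obs"))^2
      if (!is.na(r2) && r2 > r2max) keep[j] <- FALSE
    }
  }
  keep
}

# Write a tiny PED/MAP pair; genos is a list of per-individual allele
# strings like c("A A", "A G", "0 0").
writeTinyPlink <- function(dir, genos, breeds, nSnp) {
  ped <- file.path(dir, "tiny.ped"); map <- file.path(dir, "tiny.map")
  writeLines(sprintf("1\tsnp%d\t0\t%d", seq_len(nSnp), seq_len(nSnp) * 1000),
             map)
  lines <- vapply(seq_along(genos), function(i)
    paste(breeds[i], paste0("s", i), 0, 0, 0, -9, genos[i]), "")
  writeLines(lines, ped)
  c(ped = ped, map = map)
}
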