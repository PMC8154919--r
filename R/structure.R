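#' Identity-by-state distance matrix
#'
#' For every pair of individuals, `d = 1 - (shared alleles) / (2 x jointly
#' non-missing loci)`. At a locus the shared-allele count between genotypes
#' a and b (copies of the B allele) is `2 - |a - b|`. Missing calls are
#' handled pairwise, as in PLINK, not imputed.
#'
#' @param g a [GenotypeData-class] object with at least two individuals.
#' @return symmetric matrix with zero diagonal, labelled by sample_id.
#' @export
ibsDistance <- function(g) {
  if (nIndividuals(g) < 2) stop("need at least two individuals")
  cl <- genotypeCalls(g)
  X <- cl; X[is.na(X)] <- 0L
  storage.mode(X) <- "numeric"
  M <- (!is.na(cl)) * 1
  X2 <- X^2
  # sum over jointly observed loci of (a - b)^2
  sq <- X2 %*% t(M) - 2 * X %*% t(X) + M %*% t(X2)
  I0 <- (M == 1 & X == 0) * 1
  I2 <- (M == 1 & X == 2) * 1
  opp <- I0 %*% t(I2); opp <- opp + t(opp)
  absdiff <- sq - 2 * opp       # |a-b| = (a-b)^2 except |a-b| = 2 where it is 4
  joint <- M %*% t(M)
  if (any(joint[upper.tri(joint)] == 0)) {
    pr <- pairIndices(nrow(joint))
    bad <- pr[joint[pr] == 0, , drop = FALSE][1, ]
    stop(sprintf("no jointly non-missing loci for pair %s / %s",
                 individuals(g)$sample_id[bad[1]],
                 individuals(g)$sample_id[bad[2]]))
  }
  d <- absdiff / (2 * joint)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(individuals(g)$sample_id, individuals(g)$sample_id)
  d
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of a distance matrix: double-center `-D^2/2`,
#' eigendecompose, and return the top-`k` coordinates scaled by the square
#' root of the eigenvalues. Negative eigenvalues are excluded from the
#' variance proportions. If fewer than `k` positive eigenvalues exist the
#' embedding is truncated with a warning.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param k number of axes requested.
#' @return list with `coordinates` (n x k'), `eigenvalues` and
#'   `varianceProportion` per returned axis.
#' @export
classicalMds <- function(d, k = 2) {
  stopifnot(k >= 1)
  d <- as.matrix(d)
  res <- stats::cmdscale(stats::as.dist(d), k = min(k, nrow(d) - 1),
                         eig = TRUE)
  eig <- res$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  kEff <- min(k, length(pos))
  if (kEff < k)
    warning(sprintf("only %d positive eigenvalues; returning %d axes",
                    length(pos), kEff))
  coords <- res$points[, seq_len(kEff), drop = FALSE]
  colnames(coords) <- paste0("C", seq_len(kEff))
  list(coordinates = coords,
       eigenvalues = eig[seq_len(kEff)],
       varianceProportion = eig[seq_len(kEff)] / sum(pos))
}

#' Reynolds genetic distance between two populations
#'
#' Co-ancestry coefficient theta of Reynolds, Weir and Cockerham for
#' biallelic loci:
#' `theta = sum_l (p1 - p2)^2 / sum_l (1 - p1 p2 - q1 q2)`
#' (the per-locus numerator `(p1-p2)^2 + (q1-q2)^2` and denominator
#' `2 (1 - p1 p2 - q1 q2)` both carry a factor 2 that cancels). Loci with a
#' frequency missing in either population are skipped. Variants `sqrt`
#' (the distance metric form) and `-ln(1 - theta)` (drift time scale) are
#' selectable; the plain coefficient is the default.
#'
#' @param p1,p2 numeric vectors of B-allele frequencies on a shared locus
#'   set.
#' @param variant `"theta"` (default), `"sqrt"` or `"log"`.
#' @return nonnegative scalar.
#' @export
reynoldsDistance <- function(p1, p2, variant = c("theta", "sqrt", "log")) {
  variant <- match.arg(variant)
  stopifnot(length(p1) == length(p2))
  ok <- !is.na(p1) & !is.na(p2)
  if (!any(ok)) stop("no shared loci with frequencies in both populations")
  p1 <- p1[ok]; p2 <- p2[ok]
  num <- sum((p1 - p2)^2)
  den <- sum(1 - p1 * p2 - (1 - p1) * (1 - p2))
  theta <- if (den == 0) 0 else num / den
  switch(variant,
         theta = theta,
         sqrt = sqrt(theta),
         log = -log(1 - min(theta, 1 - 1e-12)))
}

#' Reynolds distance matrix across breeds
#'
#' @param freqs breeds x loci matrix of B-allele frequencies (see
#'   [frequencyMatrix()]).
#' @inheritParams reynoldsDistance
#' @return symmetric matrix labelled by breed.
#' @export
reynoldsMatrix <- function(freqs, variant = "theta") {
  nB <- nrow(freqs)
  d <- matrix(0, nB, nB, dimnames = list(rownames(freqs), rownames(freqs)))
  for (i in seq_len(nB - 1)) {
    for (j in (i + 1):nB) {
      d[i, j] <- d[j, i] <- reynoldsDistance(freqs[i, ], freqs[j, ],
                                             variant = variant)
    }
  }
  d
}

#' Bootstrap neighbor-joining tree on Reynolds distances
#'
#' Computes breed allele frequencies, builds the Saitou-Nei neighbor-joining
#' tree from the Reynolds distance matrix, and assesses support by
#' resampling loci with replacement `nBoot` times (individuals fixed).
#' Supports are the percentage of replicates containing each bipartition of
#' the majority-rule consensus, stored in the trees' node labels. The point
#' estimate (with branch lengths) is rooted on the outgroup for display.
#'
#' @param g a [GenotypeData-class] with at least three breeds.
#' @param nBoot bootstrap replicates (default 100).
#' @param seed integer seed for the locus resampling.
#' @param outgroup breed code used to root the displayed tree, or `NULL`.
#' @param variant Reynolds variant, see [reynoldsDistance()].
#' @param keepReplicates keep the list of replicate trees (for diagnostics).
#' @return list with `tree` (point-estimate `phylo`, node labels carrying
#'   supports), `consensus` (majority-rule `phylo`), `support` (named
#'   percentages per consensus bipartition) and optionally `replicates`.
#' @export
njBootstrapTree <- function(g, nBoot = 100, seed = 1L, outgroup = NULL,
                            variant = "theta", keepReplicates = FALSE) {
  freqs <- frequencyMatrix(g)
  if (nrow(freqs) < 3) stop("need at least three breeds")
  if (!is.null(outgroup) && !outgroup %in% rownames(freqs))
    stop("outgroup '", outgroup, "' is not a breed in the panel")
  point <- ape::nj(stats::as.dist(reynoldsMatrix(freqs, variant)))
  set.seed(seed)
  L <- ncol(freqs)
  reps <- vector("list", nBoot)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(L, L, replace = TRUE)
    reps[[b]] <- ape::nj(stats::as.dist(
      reynoldsMatrix(freqs[, idx, drop = FALSE], variant)))
  }
  cons <- ape::consensus(reps, p = 0.5)
  cla <- ape::prop.clades(cons, reps, rooted = FALSE)
  cla[is.na(cla)] <- 0
  support <- round(100 * cla / nBoot, 1)
  cons$node.label <- as.character(support)
  pointClades <- ape::prop.clades(point, reps, rooted = FALSE)
  pointClades[is.na(pointClades)] <- 0
  point$node.label <- as.character(round(100 * pointClades / nBoot, 1))
  if (!is.null(outgroup))
    point <- ape::root(point, outgroup = outgroup, resolve.root = TRUE)
  out <- list(tree = point, consensus = cons, support = support,
              nBoot = nBoot)
  if (keepReplicates) out$replicates <- reps
  out
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d symmetric labelled matrix.
#' @param path output path.
#' @export
writePhylipDistances <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  lab <- sprintf("%-10s", substr(rownames(d), 1, 10))
  for (i in seq_len(nrow(d)))
    writeLines(paste0(lab[i], paste(sprintf("%.6f", d[i, ]), collapse = " ")),
               con)
  invisible(path)
}
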