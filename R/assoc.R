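#' Population-structure covariates via principal components
#'
#' PCA on the centered, unit-variance genotype matrix (missing calls
#' mean-imputed per locus for the decomposition only; monomorphic loci
#' dropped). With `k = "auto"` the number of retained components is the
#' count of eigenvalues exceeding the broken-stick expectation, with a
#' floor of 2.
#'
#' @param g a [GenotypeData-class] object with at least two individuals.
#' @param k number of components, or `"auto"` (default).
#' @return list with `scores` (n x k, centered), `k`, `varianceExplained`
#'   per retained component, and `method` ("fixed" or "broken-stick").
#' @export
structurePca <- function(g, k = "auto") {
  if (nIndividuals(g) < 2) stop("need at least two individuals")
  X <- genotypeCalls(g)
  storage.mode(X) <- "numeric"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu[j]
  }
  v <- apply(X, 2, stats::var)
  X <- X[, v > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  prop <- ev / sum(ev)
  method <- "fixed"
  if (identical(k, "auto")) {
    p <- length(ev)
    bs <- rev(cumsum(1 / rev(seq_len(p)))) / p   # broken-stick expectations
    # leading run of components above expectation, floored at two
    below <- which(prop <= bs)
    k <- max(2L, if (length(below)) below[1] - 1L else p)
    method <- "broken-stick"
  }
  k <- min(as.integer(k), ncol(pc$x))
  if (k < 1) stop("no usable components")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scores <- scale(scores, center = TRUE, scale = FALSE)
  rownames(scores) <- individuals(g)$sample_id
  list(scores = scores, k = k, varianceExplained = prop[seq_len(k)],
       method = method)
}

#' Per-locus binary genotype indicators
#'
#' The per-genotype response coding of Samvada-style landscape genomics:
#' at each biallelic locus, up to three binary vectors mark the presence of
#' the homozygous-A, heterozygous and homozygous-B genotypes. Genotypes
#' observed in fewer than `minCount` individuals are skipped, as are
#' degenerate indicators that are constant over the observed calls (e.g.
#' the single genotype of a monomorphic locus). Missing calls stay `NA` and
#' are excluded from that locus's tests.
#'
#' @param g a [GenotypeData-class] object.
#' @param minCount minimum carrier count for a genotype to be tested
#'   (default 5).
#' @return list (one element per locus, named by snp_id) of lists with
#'   `label` (e.g. "AG"), `code` (0/1/2) and `y` (0/1/NA vector).
#' @export
genotypeIndicators <- function(g, minCount = 5L) {
  cl <- genotypeCalls(g)
  loc <- loci(g)
  out <- vector("list", nLoci(g))
  names(out) <- loc$snp_id
  for (j in seq_len(nLoci(g))) {
    x <- cl[, j]
    lab <- c(paste0(loc$allele_a[j], loc$allele_a[j]),
             paste0(loc$allele_a[j], loc$allele_b[j]),
             paste0(loc$allele_b[j], loc$allele_b[j]))
    keep <- list()
    for (code in 0:2) {
      y <- as.integer(x == code)
      nCarrier <- sum(y == 1L, na.rm = TRUE)
      nOther <- sum(y == 0L, na.rm = TRUE)
      if (nCarrier < minCount) next
      if (nOther == 0) next   # constant response: degenerate
      keep[[length(keep) + 1L]] <- list(label = lab[code + 1L],
                                        code = code, y = y)
    }
    out[[j]] <- keep
  }
  out
}

#' Logistic likelihood-ratio test for one genotype and one variable
#'
#' Fits two logistic regressions by iteratively reweighted least squares
#' (at most 50 iterations, deviance tolerance 1e-8): the null model with
#' the structure covariates alone and the alternative adding the focal
#' environmental variable (standardized internally). The statistic is
#' `G = deviance_null - deviance_alt`, referred to a chi-square with one
#' degree of freedom. Non-convergence or separation (diverging
#' coefficients) is flagged; the result is retained.
#'
#' @param y binary response (0/1, `NA` allowed and dropped).
#' @param x environmental variable, one value per individual.
#' @param S structure covariate matrix (or the list from
#'   [structurePca()]).
#' @return one-row data.frame: `deviance_null`, `deviance_alt`, `G`,
#'   `p_value`, `effect_sign`, `converged`.
#' @export
lrtAssociation <- function(y, x, S) {
  if (is.list(S) && !is.null(S$scores)) S <- S$scores
  S <- as.matrix(S)
  ok <- !is.na(y) & !is.na(x) & stats::complete.cases(S)
  y <- y[ok]; x <- x[ok]; S <- S[ok, , drop = FALSE]
  if (length(unique(y)) < 2) stop("degenerate response: y is constant")
  sdx <- stats::sd(x)
  xs <- if (sdx > 0) (x - mean(x)) / sdx else x - mean(x)
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 50)
  X0 <- cbind(`(Intercept)` = 1, S)
  X1 <- cbind(X0, env = xs)
  f0 <- suppressWarnings(
    stats::glm.fit(X0, y, family = stats::binomial(), control = ctrl))
  f1 <- suppressWarnings(
    stats::glm.fit(X1, y, family = stats::binomial(), control = ctrl))
  G <- max(f0$deviance - f1$deviance, 0)
  beta <- f1$coefficients[["env"]]
  sep <- is.na(beta) || abs(beta) > 15
  data.frame(deviance_null = f0$deviance, deviance_alt = f1$deviance,
             G = G, p_value = stats::pchisq(G, df = 1, lower.tail = FALSE),
             effect_sign = sign(ifelse(is.na(beta), 0, beta)),
             converged = f0$converged && f1$converged && !sep)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The classic step-up q-values: order the m p-values increasingly,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to input order.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Genome-wide genotype-environment association scan
#'
#' Runs [lrtAssociation()] for every (locus, genotype indicator,
#' environmental variable) combination, with principal-component structure
#' correction, and applies Benjamini-Hochberg control over the pooled
#' family of tests (`bhFamily = "pooled"`) or within each variable
#' (`"per_variable"`).
#'
#' @param g a [GenotypeData-class] object.
#' @param envTable long environmental table (`breed` or `id`, `variable`,
#'   `epoch`, `value`); current-epoch values are used. Breed-level values
#'   are expanded to individuals through the breed code.
#' @param variables which variables to test (default: all in the table).
#' @param k principal components to keep, or `"auto"`; alternatively pass
#'   a precomputed [structurePca()] result as `structure`.
#' @param structure optional precomputed structure covariates.
#' @param minCount minimum genotype carrier count (see
#'   [genotypeIndicators()]).
#' @param bhFamily `"pooled"` (default) or `"per_variable"`.
#' @return data.frame with one row per test: `snp_id`, `genotype`,
#'   `variable`, `deviance_null`, `deviance_alt`, `G`, `p_value`,
#'   `q_value`, `effect_sign`, `converged`.
#' @export
runAssociation <- function(g, envTable, variables = NULL, k = "auto",
                           structure = NULL, minCount = 5L,
                           bhFamily = c("pooled", "per_variable")) {
  bhFamily <- match.arg(bhFamily)
  if (is.null(structure)) structure <- structurePca(g, k = k)
  S <- structure$scores
  if (is.null(variables))
    variables <- unique(envTable$variable)
  idCol <- intersect(c("breed", "id"), names(envTable))[1]
  ind <- individuals(g)
  indKey <- if (idCol == "breed") ind$breed else ind$sample_id
  indic <- genotypeIndicators(g, minCount = minCount)
  rows <- list()
  for (v in variables) {
    val <- envValue(envTable, v, "current")
    x <- unname(val[indKey])
    if (all(is.na(x)))
      stop("variable '", v, "' has no current-epoch values matching the panel")
    for (s in seq_along(indic)) {
      for (gi in indic[[s]]) {
        res <- lrtAssociation(gi$y, x, S)
        res$snp_id <- names(indic)[s]
        res$genotype <- gi$label
        res$variable <- v
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(snp_id = character(), genotype = character(),
                      variable = character(), deviance_null = numeric(),
                      deviance_alt = numeric(), G = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      effect_sign = numeric(), converged = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (bhFamily == "pooled") {
    out$q_value <- bhAdjust(out$p_value)
  } else {
    out$q_value <- NA_real_
    for (v in unique(out$variable)) {
      i <- out$variable == v
      out$q_value[i] <- bhAdjust(out$p_value[i])
    }
  }
  out[, c("snp_id", "genotype", "variable", "deviance_null", "deviance_alt",
          "G", "p_value", "q_value", "effect_sign", "converged")]
}

#' Annotate association hits with overlapping genes
#'
#' Genes are supplied BED-style: 0-based half-open intervals. A SNP at
#' 1-based physical position `pos` overlaps a gene `[start, end)` when
#' `start <= pos - 1 < end`, so a SNP on the gene's first base is annotated
#' and one at the exclusive end coordinate is not. A SNP overlapping
#' several genes gets all of them, comma-separated.
#'
#' @param results association results (any data.frame with a `snp_id`
#'   column) to annotate.
#' @param lociTable the panel's locus table ([loci()]) giving each SNP's
#'   chromosome and position.
#' @param genes data.frame with `chromosome`, `start`, `end`, `name`
#'   (0-based half-open).
#' @return `results` with an added `gene` column (`NA` when no overlap).
#' @export
annotateHits <- function(results, lociTable, genes) {
  if (nrow(genes) && any(genes$end <= genes$start))
    stop("malformed gene interval: end <= start")
  results$gene <- NA_character_
  if (!nrow(genes) || !nrow(results)) return(results)
  pos <- lociTable$position_bp[match(results$snp_id, lociTable$snp_id)]
  chr <- lociTable$chromosome[match(results$snp_id, lociTable$snp_id)]
  for (cc in unique(chr)) {
    gi <- genes[genes$chromosome == cc, , drop = FALSE]
    ri <- which(chr == cc)
    if (!nrow(gi) || !length(ri)) next
    snpR <- IRanges::IRanges(start = pos[ri], width = 1L)      # 1-based point
    geneR <- IRanges::IRanges(start = gi$start + 1L, end = gi$end)
    ov <- IRanges::findOverlaps(snpR, geneR)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    o <- order(qh, sh)               # genes reported in table order
    hitGenes <- tapply(gi$name[sh[o]], qh[o], paste, collapse = ",")
    results$gene[ri[as.integer(names(hitGenes))]] <- unname(hitGenes)
  }
  results
}
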