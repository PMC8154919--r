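#' Per-group allele frequencies
#'
#' Computes, for each group (breed by default) and locus, the frequency of
#' the B allele over non-missing calls, `p = (sum of B copies) /
#' (2 * non-missing individuals)`, together with the minor allele frequency
#' `min(p, 1 - p)` and the sample size used.
#'
#' @param g a [GenotypeData-class] object.
#' @param grouping either `"breed"` (default) or a vector of group labels,
#'   one per individual.
#' @return A long data.frame with columns `group`, `snp_id`, `p` (B-allele
#'   frequency), `maf`, `n` (non-missing individuals). `p` is `NA` where a
#'   (group, locus) cell has no non-missing call.
#' @export
alleleFrequencies <- function(g, grouping = "breed") {
  if (identical(grouping, "breed")) grouping <- breeds(g)
  if (length(grouping) != nIndividuals(g))
    stop("grouping must supply one label per individual")
  tab <- table(grouping)   # a factor keeps its empty levels here
  if (any(tab == 0)) stop("empty group: ", names(tab)[tab == 0][1])
  grouping <- as.character(grouping)
  cl <- genotypeCalls(g)
  groups <- sort(unique(grouping))
  out <- lapply(groups, function(gr) {
    sub <- cl[grouping == gr, , drop = FALSE]
    n <- colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / (2 * n)
    p[n == 0] <- NA_real_
    data.frame(group = gr, snp_id = loci(g)$snp_id, p = p,
               maf = pmin(p, 1 - p), n = n,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Breed-by-locus allele-frequency matrix
#'
#' Wide-format companion of [alleleFrequencies()]: rows are groups, columns
#' loci, entries the B-allele frequency.
#'
#' @inheritParams alleleFrequencies
#' @param value `"p"` for the B-allele frequency or `"maf"`.
#' @return numeric matrix, groups x loci.
#' @export
frequencyMatrix <- function(g, grouping = "breed", value = c("p", "maf")) {
  value <- match.arg(value)
  long <- alleleFrequencies(g, grouping)
  groups <- sort(unique(long$group))
  m <- matrix(long[[value]], nrow = length(groups), byrow = TRUE,
              dimnames = list(groups, loci(g)$snp_id))
  m
}
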