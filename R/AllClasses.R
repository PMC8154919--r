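#' @import methods
NULL

#' GenotypeData: multi-breed SNP-array genotypes
#'
#' The central container of the package: an individuals-by-loci matrix of
#' biallelic genotype calls coded as copies of the B allele (0, 1, 2, or
#' `NA` for a missing call), together with per-individual metadata (breed
#' code, optional geographic coordinates) and per-locus metadata (chromosome,
#' 1-based physical position, and the two allele symbols, oriented at load
#' time so that the B allele is by default the minor allele).
#'
#' When `phased` is `TRUE`, two haplotype matrices (same shape as `calls`,
#' binary: 1 = B allele) are carried and their element-wise sum reproduces
#' `calls` at every non-missing entry.
#'
#' @slot calls integer matrix, individuals x loci, values in \{0,1,2,NA\}.
#' @slot individuals data.frame with columns `sample_id`, `breed`, and
#'   optionally `latitude`, `longitude`.
#' @slot loci data.frame with columns `snp_id`, `chromosome`, `position_bp`,
#'   `allele_a`, `allele_b`.
#' @slot phased logical scalar.
#' @slot haplotypes list of two binary matrices (`hap1`, `hap2`) when phased,
#'   empty list otherwise.
#'
#' @seealso [GenotypeData()] for the user-facing constructor,
#'   [readPlinkText()] to build one from PLINK PED/MAP files.
#' @export
setClass("GenotypeData",
  slots = c(
    calls       = "matrix",
    individuals = "data.frame",
    loci        = "data.frame",
    phased      = "logical",
    haplotypes  = "list"
  )
)

setValidity("GenotypeData", function(object) {
  msgs <- character()
  ind <- object@individuals
  loc <- object@loci
  if (!all(c("sample_id", "breed") %in% names(ind)))
    msgs <- c(msgs, "individuals must have columns 'sample_id' and 'breed'")
  need <- c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")
  if (!all(need %in% names(loc)))
    msgs <- c(msgs, sprintf("loci must have columns %s",
                            paste(need, collapse = ", ")))
  if (nrow(object@calls) != nrow(ind))
    msgs <- c(msgs, "nrow(calls) must equal nrow(individuals)")
  if (ncol(object@calls) != nrow(loc))
    msgs <- c(msgs, "ncol(calls) must equal nrow(loci)")
  cl <- object@calls
  if (length(cl) && !all(cl[!is.na(cl)] %in% 0:2))
    msgs <- c(msgs, "calls must be 0, 1, 2 or NA")
  if (length(msgs) == 0 && "position_bp" %in% names(loc) && nrow(loc)) {
    if (any(loc$position_bp < 1, na.rm = TRUE))
      msgs <- c(msgs, "position_bp must be >= 1")
    if (anyDuplicated(loc$snp_id))
      msgs <- c(msgs, "snp_id must be unique within a panel")
    if (any(loc$allele_a == loc$allele_b))
      msgs <- c(msgs, "the two alleles of a locus must be distinct")
  }
  if (isTRUE(object@phased)) {
    if (!all(c("hap1", "hap2") %in% names(object@haplotypes))) {
      msgs <- c(msgs, "phased data must carry haplotypes 'hap1' and 'hap2'")
    } else {
      h <- object@haplotypes$hap1 + object@haplotypes$hap2
      ok <- is.na(cl) | (h == cl)
      if (!all(ok, na.rm = TRUE))
        msgs <- c(msgs, "haplotype sums must reproduce calls at non-missing entries")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeData object
#'
#' @param calls numeric or integer matrix of 0/1/2/NA calls
#'   (individuals x loci).
#' @param individuals data.frame with `sample_id` and `breed` columns.
#' @param loci data.frame with `snp_id`, `chromosome`, `position_bp`,
#'   `allele_a`, `allele_b`.
#' @param haplotypes optional list of two binary matrices `hap1`, `hap2`;
#'   supplying it marks the object as phased.
#' @return A validated [GenotypeData-class] object.
#' @examples
#' g <- GenotypeData(
#'   calls = matrix(c(0L, 1L, 2L, 1L), 2, 2),
#'   individuals = data.frame(sample_id = c("i1", "i2"), breed = "BRD"),
#'   loci = data.frame(snp_id = c("s1", "s2"), chromosome = "1",
#'                     position_bp = c(100L, 200L),
#'                     allele_a = "A", allele_b = "G")
#' )
#' nIndividuals(g)
#' @export
GenotypeData <- function(calls, individuals, loci, haplotypes = list()) {
  storage.mode(calls) <- "integer"
  rownames(calls) <- individuals$sample_id
  colnames(calls) <- loci$snp_id
  phased <- length(haplotypes) > 0
  if (phased) {
    haplotypes <- lapply(haplotypes, function(h) {
      storage.mode(h) <- "integer"
      h
    })
  }
  new("GenotypeData",
      calls = calls,
      individuals = as.data.frame(individuals, stringsAsFactors = FALSE),
      loci = as.data.frame(loci, stringsAsFactors = FALSE),
      phased = phased,
      haplotypes = haplotypes)
}

#' @describeIn GenotypeData Number of individuals.
#' @param g a `GenotypeData` object.
#' @export
nIndividuals <- function(g) nrow(g@calls)

#' @describeIn GenotypeData Number of loci.
#' @export
nLoci <- function(g) ncol(g@calls)

#' @describeIn GenotypeData The call matrix (individuals x loci).
#' @export
genotypeCalls <- function(g) g@calls

#' @describeIn GenotypeData The per-individual metadata table.
#' @export
individuals <- function(g) g@individuals

#' @describeIn GenotypeData The per-locus metadata table.
#' @export
loci <- function(g) g@loci

#' @describeIn GenotypeData Breed code of each individual.
#' @export
breeds <- function(g) g@individuals$breed

#' @describeIn GenotypeData Is the object phased?
#' @export
isPhased <- function(g) isTRUE(g@phased)

#' @describeIn GenotypeData List of the two haplotype matrices (phased only).
#' @export
haplotypes <- function(g) g@haplotypes

#' Subset a GenotypeData object
#'
#' `[` keeps the usual matrix semantics: rows are individuals, columns loci.
#'
#' @param x a `GenotypeData` object.
#' @param i individual index (integer, logical or sample_id character).
#' @param j locus index (integer, logical or snp_id character).
#' @param ... ignored.
#' @param drop ignored; subsetting always returns a `GenotypeData`.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nIndividuals(x))
  if (missing(j)) j <- seq_len(nLoci(x))
  if (is.character(i)) i <- match(i, x@individuals$sample_id)
  if (is.character(j)) j <- match(j, x@loci$snp_id)
  haps <- x@haplotypes
  if (x@phased)
    haps <- lapply(haps, function(h) h[i, j, drop = FALSE])
  GenotypeData(
    calls = x@calls[i, j, drop = FALSE],
    individuals = x@individuals[i, , drop = FALSE],
    loci = x@loci[j, , drop = FALSE],
    haplotypes = haps
  )
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d individuals x %d loci (%s)\n",
              nIndividuals(object), nLoci(object),
              if (object@phased) "phased" else "unphased"))
  br <- table(object@individuals$breed)
  cat(sprintf("breeds (%d): %s%s\n", length(br),
              paste(utils::head(names(br), 8), collapse = ", "),
              if (length(br) > 8) ", ..." else ""))
  miss <- mean(is.na(object@calls))
  cat(sprintf("missing call rate: %.4f\n", miss))
  invisible(object)
})

#' Per-individual missing-call rate
#'
#' @param g a `GenotypeData` object.
#' @return numeric vector, one fraction in \[0,1\] per individual.
#' @export
missingRate <- function(g) rowMeans(is.na(g@calls))
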