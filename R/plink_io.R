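#' Read genotypes from PLINK text files (PED/MAP)
#'
#' Parses the classic whitespace-delimited PLINK PED/MAP pair. PED rows carry
#' six metadata columns (family, sample, father, mother, sex, phenotype)
#' followed by two allele symbols per MAP locus; `0 0` encodes a missing
#' call. The family-ID column is taken as the breed code. Each locus is
#' oriented to an (A, B) allele pair at load time: by default B is the minor
#' allele, so calls count minor-allele copies; the nucleotide symbols are
#' kept on the locus table so reports can print genotypes such as "AG".
#'
#' @param pedPath path to the PED file.
#' @param mapPath path to the MAP file (columns: chromosome, snp_id,
#'   genetic position, physical position).
#' @param minorAsB orient so that the B (counted) allele is the minor allele
#'   (default). When `FALSE`, the first allele symbol seen is A.
#' @return A [GenotypeData-class] object (unphased).
#' @export
readPlinkText <- function(pedPath, mapPath, minorAsB = TRUE) {
  if (!file.exists(pedPath)) stop("PED file not found: ", pedPath)
  if (!file.exists(mapPath)) stop("MAP file not found: ", mapPath)
  map <- utils::read.table(mapPath, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "snp_id",
                                         "genetic_pos", "position_bp"))
  nSnp <- nrow(map)
  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  expCols <- 6L + 2L * nSnp
  nc <- lengths(toks)
  if (any(nc != expCols)) {
    bad <- which(nc != expCols)[1]
    stop(sprintf(
      "malformed PED: row %d has %d fields, expected %d for a %d-SNP MAP",
      bad, nc[bad], expCols, nSnp))
  }
  meta <- t(vapply(toks, function(x) x[1:6], character(6)))
  alle <- t(vapply(toks, function(x) x[-(1:6)], character(2L * nSnp)))
  n <- nrow(alle)
  a1 <- alle[, seq(1L, 2L * nSnp, by = 2L), drop = FALSE]
  a2 <- alle[, seq(2L, 2L * nSnp, by = 2L), drop = FALSE]

  calls <- matrix(NA_integer_, n, nSnp)
  alleleA <- alleleB <- character(nSnp)
  for (j in seq_len(nSnp)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(x1, x2)
    obs <- obs[obs != "0"]
    sym <- unique(obs)
    if (length(sym) > 2)
      stop(sprintf("parse error at SNP '%s': more than two allele symbols (%s)",
                   map$snp_id[j], paste(sym, collapse = ",")))
    if (any(!sym %in% c("A", "C", "G", "T", "1", "2", "3", "4")))
      stop(sprintf("parse error at SNP '%s': unknown allele symbol '%s'",
                   map$snp_id[j],
                   sym[!sym %in% c("A", "C", "G", "T", "1", "2", "3", "4")][1]))
    if (length(sym) == 0) sym <- c("A", "B")     # fully missing column
    if (length(sym) == 1) sym <- c(sym, setdiff(c("A", "C", "G", "T"), sym)[1])
    cnt <- c(sum(obs == sym[1]), sum(obs == sym[2]))
    if (minorAsB) {
      ord <- order(cnt, decreasing = TRUE)       # A = major, B = minor
      sym <- sym[ord]
    }
    alleleA[j] <- sym[1]; alleleB[j] <- sym[2]
    miss <- x1 == "0" | x2 == "0"
    g <- (x1 == sym[2]) + (x2 == sym[2])
    g[miss] <- NA_integer_
    calls[, j] <- g
  }
  ind <- data.frame(sample_id = meta[, 2], breed = meta[, 1],
                    stringsAsFactors = FALSE)
  loc <- data.frame(snp_id = map$snp_id, chromosome = as.character(map$chromosome),
                    position_bp = as.integer(map$position_bp),
                    allele_a = alleleA, allele_b = alleleB,
                    stringsAsFactors = FALSE)
  GenotypeData(calls = calls, individuals = ind, loci = loc)
}

#' Write genotypes to PLINK text files (PED/MAP)
#'
#' Inverse of [readPlinkText()]: missing calls become `0 0`, heterozygotes
#' are written A-allele first. Round-tripping preserves calls, identifiers
#' and positions exactly.
#'
#' @param g a [GenotypeData-class] object.
#' @param pedPath,mapPath output paths.
#' @return Invisibly, the two paths.
#' @export
writePlinkText <- function(g, pedPath, mapPath) {
  loc <- loci(g)
  utils::write.table(
    data.frame(loc$chromosome, loc$snp_id, 0, loc$position_bp),
    mapPath, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  cl <- genotypeCalls(g)
  n <- nrow(cl); nSnp <- ncol(cl)
  a1 <- matrix("0", n, nSnp); a2 <- matrix("0", n, nSnp)
  A <- matrix(loc$allele_a, n, nSnp, byrow = TRUE)
  B <- matrix(loc$allele_b, n, nSnp, byrow = TRUE)
  ok <- !is.na(cl)
  a1[ok & cl == 0] <- A[ok & cl == 0]; a2[ok & cl == 0] <- A[ok & cl == 0]
  a1[ok & cl == 1] <- A[ok & cl == 1]; a2[ok & cl == 1] <- B[ok & cl == 1]
  a1[ok & cl == 2] <- B[ok & cl == 2]; a2[ok & cl == 2] <- B[ok & cl == 2]
  inter <- matrix("", n, 2L * nSnp)
  inter[, seq(1L, 2L * nSnp, 2L)] <- a1
  inter[, seq(2L, 2L * nSnp, 2L)] <- a2
  ind <- individuals(g)
  rows <- cbind(ind$breed, ind$sample_id, "0", "0", "0", "-9", inter)
  writeLines(apply(rows, 1, paste, collapse = " "), pedPath)
  invisible(c(ped = pedPath, map = mapPath))
}

#' Read RefinedIBD-style identity-by-descent segment files
#'
#' Tab-separated columns: sample_a, hap_a, sample_b, hap_b, chromosome,
#' start_bp, end_bp and optionally a score (LOD).
#'
#' @param path segment file path.
#' @return data.frame of segments with the columns above.
#' @export
readIbdSegments <- function(path) {
  seg <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(seg) < 7)
    stop("segment file must have at least 7 tab-separated columns")
  names(seg)[1:7] <- c("sample_a", "hap_a", "sample_b", "hap_b",
                       "chromosome", "start_bp", "end_bp")
  seg$sample_a <- as.character(seg$sample_a)
  seg$sample_b <- as.character(seg$sample_b)
  seg$chromosome <- as.character(seg$chromosome)
  if (ncol(seg) >= 8) names(seg)[8] <- "score"
  if (any(seg$end_bp <= seg$start_bp))
    stop("segment with end_bp <= start_bp")
  seg
}

#' Write identity-by-descent segments
#'
#' @param segments data.frame as returned by [readIbdSegments()] or
#'   [detectIbdNaive()].
#' @param path output path (tab-separated, no header).
#' @export
writeIbdSegments <- function(segments, path) {
  cols <- c("sample_a", "hap_a", "sample_b", "hap_b",
            "chromosome", "start_bp", "end_bp")
  if ("score" %in% names(segments)) cols <- c(cols, "score")
  utils::write.table(segments[, cols], path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
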