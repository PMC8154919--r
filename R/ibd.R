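#' Naive identity-by-descent detection on phased haplotypes
#'
#' Scans every pair of haplotypes for maximal runs of identical alleles and
#' reports runs whose physical span is at least `minLenBp`. This is an exact
#' identical-run detector intended for simulated data, where planted
#' segments are copied verbatim; it is not a probabilistic IBD model and
#' makes no allowance for genotyping error.
#'
#' @param g a phased [GenotypeData-class] object.
#' @param minLenBp minimum physical span (bp) of a reported run
#'   (default 200000, i.e. 0.2 Mb).
#' @return data.frame of segments with columns `sample_a`, `hap_a`,
#'   `sample_b`, `hap_b`, `chromosome`, `start_bp`, `end_bp`.
#' @export
detectIbdNaive <- function(g, minLenBp = 200000) {
  if (!isPhased(g))
    stop("genotypes are not phased; ingest a segment file with readIbdSegments() instead")
  loc <- loci(g)
  ids <- individuals(g)$sample_id
  h <- haplotypes(g)
  n <- nIndividuals(g)
  # haplotype index: 2*i-1 -> (ind i, hap 1), 2*i -> (ind i, hap 2)
  H <- matrix(0L, 2L * n, nLoci(g))
  H[seq(1L, 2L * n, 2L), ] <- h$hap1
  H[seq(2L, 2L * n, 2L), ] <- h$hap2
  out <- list()
  for (chr in unique(loc$chromosome)) {
    cidx <- which(loc$chromosome == chr)
    cidx <- cidx[order(loc$position_bp[cidx])]
    pos <- loc$position_bp[cidx]
    Hc <- H[, cidx, drop = FALSE]
    nh <- nrow(Hc)
    for (a in seq_len(nh - 1L)) {
      ia <- (a + 1L) %/% 2L
      for (b in (a + 1L):nh) {
        ib <- (b + 1L) %/% 2L
        if (ia == ib) next    # within-individual pairs are not IBD sharing
        eq <- Hc[a, ] == Hc[b, ]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runs <- which(r$values)
        for (k in runs) {
          span <- pos[ends[k]] - pos[starts[k]]
          if (span >= minLenBp) {
            out[[length(out) + 1L]] <- data.frame(
              sample_a = ids[ia], hap_a = 2L - a %% 2L,
              sample_b = ids[ib], hap_b = 2L - b %% 2L,
              chromosome = chr,
              start_bp = pos[starts[k]], end_bp = pos[ends[k]],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_a = character(), hap_a = integer(),
                      sample_b = character(), hap_b = integer(),
                      chromosome = character(), start_bp = integer(),
                      end_bp = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Breed-level haplotype-sharing matrix
#'
#' Summarizes pairwise IBD segments into a breed x breed matrix. For each
#' inter-breed pair of individuals the shared length is the sum of segment
#' lengths over their four haplotype pairings (`summarise = "sum"`, the
#' default) or each segment taken singly (`summarise = "per_segment"`). The
#' breed-pair statistic is the median of that quantity over all inter-breed
#' individual pairs, with pairs that share nothing contributing zero; even
#' counts use the midpoint convention. Because of the zero fill, an entry is
#' nonzero only when at least half of the individual pairs share.
#'
#' @param segments data.frame of segments (see [readIbdSegments()]).
#' @param individualTable data.frame with columns `sample_id`, `breed`
#'   covering every sample named by the segments.
#' @param summarise per-pair summary before the median: `"sum"` (default)
#'   or `"per_segment"` (median over individual segments, unshared pairs
#'   still contributing zeros).
#' @param unitMb report entries in megabases (default) or base pairs.
#' @return list with `matrix` (breed x breed, symmetric, `NA` diagonal) and
#'   `pairCounts` (number of individual pairs per breed pair).
#' @export
breedSharingMatrix <- function(segments, individualTable,
                               summarise = c("sum", "per_segment"),
                               unitMb = TRUE) {
  summarise <- match.arg(summarise)
  ids <- individualTable$sample_id
  breedOf <- stats::setNames(individualTable$breed, ids)
  if (nrow(segments)) {
    unknown <- setdiff(unique(c(segments$sample_a, segments$sample_b)), ids)
    if (length(unknown))
      stop("segments name unknown sample(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))
  }
  brs <- sort(unique(individualTable$breed))
  nB <- length(brs)
  m <- matrix(0, nB, nB, dimnames = list(brs, brs))
  cnt <- matrix(0L, nB, nB, dimnames = list(brs, brs))
  scale <- if (unitMb) 1e6 else 1
  # per ordered individual-pair key, total (or listed) shared lengths
  if (nrow(segments)) {
    key <- ifelse(segments$sample_a < segments$sample_b,
                  paste(segments$sample_a, segments$sample_b, sep = "\r"),
                  paste(segments$sample_b, segments$sample_a, sep = "\r"))
    len <- (segments$end_bp - segments$start_bp) / scale
    if (summarise == "sum") {
      perPair <- tapply(len, key, sum)
    } else {
      perPair <- tapply(len, key, function(x) x)   # keep the list
    }
  } else {
    perPair <- numeric(0)
  }
  for (i in seq_len(nB - 1)) {
    for (j in (i + 1):nB) {
      ia <- ids[breedOf[ids] == brs[i]]
      ib <- ids[breedOf[ids] == brs[j]]
      pairsKeys <- as.vector(outer(ia, ib, function(x, y)
        ifelse(x < y, paste(x, y, sep = "\r"), paste(y, x, sep = "\r"))))
      cnt[i, j] <- cnt[j, i] <- length(pairsKeys)
      if (summarise == "sum") {
        vals <- unname(perPair[pairsKeys])
        vals[is.na(vals)] <- 0
      } else {
        vals <- unlist(lapply(pairsKeys, function(k) {
          ix <- match(k, names(perPair))
          if (is.na(ix)) 0 else perPair[[ix]]
        }))
      }
      m[i, j] <- m[j, i] <- if (length(vals)) stats::median(vals) else 0
    }
  }
  diag(m) <- NA_real_
  list(matrix = m, pairCounts = cnt)
}

#' Write a sharing matrix and a Circos-style link file
#'
#' @param sharing result of [breedSharingMatrix()].
#' @param matrixPath TSV output for the matrix.
#' @param linksPath optional path for a link table (`breed_a`, `breed_b`,
#'   `value`) restricted to nonzero entries, the layout Circos ribbon plots
#'   consume.
#' @export
writeSharingMatrix <- function(sharing, matrixPath, linksPath = NULL) {
  utils::write.table(sharing$matrix, matrixPath, quote = FALSE, sep = "\t",
                     col.names = NA)
  if (!is.null(linksPath)) {
    m <- sharing$matrix
    pr <- which(upper.tri(m) & !is.na(m) & m > 0, arr.ind = TRUE)
    links <- data.frame(breed_a = rownames(m)[pr[, 1]],
                        breed_b = colnames(m)[pr[, 2]],
                        value = m[pr], stringsAsFactors = FALSE)
    utils::write.table(links, linksPath, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  invisible(matrixPath)
}
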