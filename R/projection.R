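#' Köppen-Geiger class to temperature/humidity groups
#'
#' Assigns each breed to HOT/NOTHOT and DRY/NOTDRY groups from its current
#' Köppen-Geiger class. The default humidity map puts the summer-dry
#' temperate classes and the cold steppe in DRY (`Csa`, `Csb`, `BSk`) and
#' the no-dry-season classes plus polar tundra in NOTDRY (`Cfa`, `Cfb`,
#' `Dfb`, `Dfc`, `EF`). The default temperature map puts the hot-summer
#' temperate classes in HOT (`Csa`, `Cfa`) and everything else in NOTHOT.
#' Both maps are fully configurable; an input class covered by neither side
#' of a map raises an error naming the breed.
#'
#' @param koppen data.frame with columns `breed`, `current_class` and
#'   optionally `future_class`.
#' @param hotClasses,dryClasses character vectors of classes mapped to HOT
#'   and DRY; classes listed in `nothotClasses`/`notdryClasses` go to the
#'   complementary group.
#' @param nothotClasses,notdryClasses classes of the complementary groups.
#' @return the input with added `hot_group` and `dry_group` columns.
#' @export
assignKoppenGroups <- function(koppen,
                               hotClasses = c("Csa", "Cfa"),
                               nothotClasses = c("Csb", "Cfb", "BSk", "BSh",
                                                 "Dfa", "Dfb", "Dfc", "ET", "EF"),
                               dryClasses = c("Csa", "Csb", "BSk", "BSh"),
                               notdryClasses = c("Cfa", "Cfb", "Dfa", "Dfb",
                                                 "Dfc", "ET", "EF")) {
  stopifnot(all(c("breed", "current_class") %in% names(koppen)))
  cls <- koppen$current_class
  knownT <- c(hotClasses, nothotClasses)
  knownD <- c(dryClasses, notdryClasses)
  badT <- !(cls %in% knownT); badD <- !(cls %in% knownD)
  if (any(badT | badD)) {
    i <- which(badT | badD)[1]
    stop(sprintf("Koppen class '%s' of breed %s is absent from the group map",
                 cls[i], koppen$breed[i]))
  }
  koppen$hot_group <- ifelse(cls %in% hotClasses, "HOT", "NOTHOT")
  koppen$dry_group <- ifelse(cls %in% dryClasses, "DRY", "NOTDRY")
  koppen
}

#' Summaries of Köppen-Geiger class change
#'
#' @param koppen data.frame with `breed`, `current_class`, `future_class`.
#' @return list with `nUnchanged` (breeds whose class does not change),
#'   `unchangedByClass` (table of the unchanged breeds' current class),
#'   `currentMacroClass` (counts per macro-class: B Arid, C Temperate,
#'   D Cold, E Polar) and `unchangedBreeds`.
#' @export
koppenChangeSummary <- function(koppen) {
  if (!nrow(koppen)) {
    return(list(nUnchanged = 0L, unchangedByClass = table(character()),
                currentMacroClass = table(character()),
                unchangedBreeds = character()))
  }
  same <- koppen$current_class == koppen$future_class
  macro <- c(A = "Tropical", B = "Arid", C = "Temperate",
             D = "Cold", E = "Polar")
  cm <- macro[substr(koppen$current_class, 1, 1)]
  list(nUnchanged = sum(same),
       unchangedByClass = table(koppen$current_class[same]),
       currentMacroClass = table(cm),
       unchangedBreeds = koppen$breed[same])
}

#' One-way ANOVA of breed allele frequencies between two climate groups
#'
#' @param values per-breed allele frequencies (or MAF) for one SNP.
#' @param groups two-level factor (e.g. DRY/NOTDRY), one level per breed.
#' @return list with `F`, `p`, `df` (c(1, n - 2)) and the two group means.
#' @export
groupAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  cnt <- table(groups)
  if (any(cnt < 2))
    stop("each level needs at least two breeds; '",
         names(cnt)[cnt < 2][1], "' has ", min(cnt))
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]),
       means = tapply(values, groups, mean))
}

#' Linear regression of breed allele frequency on an environmental variable
#'
#' Ordinary least squares across breeds (both climate groups pooled, so a
#' single regressor serves every group), frequency on mean current value of
#' the variable. The slope's t-test p-value gates the projection step.
#'
#' @param env per-breed mean value of the variable.
#' @param freq per-breed allele frequency of the focal allele.
#' @return list with `b` (slope), `intercept`, `p` (slope p-value), `n`.
#' @export
climateRegression <- function(env, freq) {
  ok <- !is.na(env) & !is.na(freq)
  env <- env[ok]; freq <- freq[ok]
  if (length(env) < 3) stop("need at least three breeds")
  if (stats::var(env) == 0) stop("environmental variable has zero variance")
  fit <- stats::lm(freq ~ env)
  cf <- summary(fit)$coefficients
  list(b = unname(cf["env", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p = unname(cf["env", "Pr(>|t|)"]),
       n = length(env))
}

#' Project future allele and genotype frequencies
#'
#' The future frequency of the focal allele is
#' `p_future = clamp(p_current + b * delta, 0, 1)` with `delta = future -
#' current` value of the associated environmental variable (group mean) and
#' `b` the regression slope of frequency on that variable. Genotype
#' frequencies now and in the future follow Hardy-Weinberg:
#' `(1-p)^2, 2p(1-p), p^2` for the (AA, AB, BB) triple, with B the focal
#' allele.
#'
#' @param pCurrent current frequency of the focal allele, in \[0,1\].
#' @param b regression slope (frequency per unit of the variable).
#' @param delta future minus current group-mean value of the variable.
#' @param group optional group label carried through.
#' @param snpId,gene,genotype optional annotation carried through.
#' @param alleles length-2 character: the non-focal and focal allele
#'   symbols (default A, G).
#' @return one-row data.frame with the current and future allele frequency
#'   and the two Hardy-Weinberg genotype triples (columns `AA_current`,
#'   `BB_current`, `AB_current`, `AA_future`, `BB_future`, `AB_future`
#'   renamed with the actual allele symbols, e.g. `GG_*`), plus a `clamped`
#'   flag.
#' @export
projectFrequencies <- function(pCurrent, b, delta, group = NA_character_,
                               snpId = NA_character_, gene = NA_character_,
                               genotype = NA_character_,
                               alleles = c("A", "G")) {
  stopifnot(pCurrent >= 0, pCurrent <= 1)
  raw <- pCurrent + b * delta
  pFuture <- min(max(raw, 0), 1)
  hw <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  cur <- hw(pCurrent); fut <- hw(pFuture)
  hom1 <- paste0(alleles[1], alleles[1])
  het  <- paste0(alleles[1], alleles[2])
  hom2 <- paste0(alleles[2], alleles[2])
  out <- data.frame(snp_id = snpId, gene = gene, genotype = genotype,
                    group = group, p_current = pCurrent, b = b,
                    delta = delta, p_future = pFuture,
                    clamped = !identical(raw, pFuture),
                    stringsAsFactors = FALSE)
  out[[paste0(hom1, "_current")]] <- cur[1]
  out[[paste0(het, "_current")]]  <- cur[2]
  out[[paste0(hom2, "_current")]] <- cur[3]
  out[[paste0(hom1, "_future")]] <- fut[1]
  out[[paste0(het, "_future")]]  <- fut[2]
  out[[paste0(hom2, "_future")]] <- fut[3]
  out
}

#' Köppen-group projection of significant SNPs
#'
#' End-to-end future-genotype stage for a set of SNPs: per climate group
#' (DRY/NOTDRY or HOT/NOTHOT), screen each SNP by one-way ANOVA of breed
#' frequencies between the two groups, regress frequency on the group-mean
#' environmental variable across all breeds, and project group-level
#' future frequencies for SNPs whose regression slope is significant.
#'
#' @param freqTable long output of [alleleFrequencies()] restricted to the
#'   SNPs of interest (column `p` is used as the focal-allele frequency).
#' @param koppen output of [assignKoppenGroups()].
#' @param envTable long environmental table with current and future epochs
#'   per breed.
#' @param variable the environmental variable associated with the SNPs.
#' @param grouping `"dry_group"` or `"hot_group"`.
#' @param anovaAlpha ANOVA screen level (default 0.05).
#' @param slopeAlpha regression-gate level (default 0.05).
#' @return list with `screen` (per-SNP ANOVA F and p), `regression`
#'   (per-SNP slope, p), and `projection` (rows from
#'   [projectFrequencies()] for each significant SNP x group).
#' @export
projectKoppenGroups <- function(freqTable, koppen, envTable, variable,
                                grouping = c("dry_group", "hot_group"),
                                anovaAlpha = 0.05, slopeAlpha = 0.05) {
  grouping <- match.arg(grouping)
  grpOf <- stats::setNames(koppen[[grouping]], koppen$breed)
  envCur <- envValue(envTable, variable, "current")
  envFut <- envValue(envTable, variable, "future")
  snps <- unique(freqTable$snp_id)
  screen <- list(); regr <- list(); proj <- list()
  for (s in snps) {
    sub <- freqTable[freqTable$snp_id == s, ]
    sub <- sub[sub$group %in% names(grpOf) & !is.na(sub$p), ]
    grp <- grpOf[sub$group]
    an <- groupAnova(sub$p, grp)
    screen[[s]] <- data.frame(snp_id = s, F = an$F, p_anova = an$p,
                              stringsAsFactors = FALSE)
    reg <- climateRegression(envCur[sub$group], sub$p)
    regr[[s]] <- data.frame(snp_id = s, b = reg$b, p_slope = reg$p,
                            stringsAsFactors = FALSE)
    if (is.na(an$p) || an$p >= anovaAlpha) next
    if (reg$p >= slopeAlpha) next
    for (lev in unique(grp)) {
      inGrp <- names(grp)[grp == lev]
      inGrp <- sub$group[grp == lev]
      pCur <- mean(sub$p[grp == lev])
      dAll <- envFut[inGrp] - envCur[inGrp]
      proj[[paste(s, lev)]] <- projectFrequencies(
        pCurrent = pCur, b = reg$b, delta = mean(dAll), group = lev,
        snpId = s)
    }
  }
  bindOr <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(screen = bindOr(screen, data.frame()),
       regression = bindOr(regr, data.frame()),
       projection = if (length(proj)) do.call(rbind, proj) else data.frame())
}
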