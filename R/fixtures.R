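#' Bundled reference tables
#'
#' `koppenClasses()` returns the bundled table of current and 2070-horizon
#' Köppen-Geiger classes for the 32 georeferenced Italian goat breeds
#' (breed code, current class, future class). `projectedGenotypeTable()`
#' returns the bundled table of published current and projected
#' Hardy-Weinberg genotype frequencies for five climate-associated SNPs,
#' used in the package's consistency tests.
#'
#' @return data.frame.
#' @export
koppenClasses <- function() {
  utils::read.table(system.file("extdata", "koppen_classes.tsv",
                                package = "caprascape"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname koppenClasses
#' @export
projectedGenotypeTable <- function() {
  utils::read.table(system.file("extdata",
                                "projected_genotype_frequencies.tsv",
                                package = "caprascape"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
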