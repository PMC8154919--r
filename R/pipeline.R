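#' Pipeline configuration
#'
#' Collects inputs, thresholds and stage toggles for [runPipeline()].
#' Either a simulation config (`simulate`) or paths to PED/MAP files must
#' be given. Stage outputs are plain TSV/Newick so each stage is
#' independently inspectable and replaceable.
#'
#' @param outDir output directory.
#' @param simulate optional [simulationConfig()]; when present the run
#'   starts by generating the dataset.
#' @param pedPath,mapPath genotype input (ignored when simulating).
#' @param envTable long environmental table (or `NULL` to use the
#'   simulated one).
#' @param koppen optional Köppen table (`breed`, `current_class`,
#'   `future_class`).
#' @param genes optional BED-like gene table for annotation.
#' @param qc [qcParams()] thresholds.
#' @param stages character subset of
#'   `c("qc", "structure", "sharing", "assoc", "project")`.
#' @param assocVariable variable tested in the association/projection
#'   stages (default: first in the environmental table).
#' @param pcK principal components for structure correction (or "auto").
#' @param seed integer master seed.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(outDir, simulate = NULL, pedPath = NULL,
                           mapPath = NULL, envTable = NULL, koppen = NULL,
                           genes = NULL, qc = qcParams(),
                           stages = c("qc", "structure", "sharing",
                                      "assoc", "project"),
                           assocVariable = NULL, pcK = "auto", seed = 1L) {
  if (is.null(simulate) && (is.null(pedPath) || is.null(mapPath)))
    stop("either a simulation config or PED/MAP paths are required")
  structure(list(outDir = outDir, simulate = simulate, pedPath = pedPath,
                 mapPath = mapPath, envTable = envTable, koppen = koppen,
                 genes = genes, qc = qc, stages = stages,
                 assocVariable = assocVariable, pcK = pcK,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

writeStageTable <- function(x, path, cfg, stage) {
  con <- file(path, "w")
  writeLines(sprintf("# caprascape stage=%s seed=%d", stage, cfg$seed), con)
  close(con)
  suppressWarnings(
    utils::write.table(x, path, quote = FALSE, sep = "\t",
                       row.names = FALSE, append = TRUE))
  path
}

#' Run the full landscape-genomics pipeline
#'
#' Executes, as toggled: simulation (or PLINK ingestion), the QC cascade,
#' population-structure summaries (MDS, Reynolds neighbor-joining tree),
#' haplotype sharing, genotype-environment association and Köppen-group
#' projection. Halts on the first failing stage with a stage-attributed
#' error; outputs written before the failure are preserved. Every output
#' table carries a provenance header (stage and seed), and the returned
#' manifest records dataset sizes after each filter, all parameters, and
#' md5 checksums of the outputs.
#'
#' @param cfg a [pipelineConfig()] list.
#' @return the run manifest (list), invisibly also written to
#'   `manifest.json` in the output directory.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list(),
                   parameters = list(qc = unclass(cfg$qc), pcK = cfg$pcK))
  outputs <- character()
  stageWrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- input ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- stageWrap("simulate", simulateDataset(cfg$simulate))
    g <- sim$genotypes
    envTable <- if (is.null(cfg$envTable)) sim$env else cfg$envTable
    manifest$stages$simulate <- list(
      n_individuals = nIndividuals(g), n_loci = nLoci(g),
      n_adaptive = length(sim$truth$adaptive_snps))
  } else {
    g <- stageWrap("input", readPlinkText(cfg$pedPath, cfg$mapPath))
    sim <- NULL
    envTable <- cfg$envTable
    manifest$stages$input <- list(n_individuals = nIndividuals(g),
                                  n_loci = nLoci(g))
  }

  # --- qc ------------------------------------------------------------
  if ("qc" %in% cfg$stages) {
    res <- stageWrap("qc", {
      step1 <- filterCallRateMaf(g, cfg$qc)
      step2 <- removeDuplicatesRelatives(step1$genotypes, cfg$qc)
      report <- rbind(step1$report, step2$report)
      list(genotypes = step2$genotypes, report = report)
    })
    g <- res$genotypes
    p <- writeStageTable(res$report, file.path(cfg$outDir, "qc_report.tsv"),
                         cfg, "qc")
    outputs <- c(outputs, p)
    manifest$stages$qc <- list(n_individuals = nIndividuals(g),
                               n_loci = nLoci(g),
                               n_removed = nrow(res$report))
  }

  # --- structure -----------------------------------------------------
  if ("structure" %in% cfg$stages) {
    stageWrap("structure", {
      gs <- representativeSubsample(g, cfg$qc$maxPerBreed, seed = cfg$seed)
      keep <- ldPrune(gs, cfg$qc)
      gs <- gs[, keep]
      d <- ibsDistance(gs)
      mds <- classicalMds(d, k = 2)
      mdsTab <- data.frame(sample_id = rownames(mds$coordinates),
                           breed = breeds(gs),
                           mds$coordinates, stringsAsFactors = FALSE)
      p1 <- writeStageTable(mdsTab, file.path(cfg$outDir, "mds.tsv"),
                            cfg, "structure")
      nBreed <- length(unique(breeds(gs)))
      p2 <- NULL
      if (nBreed >= 3) {
        tr <- njBootstrapTree(gs, nBoot = 100, seed = cfg$seed)
        p2 <- file.path(cfg$outDir, "reynolds_nj.nwk")
        ape::write.tree(tr$tree, p2)
      }
      outputs <- c(outputs, p1, p2)
      manifest$stages$structure <- list(
        n_individuals = nIndividuals(gs), n_loci = nLoci(gs),
        mds_variance = unname(mds$varianceProportion))
    })
  }

  # --- sharing -------------------------------------------------------
  if ("sharing" %in% cfg$stages) {
    stageWrap("sharing", {
      if (!isPhased(g))
        stop("haplotype sharing needs phased genotypes or a segment file")
      segs <- detectIbdNaive(g)
      sh <- breedSharingMatrix(segs, individuals(g))
      p <- file.path(cfg$outDir, "sharing_matrix.tsv")
      writeSharingMatrix(sh, p, file.path(cfg$outDir, "sharing_links.tsv"))
      outputs <- c(outputs, p)
      manifest$stages$sharing <- list(n_segments = nrow(segs))
    })
  }

  # --- association ---------------------------------------------------
  assocRes <- NULL
  if ("assoc" %in% cfg$stages) {
    stageWrap("assoc", {
      if (is.null(envTable)) stop("no environmental table available")
      v <- cfg$assocVariable
      if (is.null(v)) v <- envTable$variable[1]
      assocRes <- runAssociation(g, envTable, variables = v, k = cfg$pcK)
      if (!is.null(cfg$genes))
        assocRes <- annotateHits(assocRes, loci(g), cfg$genes)
      p <- writeStageTable(assocRes,
                           file.path(cfg$outDir, "association.tsv"),
                           cfg, "assoc")
      outputs <- c(outputs, p)
      manifest$stages$assoc <- list(
        n_tests = nrow(assocRes),
        n_significant = sum(assocRes$q_value < 0.05))
    })
  }

  # --- projection ----------------------------------------------------
  if ("project" %in% cfg$stages) {
    stageWrap("project", {
      if (is.null(assocRes))
        stop("projection requires the association stage; enable 'assoc'")
      if (is.null(cfg$koppen)) stop("no Koppen table supplied")
      hits <- unique(assocRes$snp_id[assocRes$q_value < 0.05])
      manifest$stages$project <- list(n_candidate_snps = length(hits))
      if (length(hits)) {
        v <- cfg$assocVariable
        if (is.null(v)) v <- envTable$variable[1]
        freqs <- alleleFrequencies(g)
        freqs <- freqs[freqs$snp_id %in% hits, ]
        kop <- assignKoppenGroups(cfg$koppen)
        pr <- projectKoppenGroups(freqs, kop, envTable, v)
        if (nrow(pr$projection)) {
          p <- writeStageTable(pr$projection,
                               file.path(cfg$outDir, "projection.tsv"),
                               cfg, "project")
          outputs <- c(outputs, p)
        }
        manifest$stages$project$n_projected <-
          if (nrow(pr$projection)) length(unique(pr$projection$snp_id)) else 0L
      }
    })
  }

  outputs <- outputs[!vapply(outputs, is.null, TRUE)]
  manifest$outputs <- as.list(tools::md5sum(unlist(outputs)))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
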