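#' Declarative configuration of a full pipeline run
#'
#' Exactly one of \code{simulation} (a [simSpec()] or list of its
#' arguments) or \code{inputs} (list with paths \code{pedigree},
#' \code{genotypes} — dosage TSV or VCF —, \code{phenotypes}) must be
#' given. Settings follow the study defaults: QC at 90\% call rate and
#' 0.5\% MAF, scale-2/df-5 variance priors.
#'
#' @param simulation a [simSpec()] or argument list, or NULL
#' @param inputs list of input paths, or NULL
#' @param traits phenotype column names to analyse (default \code{"y"})
#' @param covariates covariate columns for the pre-adjustment
#' @param minCallRate,minMAF QC thresholds
#' @param prior a [priorSpec()]
#' @param gibbs a [gibbsConfig()]
#' @param outDir output directory (created if absent)
#' @param seed master seed (overrides the simulation spec seed)
#' @return a validated list of class \code{"runConfig"}
#' @export
runConfig <- function(simulation = NULL, inputs = NULL, traits = "y",
                      covariates = c("female", "age", "pc1", "pc2",
                                     "cohort"),
                      minCallRate = 0.90, minMAF = 0.005,
                      prior = priorSpec(), gibbs = gibbsConfig(),
                      outDir = tempfile("gherit_run_"), seed = 1L) {
  if (is.null(simulation) == is.null(inputs))
    stop("exactly one of 'simulation' and 'inputs' must be given")
  if (!is.null(simulation) && !inherits(simulation, "simSpec"))
    simulation <- do.call(simSpec, simulation)
  if (!is.null(simulation)) simulation$seed <- as.integer(seed)
  if (!is.null(inputs)) {
    need <- c("pedigree", "genotypes", "phenotypes")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("inputs missing: ", paste(miss, collapse = ", "))
  }
  structure(list(simulation = simulation, inputs = inputs, traits = traits,
                 covariates = covariates, minCallRate = minCallRate,
                 minMAF = minMAF, prior = prior, gibbs = gibbs,
                 outDir = outDir, seed = as.integer(seed)),
            class = "runConfig")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat key-value document; recognised keys mirror the [runConfig()]
#' arguments (simulation.* keys populate the simulation spec, input paths
#' go under inputs.*, gibbs.* and prior.* populate the samplers).
#'
#' @param path YAML file path
#' @param overrides named list applied on top of the file values
#' @return a \code{"runConfig"}
#' @export
readRunConfig <- function(path, overrides = list()) {
  y <- utils::modifyList(yaml::read_yaml(path), overrides)
  args <- list()
  if (!is.null(y$simulation)) args$simulation <- y$simulation
  if (!is.null(y$inputs)) args$inputs <- y$inputs
  for (k in c("traits", "covariates", "minCallRate", "minMAF", "outDir",
              "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$prior)) args$prior <- do.call(priorSpec, y$prior)
  if (!is.null(y$gibbs)) args$gibbs <- do.call(gibbsConfig, y$gibbs)
  do.call(runConfig, args)
}

#' Validate pipeline inputs without mutating them
#'
#' Cross-checks file existence, format conformance and the family-study id
#' containment rule (pedigree ids must cover genotyped ids and phenotyped
#' ids). For VCF genotypes, non-biallelic records are reported (they are
#' skipped at load time). Returns a findings table; [runPipeline()] refuses
#' to start on any fatal finding.
#'
#' @param config a [runConfig()]
#' @return data.frame with columns level ("fatal"/"warning"/"info") and
#'   message; zero rows means a clean bill
#' @export
validateInputs <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  findings <- list()
  note <- function(level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(level = level,
                                                     message = msg)
  if (!is.null(config$simulation)) {
    spec <- config$simulation
    if (spec$nFounders < 2L && spec$nGenerations > 1L)
      note("fatal", "simulation: fewer than 2 founders cannot form matings")
  } else {
    for (k in names(config$inputs)) {
      p <- config$inputs[[k]]
      if (!file.exists(p)) note("fatal", paste0(k, " file not found: ", p))
    }
    if (!any(vapply(findings, function(f) f$level == "fatal", logical(1)))) {
      ped <- tryCatch(readPedigree(config$inputs$pedigree), error = function(e) {
        note("fatal", paste("pedigree unreadable:", conditionMessage(e)))
        NULL
      })
      gen <- tryCatch({
        gp <- config$inputs$genotypes
        if (grepl("\\.vcf(\\.gz)?$", gp)) readGenotypeVCF(gp) else readDosage(gp)
      }, error = function(e) {
        note("fatal", paste("genotypes unreadable:", conditionMessage(e)))
        NULL
      })
      phe <- tryCatch(readTSV(config$inputs$phenotypes), error = function(e) {
        note("fatal", paste("phenotypes unreadable:", conditionMessage(e)))
        NULL
      })
      if (!is.null(gen)) {
        skipped <- gen@metadata$skippedNonBiallelic
        if (!is.null(skipped) && skipped > 0)
          note("warning", sprintf("site skipped: not biallelic (%d record(s))",
                                  skipped))
      }
      if (!is.null(ped) && !is.null(gen)) {
        extra <- setdiff(ids(gen), ids(ped))
        if (length(extra))
          note("fatal", paste("genotyped individual(s) absent from pedigree:",
                              paste(utils::head(extra, 5), collapse = ", ")))
      }
      if (!is.null(ped) && !is.null(phe)) {
        if (!"id" %in% names(phe)) {
          note("fatal", "phenotype file lacks an id column")
        } else {
          extra <- setdiff(as.character(phe$id), ids(ped))
          if (length(extra))
            note("fatal",
                 paste("phenotyped individual(s) absent from pedigree:",
                       paste(utils::head(extra, 5), collapse = ", ")))
        }
        missTraits <- setdiff(config$traits, names(phe))
        if (length(missTraits))
          note("fatal", paste("trait column(s) absent:",
                              paste(missTraits, collapse = ", ")))
      }
    }
  }
  if (config$minCallRate <= 0 || config$minCallRate >= 1)
    note("fatal", "minCallRate must lie in (0, 1)")
  if (config$minMAF <= 0 || config$minMAF >= 1)
    note("fatal", "minMAF must lie in (0, 1)")
  if (length(findings)) do.call(rbind, findings) else
    data.frame(level = character(), message = character())
}

stageDone <- function(outDir, stage)
  file.path(outDir, sprintf("stage_%s.done", stage))

runStage <- function(outDir, stage, expr) {
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
  writeLines(format(Sys.time()), stageDone(outDir, stage))
  res
}

#' Run the full heritability pipeline
#'
#' Fixed stage order: simulate (or load) inputs; QC filter and impute the
#' genotypes; build the pedigree A and genomic G matrices; pre-adjust each
#' trait for covariates; fit the additive genetic model under both kernels
#' by Gibbs sampling; compare G vs A and the two sets of predicted genetic
#' values. Per-stage artifacts are written under \code{config$outDir}
#' (TSV tables, GRM triplets, plots) with a \code{stage_*.done} marker per
#' completed stage, so a failed run leaves resumable evidence of what
#' finished. Reruns with an identical config and seed are numerically
#' identical.
#'
#' @param config a [runConfig()]
#' @return a list of class \code{"runReport"}: \code{heritability}
#'   (Table-2-shaped data.frame: trait, kernel, h2Pct, h2PctSD, logLik),
#'   \code{coefficients} per trait, \code{gaBins}, \code{predictedValues}
#'   correlations per trait, \code{setSizes}, \code{fits}, and a
#'   \code{provenance} block (seed, config echo, timings)
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  findings <- validateInputs(config)
  if (any(findings$level == "fatal"))
    stop("validation failed:\n  ",
         paste(findings$message[findings$level == "fatal"], collapse = "\n  "))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  clock <- function(stage, expr) {
    s <- Sys.time()
    res <- runStage(config$outDir, stage, expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    res
  }

  inputs <- clock("inputs", {
    if (!is.null(config$simulation)) {
      study <- simulateStudy(config$simulation)
      writePedigree(study$pedigree, file.path(config$outDir, "pedigree.tsv"))
      writeDosage(study$genotypesRaw,
                  file.path(config$outDir, "genotypes.dosage.tsv"))
      writeTSV(study$phenotypes, file.path(config$outDir, "phenotypes.tsv"))
      writeTSV(data.frame(id = names(study$truth$u), u = study$truth$u),
               file.path(config$outDir, "truth.tsv"))
      list(pedigree = study$pedigree, genotypes = study$genotypesRaw,
           phenotypes = study$phenotypes, truth = study$truth)
    } else {
      gp <- config$inputs$genotypes
      list(pedigree = readPedigree(config$inputs$pedigree),
           genotypes = if (grepl("\\.vcf(\\.gz)?$", gp)) readGenotypeVCF(gp)
                       else readDosage(gp),
           phenotypes = readTSV(config$inputs$phenotypes), truth = NULL)
    }
  })

  qc <- clock("qc", {
    filtered <- filterGenotypes(inputs$genotypes, config$minCallRate,
                                config$minMAF)
    writeTSV(filtered@metadata$exclusions,
             file.path(config$outDir, "exclusions.tsv"))
    imputeMissing(filtered, seed = config$seed + 1L)
  })

  # analysis set: pedigree ∩ genotyped-after-QC ∩ phenotyped
  common <- intersect(intersect(ids(inputs$pedigree), ids(qc)),
                      as.character(inputs$phenotypes$id))
  common <- ids(inputs$pedigree)[ids(inputs$pedigree) %in% common]
  setSizes <- c(pedigree = nIndividuals(inputs$pedigree),
                genotypedAfterQC = nIndividuals(qc),
                phenotyped = nrow(inputs$phenotypes),
                analysed = length(common))

  kernels <- clock("kernels", {
    A <- buildA(inputs$pedigree)
    Aw <- new("RelationshipMatrix", values = relValues(A)[common, common],
              kind = "pedigree_A")
    Gfull <- computeG(GenotypeData(genotypeCounts(qc)[common, , drop = FALSE],
                                   theta = alleleFreq(qc)))
    writeGRM(Aw, file.path(config$outDir, "A.grm.txt"))
    writeGRM(Gfull, file.path(config$outDir, "G.grm.txt"),
             nMarkers = ncol(genotypeCounts(qc)))
    list(A = Aw, G = Gfull)
  })

  ga <- clock("ga_compare", {
    cmp <- compareGA(kernels$G, kernels$A)
    writeTSV(cmp@bins, file.path(config$outDir, "ga_bins.tsv"))
    ggplot2::ggsave(file.path(config$outDir, "ga_scatter.pdf"), plotGA(cmp),
                    width = 6, height = 4)
    cmp
  })

  pheno <- inputs$phenotypes[match(common, as.character(inputs$phenotypes$id)), ]
  report <- list()
  fits <- list()
  coefTables <- list()
  predCors <- list()
  for (trait in config$traits) {
    adj <- clock(paste0("adjust_", trait),
                 fitFixedEffects(pheno, trait, config$covariates))
    writeTSV(adj@coefficients,
             file.path(config$outDir, sprintf("coefficients_%s.tsv", trait)))
    writeTSV(data.frame(id = adj@id, y = adj@y),
             file.path(config$outDir, sprintf("residuals_%s.tsv", trait)))
    coefTables[[trait]] <- adj@coefficients
    cfgA <- config$gibbs
    cfgG <- gibbsConfig(cfgA@nIter, cfgA@burnIn, cfgA@thin,
                        seed = cfgA@seed + 1L, initH2 = cfgA@initH2)
    fitA <- clock(paste0("fit_A_", trait),
                  suppressWarnings(fitModel(adj, kernels$A, config$prior,
                                            cfgA)))
    fitG <- clock(paste0("fit_G_", trait),
                  suppressWarnings(fitModel(adj, kernels$G, config$prior,
                                            cfgG)))
    for (kn in c("A", "G")) {
      f <- if (kn == "A") fitA else fitG
      writeTSV(posteriorSamples(f),
               file.path(config$outDir,
                         sprintf("posterior_%s_%s.tsv", trait, kn)))
      h <- heritability(f)
      report[[length(report) + 1L]] <-
        data.frame(trait = trait, kernel = h$kernel, h2Pct = h$h2Pct,
                   h2PctSD = h$h2PctSD, logLik = h$logLik)
    }
    cmp <- comparePredictedValues(fitA, fitG, adj)
    writeTSV(cmp$table,
             file.path(config$outDir, sprintf("predicted_%s.tsv", trait)))
    ggplot2::ggsave(file.path(config$outDir,
                              sprintf("predicted_%s.pdf", trait)),
                    plotPredictedValues(cmp), width = 5, height = 5)
    predCors[[trait]] <- c(correlation = cmp$correlation,
                           geneticCorrelation = cmp$geneticCorrelation)
    fits[[trait]] <- list(A = fitA, G = fitG, adjusted = adj,
                          predicted = cmp)
  }
  heritTable <- do.call(rbind, report)
  writeTSV(heritTable, file.path(config$outDir, "heritability.tsv"))
  out <- structure(list(
    heritability = heritTable, coefficients = coefTables, gaBins = ga@bins,
    predictedValues = predCors, setSizes = setSizes, fits = fits,
    truth = inputs$truth,
    provenance = list(seed = config$seed, outDir = config$outDir,
                      timings = timings,
                      totalSeconds = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs")),
                      rVersion = R.version.string)),
    class = "runReport")
  writeLines(format(Sys.time()), stageDone(config$outDir, "report"))
  out
}

#' @export
print.runReport <- function(x, ...) {
  cat("Heritability pipeline report\n")
  cat(sprintf("  individuals analysed: %d (pedigree %d, genotyped %d, phenotyped %d)\n",
              x$setSizes[["analysed"]], x$setSizes[["pedigree"]],
              x$setSizes[["genotypedAfterQC"]], x$setSizes[["phenotyped"]]))
  cat("  heritability estimates (posterior mean % +/- SD):\n")
  h <- x$heritability
  for (k in seq_len(nrow(h)))
    cat(sprintf("    %-8s %-11s %6.2f%% +/- %.2f  logLik %.3f\n",
                h$trait[k], h$kernel[k], h$h2Pct[k], h$h2PctSD[k],
                h$logLik[k]))
  for (tr in names(x$predictedValues))
    cat(sprintf("  predicted-value correlation (%s): %.3f\n", tr,
                x$predictedValues[[tr]][["correlation"]]))
  invisible(x)
}
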