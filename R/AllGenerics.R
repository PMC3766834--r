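#' Individual ids of an object
#'
#' @param x a Pedigree, RelationshipMatrix, GenotypeData, AdjustedPhenotype
#'   or PosteriorSummary
#' @return character vector of individual identifiers, in object order
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @rdname ids
setMethod("ids", "Pedigree", function(x) x@id)
#' @rdname ids
setMethod("ids", "RelationshipMatrix", function(x) rownames(x@values))
#' @rdname ids
setMethod("ids", "GenotypeData", function(x) rownames(x@counts))
#' @rdname ids
setMethod("ids", "AdjustedPhenotype", function(x) x@id)
#' @rdname ids
setMethod("ids", "PosteriorSummary", function(x) x@ids)

#' Number of individuals
#'
#' @param x a Pedigree, RelationshipMatrix or GenotypeData
#' @return integer count
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname nIndividuals
setMethod("nIndividuals", "Pedigree", function(x) length(x@id))
#' @rdname nIndividuals
setMethod("nIndividuals", "RelationshipMatrix", function(x) nrow(x@values))
#' @rdname nIndividuals
setMethod("nIndividuals", "GenotypeData", function(x) nrow(x@counts))

#' Extract the numeric relationship matrix
#'
#' @param x a RelationshipMatrix
#' @return the symmetric numeric matrix with id dimnames
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))

#' @rdname relValues
setMethod("relValues", "RelationshipMatrix", function(x) x@values)

#' Kind of a relationship matrix
#'
#' @param x a RelationshipMatrix
#' @return \code{"pedigree_A"} or \code{"genomic_G"}
#' @export
setGeneric("relKind", function(x) standardGeneric("relKind"))

#' @rdname relKind
setMethod("relKind", "RelationshipMatrix", function(x) x@kind)

#' Genotype allele-count matrix
#'
#' @param x a GenotypeData
#' @return integer matrix (individuals x SNPs), entries 0/1/2/NA
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))

#' @rdname genotypeCounts
setMethod("genotypeCounts", "GenotypeData", function(x) x@counts)

#' Per-SNP coded-allele frequencies
#'
#' @param x a GenotypeData
#' @return numeric vector theta_j, one per SNP
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @rdname alleleFreq
setMethod("alleleFreq", "GenotypeData", function(x) x@theta)

#' Call rates
#'
#' @param x a GenotypeData
#' @param margin \code{"snp"} or \code{"sample"}
#' @return numeric vector of call rates (fractions non-missing)
#' @export
setGeneric("callRate", function(x, margin = "snp") standardGeneric("callRate"))

#' @rdname callRate
setMethod("callRate", "GenotypeData", function(x, margin = "snp") {
  margin <- match.arg(margin, c("snp", "sample"))
  if (margin == "snp") x@snpCallRate else x@sampleCallRate
})

#' Residual (adjusted) phenotype vector
#'
#' @param x an AdjustedPhenotype
#' @return named numeric vector of residuals
#' @export
setGeneric("residualPhenotype", function(x) standardGeneric("residualPhenotype"))

#' @rdname residualPhenotype
setMethod("residualPhenotype", "AdjustedPhenotype",
          function(x) stats::setNames(x@y, x@id))

#' Posterior samples of a fitted genetic model
#'
#' @param x a PosteriorSummary
#' @return data.frame of thinned post-burn-in draws
#' @export
setGeneric("posteriorSamples", function(x) standardGeneric("posteriorSamples"))

#' @rdname posteriorSamples
setMethod("posteriorSamples", "PosteriorSummary", function(x) x@samples)

#' Posterior-mean predicted genetic values
#'
#' @param x a PosteriorSummary
#' @return named numeric vector u-hat
#' @export
setGeneric("geneticValues", function(x) standardGeneric("geneticValues"))

#' @rdname geneticValues
setMethod("geneticValues", "PosteriorSummary",
          function(x) stats::setNames(x@uhat, x@ids))

#' Heritability posterior summary
#'
#' Posterior mean and SD of h2 = s2u/(s2u + s2e), in the percent formatting
#' used for reporting, plus the marginal log-likelihood at posterior means.
#'
#' @param x a PosteriorSummary
#' @return one-row data.frame: kernel, h2Mean, h2SD, h2Pct, h2PctSD, logLik
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname heritability
setMethod("heritability", "PosteriorSummary", function(x) {
  h2 <- x@samples$h2
  data.frame(kernel = x@kernelKind,
             h2Mean = mean(h2), h2SD = stats::sd(h2),
             h2Pct = 100 * mean(h2), h2PctSD = 100 * stats::sd(h2),
             logLik = x@logLik, row.names = NULL)
})

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@sire) & is.na(object@dam))
  cat(sprintf("Pedigree: %d individuals (%d founders), %d cohorts\n",
              length(object@id), nf, length(unique(object@cohort))))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix [%s]: %d x %d\n", object@kind,
              nrow(object@values), ncol(object@values)))
  if (nrow(object@values) > 0)
    cat(sprintf("  mean diagonal %.4f, off-diagonal range [%.4f, %.4f]\n",
                mean(diag(object@values)),
                min(object@values[upper.tri(object@values)]),
                max(object@values[upper.tri(object@values)])))
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d individuals x %d SNPs, %.2f%% missing\n",
              nrow(object@counts), ncol(object@counts),
              100 * mean(is.na(object@counts))))
})

setMethod("show", "AdjustedPhenotype", function(object) {
  cat(sprintf("AdjustedPhenotype [%s]: %d individuals, residual SD %.4f\n",
              object@trait, length(object@y), stats::sd(object@y)))
})

setMethod("show", "PosteriorSummary", function(object) {
  h <- heritability(object)
  cat(sprintf("PosteriorSummary [%s]: %d stored draws\n", object@kernelKind,
              nrow(object@samples)))
  cat(sprintf("  h2 = %.2f%% +/- %.2f (posterior mean +/- SD), logLik %.3f\n",
              h$h2Pct, h$h2PctSD, h$logLik))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "GAComparison", function(object) {
  cat(sprintf("GAComparison: %d pairs, %d pedigree levels\n",
              nrow(object@pairs), nrow(object@bins)))
})
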