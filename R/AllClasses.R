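#' @import methods
NULL

#' Pedigree of a multi-generation family study
#'
#' Ordered parent/offspring records. Individuals are stored in topological
#' order (parents always precede their offspring); the constructor computes
#' this order and refuses cyclic or inconsistent pedigrees. Unknown parents
#' are stored as \code{NA}.
#'
#' @slot id character vector of unique individual identifiers
#' @slot sire,dam character vectors of parent identifiers (\code{NA} = unknown)
#' @slot sex character vector, one of \code{"M"}, \code{"F"}, \code{"U"}
#' @slot cohort integer generation/cohort index (founders = 1)
#' @seealso [Pedigree()], [buildA()], [simulatePedigree()]
#' @exportClass Pedigree
setClass("Pedigree",
  representation(id = "character", sire = "character", dam = "character",
                 sex = "character", cohort = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@sex) != n || length(object@cohort) != n)
    return("all slots must have the same length")
  if (anyDuplicated(object@id))
    return(paste("duplicate individual id(s):",
                 paste(unique(object@id[duplicated(object@id)]), collapse = ", ")))
  pos <- seq_len(n)
  names(pos) <- object@id
  for (p in list(object@sire, object@dam)) {
    known <- !is.na(p)
    if (any(known & !(p %in% object@id)))
      return(paste("parent id(s) not present as individuals:",
                   paste(setdiff(p[known], object@id), collapse = ", ")))
    if (any(pos[p[known]] >= pos[known]))
      return("pedigree is not topologically ordered (a parent follows its offspring)")
  }
  if (any(object@id == object@sire, na.rm = TRUE) ||
      any(object@id == object@dam, na.rm = TRUE))
    return("an individual cannot be its own parent")
  if (!all(object@sex %in% c("M", "F", "U")))
    return("sex must be one of 'M', 'F', 'U'")
  TRUE
})

#' Additive relationship matrix (pedigree A or genomic G)
#'
#' A symmetric positive semidefinite kernel over the study individuals.
#' \code{kind} distinguishes the pedigree expectation (\code{"pedigree_A"},
#' entries are twice the kinship coefficients) from the marker-realized
#' genomic relationship matrix (\code{"genomic_G"}).
#'
#' @slot values symmetric numeric matrix with individual ids as dimnames
#' @slot kind either \code{"pedigree_A"} or \code{"genomic_G"}
#' @seealso [buildA()], [computeG()], [compareGA()]
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(values = "matrix", kind = "character"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("matrix must carry individual ids as dimnames")
  if (!identical(rownames(v), colnames(v)))
    return("row and column ids must agree")
  if (!object@kind %in% c("pedigree_A", "genomic_G"))
    return("kind must be 'pedigree_A' or 'genomic_G'")
  tol <- if (object@kind == "pedigree_A") 1e-12 else 1e-8
  if (nrow(v) > 0 && max(abs(v - t(v))) > tol)
    return(sprintf("matrix is not symmetric (max asymmetry %.3g)", max(abs(v - t(v)))))
  TRUE
})

#' Genotype matrix with per-SNP metadata
#'
#' Allele counts (0/1/2 copies of the coded allele, \code{NA} = missing) for
#' n individuals at p SNPs, together with the per-SNP estimated coded-allele
#' frequency and call rates. After [filterGenotypes()] the frequencies are
#' frozen: [imputeMissing()] and [computeG()] reuse them without
#' re-estimation.
#'
#' @slot counts integer-valued matrix, individuals x SNPs, entries 0/1/2/NA
#' @slot theta per-SNP frequency of the coded allele (from non-missing entries)
#' @slot snpCallRate,sampleCallRate fractions of non-missing entries
#' @slot metadata list; carries exclusion logs and processing notes
#' @seealso [GenotypeData()], [filterGenotypes()], [computeG()]
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(counts = "matrix", theta = "numeric",
                 snpCallRate = "numeric", sampleCallRate = "numeric",
                 metadata = "list"))

setValidity("GenotypeData", function(object) {
  x <- object@counts
  if (is.null(rownames(x)) || is.null(colnames(x)))
    return("counts must carry individual and SNP ids as dimnames")
  bad <- !(x %in% c(0L, 1L, 2L) | is.na(x))
  if (any(bad)) return("genotype entries must be 0, 1, 2 or NA")
  if (length(object@theta) != ncol(x)) return("theta must have one entry per SNP")
  if (any(object@theta < 0 | object@theta > 1, na.rm = TRUE))
    return("theta must lie in [0, 1]")
  if (length(object@snpCallRate) != ncol(x)) return("snpCallRate length mismatch")
  if (length(object@sampleCallRate) != nrow(x)) return("sampleCallRate length mismatch")
  TRUE
})

#' Covariate-adjusted phenotype
#'
#' Residuals of an ordinary least-squares regression of a phenotype on fixed
#' covariates (sex, age, PCs, cohort), together with the coefficient table
#' and the fitted (fixed-effect) values needed later for predicted genetic
#' values.
#'
#' @slot id individual ids of the modeled rows
#' @slot y residual phenotype (mean zero; the genetic-model outcome)
#' @slot fitted fixed-effect fitted values on the same rows
#' @slot coefficients data.frame: term, estimate, se, t, p
#' @slot nUsed number of rows modeled after dropping missing phenotypes
#' @slot trait phenotype label
#' @seealso [fitFixedEffects()], [fitModel()]
#' @exportClass AdjustedPhenotype
setClass("AdjustedPhenotype",
  representation(id = "character", y = "numeric", fitted = "numeric",
                 coefficients = "data.frame", nUsed = "integer",
                 trait = "character"))

setValidity("AdjustedPhenotype", function(object) {
  if (length(object@y) != length(object@id)) return("y/id length mismatch")
  if (length(object@fitted) != length(object@id)) return("fitted/id length mismatch")
  TRUE
})

#' Scaled-inverse-chi-square prior for variance components
#'
#' Density proportional to (s2)^-(df/2 + 1) * exp(-scale / (2 s2)), i.e. the
#' distribution of scale / chisq(df); prior mean scale/(df - 2). The default
#' (scale 2, df 5) is weakly informative with prior mean 2/3.
#'
#' @slot scale positive scale parameter S
#' @slot df positive degrees of freedom nu
#' @seealso [priorSpec()], [fitModel()]
#' @exportClass PriorSpec
setClass("PriorSpec", representation(scale = "numeric", df = "numeric"))

setValidity("PriorSpec", function(object) {
  if (object@scale <= 0) return("scale must be > 0")
  if (object@df <= 0) return("df must be > 0")
  TRUE
})

#' Gibbs sampler settings
#'
#' @slot nIter total iterations
#' @slot burnIn iterations discarded before storing
#' @slot thin keep every thin-th post-burn-in draw
#' @slot seed RNG seed for the chain
#' @slot initH2 starting heritability used to initialize the variances
#' @seealso [gibbsConfig()], [fitModel()]
#' @exportClass GibbsConfig
setClass("GibbsConfig",
  representation(nIter = "integer", burnIn = "integer", thin = "integer",
                 seed = "integer", initH2 = "numeric"))

setValidity("GibbsConfig", function(object) {
  if (object@burnIn >= object@nIter) return("burnIn must be < nIter")
  if (object@thin < 1L) return("thin must be >= 1")
  if (object@initH2 < 0 || object@initH2 > 1) return("initH2 must lie in [0, 1]")
  TRUE
})

#' Posterior summary of the additive genetic model
#'
#' Thinned post-burn-in Gibbs samples of (beta0, s2u, s2e, h2), posterior
#' means/SDs, effective sample sizes, the posterior-mean genetic values
#' u-hat, and the Gaussian marginal log-likelihood evaluated at the
#' posterior-mean parameters.
#'
#' @slot samples data.frame with columns iter, beta0, s2u, s2e, h2
#' @slot uhat named numeric vector of posterior-mean genetic values
#' @slot ids individual ids (order matches uhat)
#' @slot logLik marginal Gaussian log-likelihood at posterior means
#' @slot ess named effective sample sizes (beta0, s2u, s2e, h2)
#' @slot kernelKind kind of the kernel used ("pedigree_A" / "genomic_G")
#' @slot notes character vector of runtime diagnostics/warnings
#' @seealso [fitModel()], [heritability()], [comparePredictedValues()]
#' @exportClass PosteriorSummary
setClass("PosteriorSummary",
  representation(samples = "data.frame", uhat = "numeric", ids = "character",
                 logLik = "numeric", ess = "numeric", kernelKind = "character",
                 notes = "character"))

setValidity("PosteriorSummary", function(object) {
  need <- c("iter", "beta0", "s2u", "s2e", "h2")
  if (!all(need %in% names(object@samples)))
    return("samples must have columns iter, beta0, s2u, s2e, h2")
  if (any(object@samples$s2u <= 0) || any(object@samples$s2e <= 0))
    return("variance samples must be positive")
  if (any(object@samples$h2 <= 0 | object@samples$h2 >= 1))
    return("h2 samples must lie in (0, 1)")
  if (length(object@uhat) != length(object@ids)) return("uhat/ids length mismatch")
  TRUE
})

#' G-vs-A comparison of realized and expected relationships
#'
#' Pairs every entry of the genomic relationship matrix G with the matching
#' pedigree expectation A, and summarizes the deviations d = G - A within
#' bins defined by the exact pedigree relationship level (0, 0.125, 0.25,
#' 0.5, ...). The diagonal (self-relationships) is kept but flagged.
#'
#' @slot pairs data.frame: i, j, A, G, d, diagonal flag
#' @slot bins data.frame per level: n, meanG, varG, meanD
#' @seealso [compareGA()], [plotGA()]
#' @exportClass GAComparison
setClass("GAComparison",
  representation(pairs = "data.frame", bins = "data.frame"))
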