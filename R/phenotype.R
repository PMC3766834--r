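#' Pre-adjust a phenotype for fixed covariates
#'
#' Ordinary least squares of one phenotype on the fixed covariates (by
#' default the female indicator, age, the first two ancestry PCs and cohort
#' dummy-coded against its first level), fitted by QR decomposition via
#' \code{lm()}. The residuals become the outcome of the downstream genetic
#' model; the coefficient table (estimate, SE, t, p per term, cohort levels
#' as separate rows) and the fitted fixed-effect values are kept for
#' reporting and for predicted genetic values. Rows with a missing
#' phenotype are dropped (and counted); missing covariates among modeled
#' rows are an error.
#'
#' @param pheno data.frame with an \code{id} column, the phenotype column,
#'   and the covariate columns
#' @param trait name of the phenotype column
#' @param covariates character vector of covariate column names; a column
#'   named \code{cohort} is treated as categorical (reference = first level)
#' @return an [AdjustedPhenotype-class]
#' @examples
#' d <- data.frame(id = as.character(1:50), female = rep(0:1, 25),
#'                 age = seq(20, 80, length.out = 50))
#' d$y <- 1 - 0.5 * d$female + 0.02 * d$age  # exact linear, no noise
#' fit <- fitFixedEffects(d, "y", c("female", "age"))
#' max(abs(residualPhenotype(fit)))  # ~0
#' @export
fitFixedEffects <- function(pheno, trait,
                            covariates = c("female", "age", "pc1", "pc2",
                                           "cohort")) {
  stopifnot(is.data.frame(pheno), "id" %in% names(pheno),
            trait %in% names(pheno))
  miss <- setdiff(covariates, names(pheno))
  if (length(miss)) stop("covariate column(s) absent: ",
                         paste(miss, collapse = ", "))
  keep <- !is.na(pheno[[trait]])
  nDropped <- sum(!keep)
  d <- pheno[keep, , drop = FALSE]
  if (length(covariates)) {
    cm <- vapply(d[covariates], function(z) any(is.na(z)), logical(1))
    if (any(cm)) stop("missing covariate values among modeled rows: ",
                      paste(covariates[cm], collapse = ", "))
  }
  terms <- vapply(covariates, function(v) {
    if (v == "cohort") "factor(cohort)" else v
  }, character(1))
  fml <- stats::reformulate(if (length(terms)) terms else "1",
                            response = trait)
  if (nrow(d) <= length(covariates) + 1L)
    stop("fewer observations than parameters (n = ", nrow(d), ")")
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  ct <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1L],
                      se = ct[, 2L], t = ct[, 3L], p = ct[, 4L],
                      row.names = NULL)
  ap <- new("AdjustedPhenotype", id = as.character(d$id),
            y = as.numeric(stats::residuals(fit)),
            fitted = as.numeric(stats::fitted(fit)),
            coefficients = coefs, nUsed = nrow(d), trait = trait)
  if (nDropped > 0)
    message(nDropped, " row(s) with missing ", trait, " dropped")
  ap
}

#' Keep the latest examination per individual
#'
#' For repeated-measure phenotype tables keyed by an examination index,
#' retains the row with the highest exam number for each individual.
#'
#' @param pheno data.frame with id and exam columns
#' @param idCol,examCol column names (defaults \code{"id"}, \code{"exam"})
#' @return data.frame with one row per individual
#' @export
latestExam <- function(pheno, idCol = "id", examCol = "exam") {
  stopifnot(idCol %in% names(pheno), examCol %in% names(pheno))
  ord <- order(pheno[[idCol]], -pheno[[examCol]])
  d <- pheno[ord, , drop = FALSE]
  d[!duplicated(d[[idCol]]), , drop = FALSE]
}

#' Pairwise correlations among phenotypes
#'
#' Pearson correlations over complete rows, reported with the n used.
#' Zero-variance columns yield \code{NA} with a warning flag.
#'
#' @param pheno data.frame of phenotypes
#' @param traits character vector of phenotype column names
#' @return data.frame: trait1, trait2, r, n, degenerate flag
#' @export
phenotypeCorrelations <- function(pheno, traits) {
  stopifnot(all(traits %in% names(pheno)))
  cc <- stats::complete.cases(pheno[traits])
  if (sum(cc) < 3L) stop("need at least 3 complete rows")
  d <- pheno[cc, traits, drop = FALSE]
  out <- list()
  for (a in seq_along(traits)) for (b in seq_along(traits)) {
    if (a >= b) next
    va <- stats::var(d[[a]]); vb <- stats::var(d[[b]])
    degenerate <- va == 0 || vb == 0
    out[[length(out) + 1L]] <- data.frame(
      trait1 = traits[a], trait2 = traits[b],
      r = if (degenerate) NA_real_ else stats::cor(d[[a]], d[[b]]),
      n = nrow(d), degenerate = degenerate)
  }
  res <- do.call(rbind, out)
  if (any(res$degenerate))
    warning("zero-variance column(s): correlation undefined")
  res
}
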