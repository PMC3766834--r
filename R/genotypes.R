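#' Construct a GenotypeData object
#'
#' Wraps an individuals x SNPs allele-count matrix (0/1/2 copies of the
#' coded allele, \code{NA} missing) and computes per-SNP coded-allele
#' frequencies and call rates from the non-missing entries. Supplying
#' \code{theta} freezes the frequencies instead of re-estimating them (used
#' after QC so that imputation and G construction share one estimate).
#'
#' @param counts numeric/integer matrix with individual ids as rownames and
#'   SNP ids as colnames
#' @param theta optional frozen per-SNP coded-allele frequencies
#' @param metadata optional list of processing notes
#' @return a [GenotypeData-class]
#' @export
GenotypeData <- function(counts, theta = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("ind", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("snp", seq_len(ncol(counts)))
  obs <- !is.na(counts)
  if (is.null(theta)) {
    theta <- colSums(counts * obs, na.rm = TRUE) / (2 * colSums(obs))
  } else {
    stopifnot(length(theta) == ncol(counts))
  }
  new("GenotypeData", counts = counts, theta = as.numeric(theta),
      snpCallRate = colMeans(obs), sampleCallRate = rowMeans(obs),
      metadata = metadata)
}

#' Quality-control filter on call rate and minor allele frequency
#'
#' Applies the standard marker QC: individuals with call rate below
#' \code{minCallRate} are removed first; SNP call rates and allele
#' frequencies are then recomputed on the remaining individuals; finally
#' SNPs with call rate below \code{minCallRate} or minor allele frequency
#' \code{min(theta, 1 - theta)} below \code{minMAF} are removed. The
#' surviving object carries the post-filter frequencies frozen for the
#' downstream imputation and G construction, plus an exclusion log naming
#' every removed token with its reason and value.
#'
#' @param raw a [GenotypeData-class]
#' @param minCallRate minimum fraction of non-missing genotypes (default 0.90)
#' @param minMAF minimum minor allele frequency (default 0.005)
#' @return a [GenotypeData-class]; the exclusion log is in
#'   \code{metadata(x)$exclusions} (columns token, type, reason, value)
#' @export
filterGenotypes <- function(raw, minCallRate = 0.90, minMAF = 0.005) {
  stopifnot(is(raw, "GenotypeData"),
            minCallRate > 0, minCallRate < 1, minMAF > 0, minMAF < 1)
  logs <- list()
  badInd <- raw@sampleCallRate < minCallRate
  if (any(badInd))
    logs$ind <- data.frame(token = rownames(raw@counts)[badInd],
                           type = "individual", reason = "call_rate",
                           value = raw@sampleCallRate[badInd])
  counts <- raw@counts[!badInd, , drop = FALSE]
  if (nrow(counts) == 0L)
    stop("all individuals removed by the call-rate filter")
  obs <- !is.na(counts)
  snpCR <- colMeans(obs)
  denom <- 2 * colSums(obs)
  theta <- ifelse(denom > 0, colSums(counts * obs, na.rm = TRUE) / denom, NaN)
  maf <- pmin(theta, 1 - theta)
  badCR <- snpCR < minCallRate
  badMAF <- !badCR & (is.nan(maf) | maf < minMAF)
  if (any(badCR))
    logs$snpcr <- data.frame(token = colnames(counts)[badCR], type = "snp",
                             reason = "call_rate", value = snpCR[badCR])
  if (any(badMAF))
    logs$snpmaf <- data.frame(token = colnames(counts)[badMAF], type = "snp",
                              reason = "maf", value = maf[badMAF])
  keep <- !(badCR | badMAF)
  if (!any(keep))
    stop("all SNPs removed by the call-rate/MAF filters")
  excl <- if (length(logs)) do.call(rbind, unname(logs)) else
    data.frame(token = character(), type = character(),
               reason = character(), value = numeric())
  rownames(excl) <- NULL
  GenotypeData(counts[, keep, drop = FALSE], theta = theta[keep],
               metadata = c(raw@metadata,
                            list(exclusions = excl, thetaFrozen = TRUE)))
}

#' Impute missing genotypes under Hardy-Weinberg equilibrium
#'
#' Every missing allele count x_ij is replaced by an independent draw from
#' Binomial(2, theta_j), using the frozen per-SNP frequency estimate; theta
#' is not re-estimated afterwards. With no missing entries the input is
#' returned unchanged and the RNG is not touched.
#'
#' @param g a [GenotypeData-class] (typically output of [filterGenotypes()])
#' @param seed integer RNG seed
#' @return a [GenotypeData-class] with no missing entries and the same theta
#' @export
imputeMissing <- function(g, seed = 1L) {
  stopifnot(is(g, "GenotypeData"))
  counts <- g@counts
  nmiss <- colSums(is.na(counts))
  if (!any(nmiss > 0)) return(g)
  empty <- nmiss == nrow(counts)
  if (any(empty))
    stop("SNP(s) with zero non-missing entries cannot be imputed: ",
         paste(colnames(counts)[empty], collapse = ", "))
  set.seed(as.integer(seed))
  for (j in which(nmiss > 0)) {
    miss <- is.na(counts[, j])
    counts[miss, j] <- stats::rbinom(sum(miss), 2L, g@theta[j])
  }
  GenotypeData(counts, theta = g@theta,
               metadata = c(g@metadata, list(imputed = sum(nmiss))))
}

#' Genomic relationship matrix from standardized allele counts
#'
#' Computes the marker-realized relationship matrix with entries
#' \deqn{G_{ik} = \frac1p \sum_{j=1}^p
#'   \frac{(x_{ij} - 2\theta_j)(x_{kj} - 2\theta_j)}{2\theta_j(1-\theta_j)}}
#' where x_ij is the coded-allele count and theta_j its estimated frequency.
#' The same formula is used on the diagonal. Genotypes must be complete
#' (impute first) and polymorphic (monomorphic SNPs must have been
#' filtered, otherwise the standardization divides by zero).
#'
#' @param g a complete [GenotypeData-class]
#' @return a [RelationshipMatrix-class] with \code{kind = "genomic_G"}
#' @examples
#' x <- matrix(c(2L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' relValues(computeG(GenotypeData(x, theta = 0.5)))  # 2 on diag, -2 off
#' @export
computeG <- function(g) {
  stopifnot(is(g, "GenotypeData"))
  if (anyNA(g@counts))
    stop("genotypes contain missing entries; run imputeMissing() first")
  bad <- g@theta <= 0 | g@theta >= 1
  if (any(bad))
    stop("monomorphic SNP(s) (theta 0 or 1) break the standardization; ",
         "run filterGenotypes() first: ",
         paste(utils::head(colnames(g@counts)[bad], 5), collapse = ", "))
  p <- ncol(g@counts)
  Z <- sweep(g@counts, 2L, 2 * g@theta, "-")
  W <- sweep(Z, 2L, sqrt(2 * g@theta * (1 - g@theta)), "/")
  G <- tcrossprod(W) / p
  G <- (G + t(G)) / 2
  new("RelationshipMatrix", values = G, kind = "genomic_G")
}

#' Ensure positive semidefiniteness for the sampler
#'
#' If the minimum eigenvalue falls below \code{1e-10} a jitter of
#' \code{1e-8} is added to the diagonal (logged in the returned attribute);
#' a matrix indefinite beyond jitter repair is an error.
#'
#' @param K a [RelationshipMatrix-class]
#' @return the (possibly jittered) RelationshipMatrix, with attribute
#'   \code{"jittered"} TRUE/FALSE
#' @export
ensurePSD <- function(K) {
  stopifnot(is(K, "RelationshipMatrix"))
  ev <- eigen(K@values, symmetric = TRUE, only.values = TRUE)$values
  jittered <- FALSE
  if (min(ev) < -1e-6 * max(abs(ev)))
    stop(sprintf("relationship matrix is indefinite (min eigenvalue %.3g)",
                 min(ev)))
  if (min(ev) < 1e-10) {
    K@values <- K@values + diag(1e-8, nrow(K@values))
    jittered <- TRUE
  }
  attr(K, "jittered") <- jittered
  K
}

#' Compare realized (G) against expected (A) relationships
#'
#' Pairs each entry of G with the matching A entry, bins pairs by the exact
#' pedigree relationship level (0, 0.125, 0.25, 0.5, ... and the diagonal),
#' and summarizes per-bin mean/variance of G and of the Mendelian-sampling
#' deviations d = G - A. Over many unlinked markers E[G_ij] = A_ij, so bin
#' means of d converge to 0.
#'
#' @param G a genomic [RelationshipMatrix-class]
#' @param A a pedigree [RelationshipMatrix-class] over the same individuals,
#'   in the same order
#' @return a [GAComparison-class]
#' @export
compareGA <- function(G, A) {
  stopifnot(is(G, "RelationshipMatrix"), is(A, "RelationshipMatrix"))
  if (!identical(ids(G), ids(A))) {
    extraG <- setdiff(ids(G), ids(A))
    extraA <- setdiff(ids(A), ids(G))
    stop("id mismatch between G and A; only in G: {",
         paste(extraG, collapse = ", "), "}; only in A: {",
         paste(extraA, collapse = ", "), "}",
         if (!length(extraG) && !length(extraA))
           " (same sets, different order)" else "")
  }
  n <- nrow(G@values)
  ut <- upper.tri(G@values, diag = TRUE)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(
    i = ids(G)[idx[, 1L]], j = ids(G)[idx[, 2L]],
    A = A@values[ut], G = G@values[ut],
    d = G@values[ut] - A@values[ut],
    diagonal = idx[, 1L] == idx[, 2L])
  lev <- ifelse(pairs$diagonal, paste0("diag:", pairs$A), as.character(pairs$A))
  sp <- split(seq_len(nrow(pairs)), lev)
  bins <- do.call(rbind, lapply(names(sp), function(l) {
    k <- sp[[l]]
    data.frame(level = l, A = pairs$A[k[1L]], diagonal = pairs$diagonal[k[1L]],
               n = length(k), meanG = mean(pairs$G[k]),
               varG = if (length(k) > 1L) stats::var(pairs$G[k]) else 0,
               meanD = mean(pairs$d[k]))
  }))
  bins <- bins[order(bins$diagonal, bins$A), ]
  rownames(bins) <- NULL
  new("GAComparison", pairs = pairs, bins = bins)
}

#' Scatter of genomic vs pedigree relationship coefficients
#'
#' Renders the realized genomic coefficients against the pedigree
#' expectation, with horizontal dashed reference lines at the expected
#' levels. Returns a ggplot object (save with \code{ggplot2::ggsave()}).
#'
#' @param cmp a [GAComparison-class]
#' @param includeDiagonal include self-relationships (default FALSE)
#' @return a ggplot object
#' @export
plotGA <- function(cmp, includeDiagonal = FALSE) {
  stopifnot(is(cmp, "GAComparison"))
  d <- cmp@pairs
  if (!includeDiagonal) d <- d[!d$diagonal, ]
  levels <- sort(unique(d$A))
  ggplot2::ggplot(d, ggplot2::aes(x = A, y = G)) +
    ggplot2::geom_jitter(width = diff(range(levels, 0, 1)) / 80, height = 0,
                         alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = levels, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Pedigree relationship (A)",
                  y = "Genomic relationship (G)") +
    ggplot2::theme_minimal()
}
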