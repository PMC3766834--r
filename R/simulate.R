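utils::globalVariables(c("A", "G"))

#' Specification of a synthetic family study
#'
#' Bundles every knob of the generator: pedigree shape, marker panel,
#' founder allele-frequency law, true heritability, covariate effects,
#' genotype missingness and the master seed. Defaults emulate a
#' three-generation human family study with a quantitative trait of
#' heritability 0.5, Table-style covariate effects (female-coded sex
#' indicator, linear age, cohort shifts), uniform founder MAF on
#' (0.05, 0.5) so every SNP is polymorphic and QC-survivable, and roughly
#' 1\% genotype missingness.
#'
#' @param nFounders number of founders (generation 1); must be >= 2
#' @param nGenerations number of generations including founders (>= 1)
#' @param offspringPerMating offspring per mated pair
#' @param nSNPs number of biallelic SNPs (dropped independently)
#' @param mafRange support of the Uniform founder allele-frequency law;
#'   must exclude 0 and 1
#' @param trueH2 true narrow-sense heritability in [0, 1]
#' @param totalVariance genetic + residual phenotype variance (> 0)
#' @param covariateEffects list with elements \code{sex} (effect of the
#'   female indicator), \code{age}, \code{pc1}, \code{pc2} and
#'   \code{cohort} (vector of per-generation shifts, first = reference 0)
#' @param geneticModel \code{"marker_effects"} (u from per-SNP effects on
#'   the gene-dropped genotypes) or \code{"infinitesimal"} (u multivariate
#'   normal with covariance A * s2u)
#' @param missingRate fraction of genotype entries masked at random, in [0, 1)
#' @param seed master integer seed; all stage seeds derive from it
#' @return a validated list of class \code{"simSpec"}
#' @export
simSpec <- function(nFounders = 40L, nGenerations = 3L,
                    offspringPerMating = 3L, nSNPs = 5000L,
                    mafRange = c(0.05, 0.5), trueH2 = 0.5,
                    totalVariance = 1,
                    covariateEffects = list(sex = -0.96, age = -0.032,
                                            pc1 = 0, pc2 = 0,
                                            cohort = c(0, 0.28, 0.44)),
                    geneticModel = c("marker_effects", "infinitesimal"),
                    missingRate = 0.01, seed = 1L) {
  geneticModel <- match.arg(geneticModel)
  stopifnot(nFounders >= 1L, nGenerations >= 1L, offspringPerMating >= 1L,
            nSNPs >= 1L, trueH2 >= 0, trueH2 <= 1, totalVariance > 0,
            missingRate >= 0, missingRate < 1)
  if (mafRange[1] <= 0 || mafRange[2] >= 1 || mafRange[1] > mafRange[2])
    stop("mafRange must lie strictly inside (0, 1)")
  for (nm in c("sex", "age", "pc1", "pc2", "cohort"))
    if (is.null(covariateEffects[[nm]]))
      covariateEffects[[nm]] <- if (nm == "cohort") 0 else 0
  structure(list(nFounders = as.integer(nFounders),
                 nGenerations = as.integer(nGenerations),
                 offspringPerMating = as.integer(offspringPerMating),
                 nSNPs = as.integer(nSNPs), mafRange = mafRange,
                 trueH2 = trueH2, totalVariance = totalVariance,
                 covariateEffects = covariateEffects,
                 geneticModel = geneticModel,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "simSpec")
}

# deterministic stage seeds derived from the master seed; kept < 2^31
deriveSeed <- function(seed, stage) {
  offsets <- c(pedigree = 11L, theta = 29L, genedrop = 47L, missing = 61L,
               covariates = 83L, phenotype = 101L, fitA = 131L, fitG = 151L)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% 2147483629L
}

#' Simulate a multi-generation pedigree
#'
#' Founders form generation 1 with balanced sexes; within each later
#' generation, males and females of the previous generation are paired into
#' random non-overlapping monogamous matings (no selfing; full-sib matings
#' avoided when a non-sib pairing exists), each producing
#' \code{offspringPerMating} offspring of random sex. The result is in
#' topological order with cohort = generation index.
#'
#' @param spec a [simSpec()] (or arguments forwarded to it)
#' @param seed optional override of the derived stage seed
#' @return a [Pedigree-class]
#' @export
simulatePedigree <- function(spec = simSpec(), seed = NULL) {
  if (spec$nFounders < 2L && spec$nGenerations > 1L)
    stop("cannot form matings with fewer than 2 founders")
  set.seed(if (is.null(seed)) deriveSeed(spec$seed, "pedigree") else seed)
  nf <- spec$nFounders
  id <- sprintf("g1_%04d", seq_len(nf))
  sex <- rep(c("M", "F"), length.out = nf)
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  cohort <- rep(1L, nf)
  sibkey <- rep(NA_character_, nf)  # parent-pair key, to dodge sib matings
  prev <- seq_len(nf)
  if (spec$nGenerations > 1L) for (g in 2L:spec$nGenerations) {
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    npair <- min(length(males), length(females))
    if (npair == 0L) break
    males <- sample(males)
    females <- sample(females)
    # greedy swap to avoid pairing full sibs where possible
    for (k in seq_len(npair)) {
      if (!is.na(sibkey[males[k]]) &&
          identical(sibkey[males[k]], sibkey[females[k]])) {
        alt <- which(sibkey[females[seq_len(npair)]] != sibkey[males[k]] |
                     is.na(sibkey[females[seq_len(npair)]]))
        alt <- setdiff(alt, k)
        if (length(alt)) {
          sw <- alt[1L]
          tmp <- females[k]; females[k] <- females[sw]; females[sw] <- tmp
        }
      }
    }
    cnt <- 0L
    for (k in seq_len(npair)) {
      for (o in seq_len(spec$offspringPerMating)) {
        cnt <- cnt + 1L
        id <- c(id, sprintf("g%d_%04d", g, cnt))
        sire <- c(sire, id[males[k]])
        dam <- c(dam, id[females[k]])
        sex <- c(sex, if (stats::runif(1) < 0.5) "M" else "F")
        cohort <- c(cohort, g)
        sibkey <- c(sibkey, paste(id[males[k]], id[females[k]]))
      }
    }
    prev <- which(cohort == g)
  }
  Pedigree(id = id, sire = sire, dam = dam, sex = sex, cohort = cohort)
}

#' Draw founder allele frequencies
#'
#' @param spec a [simSpec()]
#' @param seed optional override of the derived stage seed
#' @return numeric vector theta_j ~ Uniform(mafRange), one per SNP
#' @export
drawFounderFreqs <- function(spec, seed = NULL) {
  set.seed(if (is.null(seed)) deriveSeed(spec$seed, "theta") else seed)
  stats::runif(spec$nSNPs, spec$mafRange[1], spec$mafRange[2])
}

#' Gene dropping: simulate genotypes down a pedigree
#'
#' Founders receive two alleles i.i.d. Bernoulli(theta_j) per SNP; each
#' non-founder inherits one uniformly chosen allele from each parent's two
#' (an unknown parent contributes a fresh founder allele). SNPs segregate
#' independently (no linkage), so realized relationships scatter around
#' their pedigree expectation purely by Mendelian sampling, with
#' E[G_ij] = A_ij.
#'
#' @param pedigree a [Pedigree-class] (topologically ordered)
#' @param theta per-SNP founder allele frequencies in [0, 1]
#' @param seed integer RNG seed
#' @return a complete [GenotypeData-class] (entries 0/1/2, no missing)
#' @export
geneDrop <- function(pedigree, theta, seed = 1L) {
  stopifnot(is(pedigree, "Pedigree"), all(theta >= 0 & theta <= 1))
  n <- length(pedigree@id)
  p <- length(theta)
  si <- match(pedigree@sire, pedigree@id)
  di <- match(pedigree@dam, pedigree@id)
  late <- which(si > seq_len(n) | di > seq_len(n))
  if (length(late))
    stop("pedigree is not topologically ordered; first offending record: ",
         pedigree@id[late[1L]])
  set.seed(as.integer(seed))
  H1 <- matrix(0L, n, p)
  H2 <- matrix(0L, n, p)
  for (i in seq_len(n)) {
    H1[i, ] <- if (is.na(si[i])) stats::rbinom(p, 1L, theta) else
      ifelse(stats::runif(p) < 0.5, H1[si[i], ], H2[si[i], ])
    H2[i, ] <- if (is.na(di[i])) stats::rbinom(p, 1L, theta) else
      ifelse(stats::runif(p) < 0.5, H1[di[i], ], H2[di[i], ])
  }
  counts <- H1 + H2
  dimnames(counts) <- list(pedigree@id, sprintf("snp%05d", seq_len(p)))
  GenotypeData(counts, metadata = list(founderTheta = theta))
}

#' Simulate covariates for a pedigree
#'
#' Sex is taken from the pedigree; age ~ Uniform(19, 92) (the adult range
#' of a long-running cohort study); pc1, pc2 ~ N(0, 1) as ancestry proxies;
#' cohort is the generation index.
#'
#' @param pedigree a [Pedigree-class]
#' @param seed integer RNG seed
#' @return data.frame: id, sex ("M"/"F"), female (0/1), age, pc1, pc2, cohort
#' @export
simulateCovariates <- function(pedigree, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(pedigree@id)
  sex <- ifelse(pedigree@sex == "U",
                ifelse(stats::runif(n) < 0.5, "M", "F"), pedigree@sex)
  data.frame(id = pedigree@id, sex = sex,
             female = as.integer(sex == "F"),
             age = stats::runif(n, 19, 92),
             pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
             cohort = pedigree@cohort)
}

#' Simulate phenotypes with known true heritability
#'
#' Builds y = covariate contribution + u + e. In \code{marker_effects} mode
#' the genetic value is \eqn{u_i = \sum_j (x_{ij} - 2\theta_j) a_j} with
#' per-SNP effects \eqn{a_j \sim N(0, \sigma^2_u / \sum_j 2\theta_j(1-\theta_j))},
#' so that Var(u) targets s2u and the generative model aligns with the
#' standardized-G denominator. In \code{infinitesimal} mode
#' u ~ MVN(0, A * s2u). Residuals are i.i.d. N(0, s2e) with
#' s2u = trueH2 * totalVariance and s2e = (1 - trueH2) * totalVariance.
#'
#' @param pedigree a [Pedigree-class]
#' @param spec a [simSpec()]
#' @param genotypes a [GenotypeData-class] (marker_effects mode); founder
#'   theta is read from its metadata unless \code{theta} is given
#' @param A a pedigree [RelationshipMatrix-class] (infinitesimal mode)
#' @param covariates optional data.frame from [simulateCovariates()]
#' @param theta optional founder allele frequencies (marker_effects mode)
#' @param seed optional override of the derived stage seed
#' @return list with \code{phenotypes} (data.frame id, y, female, age, pc1,
#'   pc2, cohort) and \code{truth} (list u, s2u, s2e, h2, causalEffects)
#' @export
simulatePhenotype <- function(pedigree, spec, genotypes = NULL, A = NULL,
                              covariates = NULL, theta = NULL, seed = NULL) {
  stopifnot(is(pedigree, "Pedigree"))
  if (is.null(genotypes) == is.null(A))
    stop("supply exactly one of 'genotypes' (marker_effects) or 'A' ",
         "(infinitesimal)")
  if (!is.null(genotypes) && spec$geneticModel != "marker_effects")
    stop("genotypes supplied but geneticModel is ", spec$geneticModel)
  if (!is.null(A) && spec$geneticModel != "infinitesimal")
    stop("A supplied but geneticModel is ", spec$geneticModel)
  n <- length(pedigree@id)
  s2u <- spec$trueH2 * spec$totalVariance
  s2e <- (1 - spec$trueH2) * spec$totalVariance
  if (s2e == 0)
    message("degenerate residual: trueH2 = 1 gives s2e = 0")
  if (is.null(covariates))
    covariates <- simulateCovariates(pedigree,
                                     deriveSeed(spec$seed, "covariates"))
  set.seed(if (is.null(seed)) deriveSeed(spec$seed, "phenotype") else seed)
  eff <- spec$covariateEffects
  cohortEff <- rep_len(eff$cohort, max(covariates$cohort))
  fixed <- eff$sex * covariates$female + eff$age * covariates$age +
    eff$pc1 * covariates$pc1 + eff$pc2 * covariates$pc2 +
    cohortEff[covariates$cohort]
  causal <- NULL
  if (s2u == 0) {
    u <- rep(0, n)
  } else if (spec$geneticModel == "marker_effects") {
    if (is.null(theta)) theta <- genotypes@metadata$founderTheta
    if (is.null(theta)) theta <- genotypes@theta
    x <- genotypes@counts[pedigree@id, , drop = FALSE]
    if (anyNA(x))
      stop("marker_effects mode needs complete genotypes (simulate before ",
           "injecting missingness)")
    denom <- sum(2 * theta * (1 - theta))
    causal <- stats::rnorm(ncol(x), 0, sqrt(s2u / denom))
    u <- as.numeric(sweep(x, 2L, 2 * theta, "-") %*% causal)
  } else {
    Av <- relValues(A)[pedigree@id, pedigree@id]
    L <- chol(Av + diag(1e-10, n))
    u <- as.numeric(crossprod(L, stats::rnorm(n)) * sqrt(s2u))
  }
  y <- fixed + u + stats::rnorm(n, 0, sqrt(s2e))
  pheno <- data.frame(id = pedigree@id, y = y,
                      female = covariates$female, age = covariates$age,
                      pc1 = covariates$pc1, pc2 = covariates$pc2,
                      cohort = covariates$cohort)
  list(phenotypes = pheno,
       truth = list(u = stats::setNames(u, pedigree@id), s2u = s2u,
                    s2e = s2e, h2 = spec$trueH2, causalEffects = causal))
}

#' Mask genotype entries at random
#'
#' Each entry is set missing independently with the given probability;
#' per-SNP and per-individual call rates (and frequencies, from the
#' remaining entries) are recomputed.
#'
#' @param genotypes a [GenotypeData-class]
#' @param rate missingness probability in [0, 1)
#' @param seed integer RNG seed
#' @return a [GenotypeData-class] with missing entries
#' @export
injectMissingness <- function(genotypes, rate, seed = 1L) {
  stopifnot(is(genotypes, "GenotypeData"), rate >= 0, rate < 1)
  if (rate == 0) return(genotypes)
  set.seed(as.integer(seed))
  counts <- genotypes@counts
  mask <- stats::runif(length(counts)) < rate
  counts[mask] <- NA_integer_
  GenotypeData(counts, metadata = genotypes@metadata)
}

#' Simulate a complete family study
#'
#' Orchestrates the generator end to end: pedigree, founder allele
#' frequencies, gene-dropped genotypes, optional missingness, covariates
#' and phenotypes with known truth. Every stage seed derives
#' deterministically from \code{spec$seed}, so reruns are byte-identical.
#'
#' @param spec a [simSpec()]
#' @return list: pedigree, genotypes (complete), genotypesRaw (with
#'   missingness), theta (founder frequencies), phenotypes, truth
#' @export
simulateStudy <- function(spec = simSpec()) {
  ped <- simulatePedigree(spec)
  theta <- drawFounderFreqs(spec)
  geno <- geneDrop(ped, theta, seed = deriveSeed(spec$seed, "genedrop"))
  if (spec$geneticModel == "infinitesimal") {
    sim <- simulatePhenotype(ped, spec, A = buildA(ped))
  } else {
    sim <- simulatePhenotype(ped, spec, genotypes = geno)
  }
  raw <- injectMissingness(geno, spec$missingRate,
                           seed = deriveSeed(spec$seed, "missing"))
  list(pedigree = ped, genotypes = geno, genotypesRaw = raw, theta = theta,
       phenotypes = sim$phenotypes, truth = sim$truth)
}

#' Simulate spirometry-like traits with a shared lung-size factor
#'
#' A minimal generative model of the two standard spirometry volumes and
#' their ratio: FVC is driven by a common lung-size factor, FEV1 equals an
#' independent airway-patency ratio times FVC. This reproduces the
#' canonical correlation pattern — FEV1 and FVC highly correlated, each
#' only weakly correlated with FEV1/FVC. Purely phenotypic (no genetics);
#' used to exercise [phenotypeCorrelations()].
#'
#' @param n number of individuals
#' @param seed integer RNG seed
#' @return data.frame: id, FEV1, FVC, ratio
#' @export
simulateSpirometry <- function(n = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  size <- stats::rnorm(n, 4.0, 0.9)          # lung size drives FVC (L)
  fvc <- pmax(size + stats::rnorm(n, 0, 0.15), 0.5)
  ratio <- pmin(pmax(stats::rnorm(n, 0.78, 0.06), 0.3), 1)
  fev1 <- ratio * fvc
  data.frame(id = sprintf("s%04d", seq_len(n)),
             FEV1 = fev1, FVC = fvc, ratio = fev1 / fvc)
}
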