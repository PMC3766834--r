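# Shared fixture builders. Everything is generated in code at test time.

# two unrelated founder pairs, a half-sib pair, a full-sib pair and a
# grandchild: covers the classic relationship levels 0, 0.25, 0.5
relationshipZoo <- function() {
  Pedigree(
    id   = c("f1", "f2", "f3", "f4", "c1", "c2", "c3", "g1"),
    sire = c(NA,   NA,   NA,   NA,   "f1", "f1", "f1", "c1"),
    dam  = c(NA,   NA,   NA,   NA,   "f2", "f3", "f2", "f4"),
    sex  = c("M", "F", "F", "F", "M", "F", "F", "M"))
}

# random pedigree with arbitrary matings (selfing excluded): produces
# inbreeding, half sibs and multi-generation loops, good stress input for
# the kinship recursion
randomPedigree <- function(n, nFounders = max(4L, n %/% 4L), seed = 1L) {
  set.seed(seed)
  id <- sprintf("i%03d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (k in (nFounders + 1L):n) {
    par <- sample(k - 1L, 2L)        # distinct earlier individuals
    sire[k] <- id[par[1L]]
    dam[k] <- id[par[2L]]
  }
  Pedigree(id = id, sire = sire, dam = dam)
}

# small complete genotype matrix with controlled frequencies
randomGenotypes <- function(n, p, seed = 1L, theta = NULL) {
  set.seed(seed)
  if (is.null(theta)) theta <- runif(p, 0.1, 0.5)
  counts <- vapply(theta, function(th) rbinom(n, 2L, th), integer(n))
  # guarantee polymorphism in tiny panels
  mono <- apply(counts, 2L, function(x) length(unique(x)) == 1L)
  counts[1L, mono] <- ifelse(counts[1L, mono] == 0L, 1L, 0L)
  dimnames(counts) <- list(sprintf("ind%03d", seq_len(n)),
                           sprintf("snp%03d", seq_len(p)))
  GenotypeData(counts)
}

# naive two-nested-loop genomic relationship, the brute-force oracle for
# computeG (kept deliberately dumb and independent)
naiveG <- function(counts, theta) {
  n <- nrow(counts)
  p <- ncol(counts)
  G <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0
    for (j in seq_len(p))
      acc <- acc + (counts[i, j] - 2 * theta[j]) * (counts[k, j] - 2 * theta[j]) /
        (2 * theta[j] * (1 - theta[j]))
    G[i, k] <- acc / p
  }
  G
}

# dense multivariate-normal log density with explicit determinant/solve,
# the oracle for the eigendecomposition-based kernelLogLik
naiveMVNLogLik <- function(y, V, mu) {
  n <- length(y)
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus +
            drop(t(y - mu) %*% solve(V) %*% (y - mu)))
}

# fast reduced Gibbs settings for tests: the chain mixes well at these
# sample sizes, so short chains suffice
testGibbs <- function(seed = 1L, nIter = 4000L, burnIn = 1000L, thin = 3L)
  gibbsConfig(nIter = nIter, burnIn = burnIn, thin = thin, seed = seed)
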