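test_that("G matches hand substitution on the two-individual toy", {
  x <- matrix(c(2L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  G <- relValues(computeG(GenotypeData(x, theta = 0.5)))
  expect_equal(G["a", "a"], 2.0)
  expect_equal(G["a", "b"], -2.0)
  expect_equal(G["b", "b"], 2.0)
})

test_that("identical genotype rows give identical G entries", {
  x <- rbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 1L, 2L, 1L))
  colnames(x) <- paste0("s", 1:4)
  G <- relValues(computeG(GenotypeData(x, theta = c(0.2, 0.5, 0.7, 0.4))))
  expect_equal(G["a", "b"], G["a", "a"])
  expect_equal(G["a", "a"], G["b", "b"])
})

test_that("G equals the naive double-loop oracle", {
  g <- randomGenotypes(20, 500, seed = 21)
  G <- relValues(computeG(g))
  expect_equal(G, naiveG(genotypeCounts(g), alleleFreq(g)),
               tolerance = 1e-10)
})

test_that("G is invariant to allele-coding flips", {
  g <- randomGenotypes(15, 200, seed = 22)
  flipped <- GenotypeData(2L - genotypeCounts(g),
                          theta = 1 - alleleFreq(g))
  expect_equal(relValues(computeG(flipped)), relValues(computeG(g)),
               tolerance = 1e-12)
})

test_that("monomorphic or missing input is refused with guidance", {
  x <- matrix(c(0L, 0L, 1L, 2L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(computeG(GenotypeData(x)), "filterGenotypes")
  x2 <- x; x2[1, 1] <- NA
  expect_error(computeG(GenotypeData(x2, theta = c(0.3, 0.5))),
               "imputeMissing")
})

test_that("mean diagonal of G approaches 1 with in-sample frequencies", {
  g <- randomGenotypes(500, 5000, seed = 23)
  G <- relValues(computeG(g))
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  # and G is PSD for p >= n
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("QC removes exactly the constructed failures, with reasons", {
  set.seed(24)
  counts <- vapply(rep(0.4, 10), function(th) rbinom(5, 2L, th), integer(5))
  dimnames(counts) <- list(paste0("i", 1:5), paste0("s", 1:10))
  counts[, 1] <- 0L                      # MAF 0
  counts[, 2] <- 2L                      # MAF 0 (other allele fixed)
  counts[1, 3] <- NA                     # SNP 3 call rate 0.8 < 0.9
  counts[, 4:10][counts[, 4:10] == 0L] <- 1L  # keep remaining MAFs healthy
  filt <- filterGenotypes(GenotypeData(counts))
  expect_equal(ncol(genotypeCounts(filt)), 7L)
  excl <- filt@metadata$exclusions
  expect_setequal(excl$token, c("s1", "s2", "s3"))
  expect_equal(excl$reason[excl$token == "s3"], "call_rate")
  expect_true(all(excl$reason[excl$token %in% c("s1", "s2")] == "maf"))

  # identity case: fully observed, all MAF above threshold
  g <- randomGenotypes(10, 20, seed = 25)
  same <- filterGenotypes(g)
  expect_identical(genotypeCounts(same), genotypeCounts(g))
  expect_equal(nrow(same@metadata$exclusions), 0L)
})

test_that("individual filter precedes SNP recomputation", {
  # i1 is 85% called; three SNPs fail call rate only because of i1
  counts <- matrix(1L, 5, 20,
                   dimnames = list(paste0("i", 1:5), paste0("s", 1:20)))
  counts[cbind(c(2, 3), c(1, 2))] <- 0L   # a little MAF variation
  counts[1, 1:3] <- NA                    # i1 call rate 17/20 = 0.85
  filt <- filterGenotypes(GenotypeData(counts))
  expect_false("i1" %in% ids(filt))
  expect_equal(ncol(genotypeCounts(filt)), 20L)  # s1..s3 survive
  excl <- filt@metadata$exclusions
  expect_equal(excl$token[excl$type == "individual"], "i1")
  expect_error(filterGenotypes(GenotypeData(counts), minCallRate = 2),
               "minCallRate|is not TRUE")
})

test_that("imputation fills from Binomial(2, frozen theta)", {
  # degenerate theta: imputed entries forced to 0
  x <- matrix(c(0L, NA, 0L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  imp <- imputeMissing(GenotypeData(x, theta = c(0, 0.5)), seed = 1)
  expect_equal(genotypeCounts(imp)["b", "s1"], 0L)

  # no missing entries: identity, RNG untouched
  g <- randomGenotypes(5, 5, seed = 26)
  expect_identical(imputeMissing(g, seed = 1), g)
  expect_identical(imputeMissing(g, seed = 99), g)

  # binomial moments at theta = 0.3 over 1e5 imputed entries
  n <- 1000L
  x <- matrix(NA_integer_, n, 100,
              dimnames = list(sprintf("i%04d", 1:n), sprintf("s%03d", 1:100)))
  x[1, ] <- 1L  # keep one observation so theta stays defined
  g <- GenotypeData(x, theta = rep(0.3, 100))
  imp <- genotypeCounts(imputeMissing(g, seed = 27))[-1, ]
  expect_lt(abs(mean(imp) - 0.6), 3 * sqrt(2 * 0.3 * 0.7 / length(imp)))

  # fully-missing column is an error naming the SNP
  x2 <- matrix(c(1L, 1L, NA, NA), 2, 2,
               dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(imputeMissing(GenotypeData(x2, theta = c(0.5, 0.5))), "empty")
})

test_that("theta is frozen through the filter -> impute -> G pipeline", {
  g <- injectMissingness(randomGenotypes(60, 80, seed = 28), 0.05, seed = 29)
  filt <- filterGenotypes(g)
  imp <- imputeMissing(filt, seed = 30)
  expect_identical(alleleFreq(imp), alleleFreq(filt))
  # imputation changes realized counts, so re-estimation would differ
  reest <- GenotypeData(genotypeCounts(imp))
  expect_false(identical(alleleFreq(reest), alleleFreq(imp)))
})

test_that("G-vs-A comparison bins by exact pedigree level", {
  ped <- relationshipZoo()
  A <- buildA(ped)
  cmp <- compareGA(A, A)  # degenerate: G == A
  expect_s4_class(cmp, "GAComparison")
  expect_true(all(cmp@pairs$d == 0))
  expect_true(all(cmp@bins$varG == 0))
  gd <- geneDrop(ped, runif(400, 0.2, 0.5), seed = 31)
  G <- computeG(GenotypeData(genotypeCounts(gd),
                             theta = gd@metadata$founderTheta))
  cmp2 <- compareGA(G, A)
  offd <- cmp2@bins[!cmp2@bins$diagonal, ]
  expect_setequal(offd$A, c(0, 0.125, 0.25, 0.5))
  expect_equal(sum(cmp2@bins$n), 8 * 9 / 2)
  # id mismatch errors list the difference
  B <- new("RelationshipMatrix",
           values = relValues(A)[1:7, 1:7], kind = "pedigree_A")
  expect_error(compareGA(G, B), "id mismatch")
  p <- plotGA(cmp2)
  expect_s3_class(p, "ggplot")
})
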