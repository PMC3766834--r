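makePheno <- function(n = 400, seed = 41, beta = c(sex = -0.96, age = -0.032,
                                                   c2 = 0.28, c3 = 0.44),
                      noiseSD = 1) {
  set.seed(seed)
  d <- data.frame(id = sprintf("p%04d", seq_len(n)),
                  female = rbinom(n, 1, 0.5),
                  age = runif(n, 19, 92),
                  pc1 = rnorm(n), pc2 = rnorm(n),
                  cohort = sample(1:3, n, replace = TRUE))
  d$y <- 2 + beta["sex"] * d$female + beta["age"] * d$age +
    c(0, beta["c2"], beta["c3"])[d$cohort] + rnorm(n, 0, noiseSD)
  d
}

test_that("an exactly linear phenotype is interpolated to zero residuals", {
  d <- makePheno(n = 100, noiseSD = 0)
  fit <- suppressWarnings(fitFixedEffects(d, "y"))  # lm flags the perfect fit
  expect_lt(max(abs(residualPhenotype(fit))), 1e-10)
  est <- setNames(fit@coefficients$estimate, fit@coefficients$term)
  expect_equal(unname(est["female"]), -0.96, tolerance = 1e-10)
  expect_equal(unname(est["age"]), -0.032, tolerance = 1e-10)
  expect_equal(unname(est["factor(cohort)2"]), 0.28, tolerance = 1e-10)
})

test_that("intercept-only adjustment centers the phenotype", {
  d <- makePheno(n = 50)
  fit <- fitFixedEffects(d, "y", covariates = character(0))
  expect_equal(unname(residualPhenotype(fit)), d$y - mean(d$y),
               tolerance = 1e-12)
})

test_that("residuals are centered, orthogonal, and reconstruct y", {
  d <- makePheno()
  fit <- fitFixedEffects(d, "y")
  y <- residualPhenotype(fit)
  expect_lt(abs(mean(y)), 1e-10)
  for (v in c("female", "age", "pc1", "pc2"))
    expect_lt(abs(sum(y * d[[v]])), 1e-8 * nrow(d))
  expect_equal(unname(y) + fit@fitted, d$y, tolerance = 1e-10)
})

test_that("coefficients are recovered within 3 SEs on simulated data", {
  d <- makePheno(n = 2000, seed = 42)
  fit <- fitFixedEffects(d, "y")
  co <- fit@coefficients
  truth <- c("female" = -0.96, "age" = -0.032,
             "factor(cohort)2" = 0.28, "factor(cohort)3" = 0.44,
             "pc1" = 0, "pc2" = 0)
  for (term in names(truth)) {
    row <- co[co$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$se)
  }
})

test_that("fits are invariant to covariate order and cohort reference", {
  d <- makePheno(n = 300, seed = 43)
  f1 <- fitFixedEffects(d, "y", c("female", "age", "pc1", "pc2", "cohort"))
  f2 <- fitFixedEffects(d, "y", c("cohort", "pc2", "pc1", "age", "female"))
  est1 <- setNames(f1@coefficients$estimate, f1@coefficients$term)
  est2 <- setNames(f2@coefficients$estimate, f2@coefficients$term)
  expect_equal(est1[names(est2)], est2, tolerance = 1e-10)
  d2 <- d
  d2$cohort <- factor(d2$cohort, levels = c(3, 1, 2))
  f3 <- fitFixedEffects(d2, "y")
  expect_equal(residualPhenotype(f3), residualPhenotype(f1),
               tolerance = 1e-10)
})

test_that("degenerate designs are refused with a diagnosis", {
  d <- makePheno(n = 60)
  d$age2 <- d$age  # exact copy -> collinear
  expect_error(fitFixedEffects(d, "y", c("age", "age2")), "collinear")
  expect_error(fitFixedEffects(d[1:4, ], "y"), "fewer observations")
  d2 <- makePheno(n = 30)
  d2$pc1[5] <- NA
  expect_error(fitFixedEffects(d2, "y"), "missing covariate")
  d3 <- makePheno(n = 30)
  d3$y[c(3, 9)] <- NA
  expect_message(f <- fitFixedEffects(d3, "y"), "2 row")
  expect_equal(f@nUsed, 28L)
})

test_that("null-covariate p-values are uniform across replicates", {
  set.seed(44)
  pvals <- replicate(500, {
    d <- data.frame(id = as.character(1:100), female = rbinom(100, 1, 0.5),
                    age = runif(100, 19, 92), y = rnorm(100))
    fit <- fitFixedEffects(d, "y", c("female", "age"))
    fit@coefficients$p[fit@coefficients$term == "age"]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("latest-exam selection keeps the maximum exam per id", {
  d <- data.frame(id = c("a", "a", "b", "b", "b"), exam = c(1, 3, 2, 7, 5),
                  y = 1:5)
  out <- latestExam(d)
  expect_equal(nrow(out), 2L)
  expect_equal(out$y[out$id == "a"], 2L)
  expect_equal(out$y[out$id == "b"], 4L)
})

test_that("phenotype correlations behave on exact, null and spirometry data", {
  d <- data.frame(FEV1 = rnorm(100))
  d$FVC <- 2 * d$FEV1
  cc <- phenotypeCorrelations(d, c("FEV1", "FVC"))
  expect_equal(cc$r, 1.0)

  set.seed(45)
  dn <- data.frame(a = rnorm(1e4), b = rnorm(1e4))
  expect_lt(abs(phenotypeCorrelations(dn, c("a", "b"))$r), 0.05)

  # shared lung-size factor: volumes correlate highly, the ratio with
  # either volume only weakly
  sp <- simulateSpirometry(n = 4000, seed = 46)
  cs <- phenotypeCorrelations(sp, c("FEV1", "FVC", "ratio"))
  r <- function(a, b) cs$r[cs$trait1 == a & cs$trait2 == b]
  expect_gt(r("FEV1", "FVC"), 0.9)
  expect_lt(abs(r("FVC", "ratio")), 0.3)
  expect_lt(r("FEV1", "ratio"), r("FEV1", "FVC"))

  dz <- data.frame(a = rnorm(10), b = rep(1, 10))
  expect_warning(cz <- phenotypeCorrelations(dz, c("a", "b")),
                 "zero-variance")
  expect_true(is.na(cz$r))
})
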