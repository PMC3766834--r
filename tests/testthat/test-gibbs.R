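test_that("scaled-inverse-chi-square draws reproduce the prior mean", {
  set.seed(51)
  draws <- rScaledInvChisq(1e5, df = 5, scale = 2)
  # prior mean S/(nu - 2) = 2/3; MC SE from the sample itself
  expect_lt(abs(mean(draws) - 2 / 3), 3 * sd(draws) / sqrt(length(draws)))
  expect_true(all(draws > 0))
})

test_that("kernel log-likelihood matches a dense MVN oracle", {
  set.seed(52)
  ped <- randomPedigree(50, seed = 52)
  A <- buildA(ped)
  y <- rnorm(50)
  s2u <- 0.7; s2e <- 0.5; b0 <- 0.3
  dense <- naiveMVNLogLik(y, relValues(A) * s2u + diag(s2e, 50),
                          rep(b0, 50))
  expect_equal(kernelLogLik(y, A, b0, s2u, s2e), as.numeric(dense),
               tolerance = 1e-8)
  # s2u = 0 collapses to the iid normal log-density
  expect_equal(kernelLogLik(y, A, 0, 0, s2e),
               sum(dnorm(y, 0, sqrt(s2e), log = TRUE)), tolerance = 1e-10)
  # K = I gives iid normal with variance s2u + s2e
  I <- new("RelationshipMatrix",
           values = diag(1, 50, 50) |>
             (\(m) {dimnames(m) <- list(ids(A), ids(A)); m})(),
           kind = "pedigree_A")
  expect_equal(kernelLogLik(y, I, 0, s2u, s2e),
               sum(dnorm(y, 0, sqrt(s2u + s2e), log = TRUE)),
               tolerance = 1e-10)
})

test_that("profile-likelihood grid oracle handles degenerate geometry", {
  set.seed(53)
  n <- 60
  ids <- sprintf("i%02d", 1:n)
  I <- new("RelationshipMatrix",
           values = diag(1, n, n) |>
             (\(m) {dimnames(m) <- list(ids, ids); m})(),
           kind = "pedigree_A")
  y <- rnorm(n, 1, 2)
  # K = I: s2u and s2e indistinguishable, profile flat in h2
  out <- gridMLOracle(y, I, h2Grid = seq(0, 0.9, by = 0.1))
  expect_lt(max(out$profile$logLik) - min(out$profile$logLik), 1e-8)
  # closed form at h2 = 0: iid Gaussian with the MLE variance
  s2 <- mean((y - mean(y))^2)
  expect_equal(out$profile$logLik[1],
               -(n / 2) * log(2 * pi * s2) - n / 2, tolerance = 1e-8)
  expect_error(gridMLOracle(y, I, h2Grid = numeric(0)), "empty")
})

test_that("the ML grid puts a zero-heritability truth at the boundary", {
  ped <- simulatePedigree(simSpec(nFounders = 60, nGenerations = 3,
                                  offspringPerMating = 2, seed = 54))
  A <- buildA(ped)
  set.seed(55)
  y <- rnorm(nIndividuals(ped))      # no genetic signal at all
  out <- gridMLOracle(y, A, h2Grid = seq(0, 0.95, by = 0.05))
  expect_lte(out$h2, 0.1)
})

test_that("sampler posterior mass sits at the analytic posterior mode", {
  spec <- simSpec(nFounders = 50, nGenerations = 3, offspringPerMating = 2,
                  nSNPs = 600, trueH2 = 0.5, seed = 56)
  st <- simulateStudy(spec)
  A <- buildA(st$pedigree)
  adj <- fitFixedEffects(st$phenotypes, "y")
  fit <- suppressWarnings(fitModel(adj, A, config = testGibbs(seed = 57)))
  sm <- posteriorSamples(fit)
  grid <- gridPosteriorSurface(residualPhenotype(adj), A,
                               s2uGrid = seq(0.02, 2, length.out = 100),
                               s2eGrid = seq(0.02, 2, length.out = 100))
  # evaluate the analytic log-posterior at every sample; its argmax must
  # land within one grid cell of the grid MAP
  lp <- mapply(grid$at, sm$s2u, sm$s2e)
  best <- which.max(lp)
  du <- diff(seq(0.02, 2, length.out = 100))[1]
  expect_lt(abs(sm$s2u[best] - grid$map[["s2u"]]), du + 1e-9)
  expect_lt(abs(sm$s2e[best] - grid$map[["s2e"]]), du + 1e-9)
})

test_that("sampler and ML grid locate the same high-likelihood region", {
  for (seed in c(58, 59)) {
    spec <- simSpec(nFounders = 40, nGenerations = 3,
                    offspringPerMating = 2, nSNPs = 400, trueH2 = 0.6,
                    seed = seed)
    st <- simulateStudy(spec)
    A <- buildA(st$pedigree)
    adj <- fitFixedEffects(st$phenotypes, "y")
    fit <- suppressWarnings(fitModel(adj, A, config = testGibbs(seed = seed)))
    ml <- gridMLOracle(residualPhenotype(adj), A)
    expect_lt(abs(mean(posteriorSamples(fit)$h2) - ml$h2), 0.2)
  }
})

test_that("heritability is recovered and the null stays low", {
  spec <- simSpec(nFounders = 80, nGenerations = 3, offspringPerMating = 3,
                  nSNPs = 800, trueH2 = 0.5, seed = 60)
  st <- simulateStudy(spec)
  A <- buildA(st$pedigree)
  adj <- fitFixedEffects(st$phenotypes, "y")
  fit <- suppressWarnings(fitModel(adj, A, config = testGibbs(seed = 61)))
  h2 <- mean(posteriorSamples(fit)$h2)
  expect_lt(abs(h2 - 0.5), 0.2)

  spec0 <- simSpec(nFounders = 80, nGenerations = 3, offspringPerMating = 3,
                   nSNPs = 800, trueH2 = 0, seed = 60)
  st0 <- simulateStudy(spec0)
  adj0 <- fitFixedEffects(st0$phenotypes, "y")
  fit0 <- suppressWarnings(fitModel(adj0, buildA(st0$pedigree),
                                    config = testGibbs(seed = 61)))
  h20 <- mean(posteriorSamples(fit0)$h2)
  expect_lt(h20, h2)
  expect_lt(h20, 0.3)
})

test_that("posterior SD of h2 shrinks as the study grows", {
  sds <- vapply(c(30, 80, 220), function(nf) {
    reps <- vapply(1:2, function(r) {
      spec <- simSpec(nFounders = nf, nGenerations = 3,
                      offspringPerMating = 3, nSNPs = 500, trueH2 = 0.5,
                      seed = 70 + r)
      st <- simulateStudy(spec)
      adj <- fitFixedEffects(st$phenotypes, "y")
      fit <- suppressWarnings(fitModel(adj, buildA(st$pedigree),
                                       config = testGibbs(seed = 70 + r)))
      sd(posteriorSamples(fit)$h2)
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("deterministic pieces are invariant to individual permutation", {
  ped <- randomPedigree(40, seed = 62)
  A <- buildA(ped)
  set.seed(63)
  y <- setNames(rnorm(40), ids(ped))
  perm <- sample(ids(ped))
  Ap <- new("RelationshipMatrix", values = relValues(A)[perm, perm],
            kind = "pedigree_A")
  expect_equal(kernelLogLik(y, A, 0.1, 0.4, 0.6),
               kernelLogLik(y[perm], Ap, 0.1, 0.4, 0.6), tolerance = 1e-9)
  expect_equal(gridMLOracle(as.numeric(y), A)$h2,
               gridMLOracle(as.numeric(y[perm]), Ap)$h2)
})

test_that("fitModel validates inputs and reports diagnostics", {
  ped <- randomPedigree(40, seed = 64)
  A <- buildA(ped)
  y <- setNames(rnorm(40), ids(ped))
  y[3] <- NA
  expect_error(fitModel(y, A, config = testGibbs()), "NaN/NA")
  y2 <- setNames(rnorm(5), c(ids(ped)[1:4], "stranger"))
  expect_error(fitModel(y2, A, config = testGibbs()), "absent from the kernel")
  y3 <- setNames(rnorm(20), ids(ped)[1:20])
  expect_warning(fit <- fitModel(y3, A, config = testGibbs(seed = 65)),
                 "small sample")
  expect_s4_class(fit, "PosteriorSummary")
  expect_true(all(c("beta0", "s2u", "s2e", "h2") %in% names(fit@ess)))
  h <- heritability(fit)
  expect_true(h$h2Mean > 0 && h$h2Mean < 1)
  expect_equal(h$h2Pct, 100 * h$h2Mean)
})
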