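#' @rdname PriorSpec-class
#' @param scale scale parameter S (> 0), default 2
#' @param df degrees of freedom nu (> 0), default 5
#' @return a [PriorSpec-class]
#' @export
priorSpec <- function(scale = 2, df = 5)
  new("PriorSpec", scale = scale, df = df)

#' @rdname GibbsConfig-class
#' @param nIter,burnIn,thin chain length controls
#' @param seed chain RNG seed
#' @param initH2 initial heritability for the variance starting values
#' @return a [GibbsConfig-class]
#' @export
gibbsConfig <- function(nIter = 30000L, burnIn = 5000L, thin = 5L,
                        seed = 1L, initH2 = 0.5)
  new("GibbsConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed), initH2 = initH2)

#' Draw from a scaled inverse chi-square distribution
#'
#' Density proportional to (s2)^-(df/2 + 1) * exp(-scale/(2 s2)); equals
#' scale / chisq(df). Mean scale/(df - 2) for df > 2. This is both the
#' prior for the variance components and the form of their Gibbs full
#' conditionals (with data-augmented df and scale).
#'
#' @param n number of draws
#' @param df degrees of freedom
#' @param scale scale parameter
#' @return numeric vector of positive draws
#' @export
rScaledInvChisq <- function(n, df, scale) scale / stats::rchisq(n, df)

# effective sample size from the initial positive sequence of autocorrelations
essOf <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(as.numeric(n))
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  max(1, n / (1 + 2 * sum(rho)))
}

# shared eigen-rotation of (y, 1) used by the sampler, the likelihood and
# the grid oracles
rotateKernel <- function(y, K) {
  Kv <- relValues(K)
  n <- length(y)
  stopifnot(nrow(Kv) == n)
  eg <- eigen(Kv, symmetric = TRUE)
  D <- eg$values
  if (min(D) < -1e-6 * max(abs(D)))
    stop(sprintf("kernel is not PSD (min eigenvalue %.3g); ensurePSD() first",
                 min(D)))
  D <- pmax(D, 0)
  list(U = eg$vectors, D = D, z = drop(crossprod(eg$vectors, y)),
       o = drop(crossprod(eg$vectors, rep(1, n))),
       keep = D > 1e-10 * max(D))
}

#' Gaussian marginal log-likelihood of the kernel model
#'
#' Log density of y under N(1*beta0, K*s2u + I*s2e), computed through the
#' eigendecomposition of K (one decomposition, O(n) per evaluation).
#'
#' @param y numeric outcome vector (typically covariate-adjusted residuals)
#' @param K a [RelationshipMatrix-class] aligned with y
#' @param beta0 intercept
#' @param s2u genetic variance (>= 0)
#' @param s2e residual variance (> 0)
#' @param rot optional precomputed rotation from an earlier call (internal
#'   reuse across traits)
#' @return the log-likelihood (a single number)
#' @export
kernelLogLik <- function(y, K, beta0, s2u, s2e, rot = NULL) {
  stopifnot(s2u >= 0, s2e > 0)
  if (is.null(rot)) rot <- rotateKernel(y, K)
  lam <- rot$D * s2u + s2e
  if (any(lam <= 0)) stop("singular covariance")
  r <- rot$z - rot$o * beta0
  -0.5 * (length(y) * log(2 * pi) + sum(log(lam)) + sum(r^2 / lam))
}

#' Fit the additive genetic model by Gibbs sampling
#'
#' Fits y = 1*beta0 + u + e with u ~ N(0, K*s2u), e ~ N(0, I*s2e) and
#' scaled-inverse-chi-square priors on both variances (flat prior on
#' beta0). The kernel is eigendecomposed once (K = U D U'); the chain
#' updates, in rotated coordinates, (1) beta0 from its Gaussian full
#' conditional, (2) each rotated genetic effect u*_m independently from a
#' Gaussian with variance (1/(D_m s2u) + 1/s2e)^-1 (modes with eigenvalue
#' below 1e-10 of the maximum are pinned at 0), (3) s2u from
#' scaled-inv-chisq(df + rank, scale + sum(u*_m^2 / D_m)), and (4) s2e from
#' scaled-inv-chisq(df + n, scale + RSS). Thinned post-burn-in draws of
#' (beta0, s2u, s2e, h2 = s2u/(s2u+s2e)) are stored; u-hat is the
#' posterior mean of the genetic values rotated back; the reported
#' log-likelihood is the Gaussian marginal likelihood at the posterior-mean
#' parameters.
#'
#' @param y an [AdjustedPhenotype-class] or a named numeric vector
#' @param K a [RelationshipMatrix-class]; must cover the ids of y
#' @param prior a [priorSpec()]
#' @param config a [gibbsConfig()]
#' @return a [PosteriorSummary-class]
#' @export
fitModel <- function(y, K, prior = priorSpec(), config = gibbsConfig()) {
  stopifnot(is(K, "RelationshipMatrix"), is(prior, "PriorSpec"),
            is(config, "GibbsConfig"))
  if (is(y, "AdjustedPhenotype")) {
    yv <- y@y
    names(yv) <- y@id
  } else yv <- y
  if (anyNA(yv)) stop("NaN/NA in y")
  if (!is.null(names(yv))) {
    missing <- setdiff(names(yv), ids(K))
    if (length(missing))
      stop("individual(s) in y absent from the kernel: ",
           paste(utils::head(missing, 5), collapse = ", "))
    if (!identical(names(yv), ids(K))) {
      Kv <- relValues(K)[names(yv), names(yv)]
      K <- new("RelationshipMatrix", values = Kv, kind = K@kind)
    }
  }
  n <- length(yv)
  notes <- character()
  if (n < 30) notes <- c(notes, sprintf("small sample (n = %d)", n))
  K <- ensurePSD(K)
  if (isTRUE(attr(K, "jittered")))
    notes <- c(notes, "kernel jittered by 1e-8 on the diagonal")
  rot <- rotateKernel(yv, K)
  keep <- rot$keep
  r <- sum(keep)
  S <- prior@scale
  nu <- prior@df
  set.seed(config@seed)
  vy <- stats::var(yv)
  s2u <- max(config@initH2 * vy, 1e-6)
  s2e <- max((1 - config@initH2) * vy, 1e-6)
  beta0 <- mean(yv)
  ustar <- rep(0, n)
  nStore <- (config@nIter - config@burnIn) %/% config@thin
  s.iter <- integer(nStore); s.beta0 <- numeric(nStore)
  s.s2u <- numeric(nStore); s.s2e <- numeric(nStore)
  uhatSum <- rep(0, n)
  stored <- 0L
  oo <- sum(rot$o^2)  # equals n (rotation preserves norms)
  for (it in seq_len(config@nIter)) {
    # (1) intercept
    beta0 <- stats::rnorm(1, sum(rot$o * (rot$z - ustar)) / oo,
                          sqrt(s2e / oo))
    # (2) rotated genetic effects
    resid0 <- rot$z - rot$o * beta0
    v <- 1 / (1 / (rot$D[keep] * s2u) + 1 / s2e)
    ustar[keep] <- stats::rnorm(r, v * resid0[keep] / s2e, sqrt(v))
    # (3) genetic variance
    ssu <- sum(ustar[keep]^2 / rot$D[keep])
    s2u <- (S + ssu) / stats::rchisq(1, nu + r)
    # (4) residual variance
    rss <- sum((resid0 - ustar)^2)
    s2e <- (S + rss) / stats::rchisq(1, nu + n)
    if (it > config@burnIn && (it - config@burnIn) %% config@thin == 0L) {
      stored <- stored + 1L
      s.iter[stored] <- it; s.beta0[stored] <- beta0
      s.s2u[stored] <- s2u; s.s2e[stored] <- s2e
      uhatSum <- uhatSum + ustar
    }
  }
  samples <- data.frame(iter = s.iter, beta0 = s.beta0, s2u = s.s2u,
                        s2e = s.s2e, h2 = s.s2u / (s.s2u + s.s2e))
  uhat <- drop(rot$U %*% (uhatSum / stored))
  ess <- vapply(samples[c("beta0", "s2u", "s2e", "h2")], essOf, numeric(1))
  if (ess[["h2"]] < 100)
    notes <- c(notes, sprintf("low effective sample size for h2 (%.0f)",
                              ess[["h2"]]))
  ll <- kernelLogLik(yv, K, mean(samples$beta0), mean(samples$s2u),
                     mean(samples$s2e), rot = rot)
  out <- new("PosteriorSummary", samples = samples,
             uhat = as.numeric(uhat),
             ids = if (is.null(names(yv))) ids(K) else names(yv),
             logLik = ll, ess = ess, kernelKind = K@kind, notes = notes)
  for (msg in notes) warning(msg, call. = FALSE)
  out
}

#' Profile maximum likelihood over a heritability grid
#'
#' Independent frequentist check of the sampler: for each h2 on the grid
#' the covariance is written sigma2 * (h2 K + (1 - h2) I); beta0 and the
#' total variance sigma2 are profiled analytically through the shared
#' eigendecomposition, giving the profile log-likelihood in h2 and the ML
#' variance components at its maximum.
#'
#' @param y numeric outcome vector
#' @param K a [RelationshipMatrix-class]
#' @param h2Grid grid of heritabilities in [0, 1)
#' @return list: h2, s2u, s2e, logLik at the maximum, plus the full
#'   \code{profile} data.frame (h2, sigma2, logLik)
#' @export
gridMLOracle <- function(y, K, h2Grid = seq(0, 0.99, by = 0.005)) {
  if (!length(h2Grid)) stop("empty h2 grid")
  rot <- rotateKernel(y, K)
  n <- length(y)
  prof <- vapply(h2Grid, function(h2) {
    w <- h2 * rot$D + (1 - h2)          # relative eigenvalues
    if (any(w <= 0)) return(c(NA_real_, -Inf))
    b0 <- sum(rot$o * rot$z / w) / sum(rot$o^2 / w)
    q <- sum((rot$z - rot$o * b0)^2 / w)
    sigma2 <- q / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + sum(log(w)) + n)
    c(sigma2, ll)
  }, numeric(2))
  profile <- data.frame(h2 = h2Grid, sigma2 = prof[1L, ], logLik = prof[2L, ])
  best <- which.max(profile$logLik)
  list(h2 = profile$h2[best],
       s2u = profile$h2[best] * profile$sigma2[best],
       s2e = (1 - profile$h2[best]) * profile$sigma2[best],
       logLik = profile$logLik[best], profile = profile)
}

#' Marginal log-posterior surface of the variance components
#'
#' Brute-force oracle for the sampler: evaluates, on a grid over
#' (s2u, s2e), the log marginal posterior with the genetic values
#' integrated out and beta0 integrated under its flat prior,
#' \deqn{\log p(\sigma^2_u, \sigma^2_e \mid y) =
#'  -\tfrac12 \sum_m \log \lambda_m - \tfrac12 \log \sum_m o_m^2/\lambda_m
#'  - \tfrac12 \sum_m (z_m - o_m \hat\beta_0)^2/\lambda_m
#'  + \log p(\sigma^2_u) + \log p(\sigma^2_e) + const}
#' with lambda = D s2u + s2e in the eigenbasis of K. The Gibbs chain
#' targets exactly this density, so its high-probability region must match
#' the grid maximum.
#'
#' @param y numeric outcome vector
#' @param K a [RelationshipMatrix-class]
#' @param prior a [priorSpec()]
#' @param s2uGrid,s2eGrid grids of positive variance values
#' @return list: \code{map} (s2u, s2e at the grid maximum), \code{logPost}
#'   matrix (rows = s2uGrid, cols = s2eGrid), and an \code{at(s2u, s2e)}
#'   function evaluating the same density anywhere
#' @export
gridPosteriorSurface <- function(y, K, prior = priorSpec(),
                                 s2uGrid, s2eGrid) {
  stopifnot(all(s2uGrid > 0), all(s2eGrid > 0))
  rot <- rotateKernel(y, K)
  S <- prior@scale; nu <- prior@df
  logPrior <- function(s2) -(nu / 2 + 1) * log(s2) - S / (2 * s2)
  at <- function(s2u, s2e) {
    lam <- rot$D * s2u + s2e
    b0 <- sum(rot$o * rot$z / lam) / sum(rot$o^2 / lam)
    -0.5 * sum(log(lam)) - 0.5 * log(sum(rot$o^2 / lam)) -
      0.5 * sum((rot$z - rot$o * b0)^2 / lam) +
      logPrior(s2u) + logPrior(s2e)
  }
  lp <- outer(seq_along(s2uGrid), seq_along(s2eGrid),
              Vectorize(function(i, j) at(s2uGrid[i], s2eGrid[j])))
  dimnames(lp) <- list(signif(s2uGrid, 6), signif(s2eGrid, 6))
  best <- arrayInd(which.max(lp), dim(lp))
  list(map = c(s2u = s2uGrid[best[1L]], s2e = s2eGrid[best[2L]]),
       logPost = lp, at = at)
}

#' Compare predicted genetic values under the two kernels
#'
#' Per-individual predicted values combine the stage-1 fixed-effect fitted
#' value with the posterior-mean genetic value u-hat under each kernel. The
#' report gives the Pearson correlation of the two totals and decomposes it
#' (the fixed part is shared, so the genetic parts drive any disagreement).
#'
#' @param fitA,fitG [PosteriorSummary-class] objects over the same
#'   individuals (pedigree and genomic kernels)
#' @param covariateFit the stage-1 [AdjustedPhenotype-class]
#' @return list: \code{table} (id, fixed, uA, uG, predA, predG),
#'   \code{correlation} (of the totals), \code{geneticCorrelation}
#'   (of uA vs uG), and variance shares of the fixed and genetic parts
#' @export
comparePredictedValues <- function(fitA, fitG, covariateFit) {
  stopifnot(is(fitA, "PosteriorSummary"), is(fitG, "PosteriorSummary"),
            is(covariateFit, "AdjustedPhenotype"))
  if (!setequal(fitA@ids, fitG@ids))
    stop("id mismatch between fits: ",
         paste(utils::head(c(setdiff(fitA@ids, fitG@ids),
                             setdiff(fitG@ids, fitA@ids)), 5),
               collapse = ", "))
  idx <- covariateFit@id
  stopifnot(all(idx %in% fitA@ids))
  uA <- geneticValues(fitA)[idx]
  uG <- geneticValues(fitG)[idx]
  fixed <- stats::setNames(covariateFit@fitted, covariateFit@id)[idx]
  tab <- data.frame(id = idx, fixed = fixed, uA = uA, uG = uG,
                    predA = fixed + uA, predG = fixed + uG,
                    row.names = NULL)
  list(table = tab,
       correlation = stats::cor(tab$predA, tab$predG),
       geneticCorrelation = stats::cor(tab$uA, tab$uG),
       varFixed = stats::var(fixed),
       varGeneticA = stats::var(uA), varGeneticG = stats::var(uG))
}

#' Scatter of pedigree- vs SNP-based predicted values
#'
#' @param cmp output of [comparePredictedValues()]
#' @return a ggplot object
#' @export
plotPredictedValues <- function(cmp) {
  tab <- cmp$table
  ggplot2::ggplot(tab, ggplot2::aes(x = predA, y = predG)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::labs(x = "Pedigree-based predicted value",
                  y = "SNP-based predicted value",
                  subtitle = sprintf("r = %.3f", cmp$correlation)) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("predA", "predG"))
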