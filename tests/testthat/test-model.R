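# Brute-force reference implementation of the model's log joint density:
# plain loops and stats::d* densities, coded independently of the package's
# vectorized version.
bruteLogJoint <- function(p, d, y, spec = horseshoeSpec(),
                          extended = FALSE) {
  P <- ncol(d$X); C <- length(d$conditions); N <- nrow(d$X)
  lp <- 0
  for (k in seq_len(N)) {
    mu <- 0
    for (q in seq_len(P)) mu <- mu + p$B[d$cond[k], q] * d$X[k, q]
    mu <- mu + p$I[d$subj[k]]
    if (extended) mu <- mu + p$b[d$subj[k]] * d$X[k, "rt"]
    lp <- lp + stats::dt((y[k] - mu) / p$sigma_g, df = p$nu, log = TRUE) -
      log(p$sigma_g)
  }
  for (i in seq_len(C)) for (q in seq_len(P)) {
    l2 <- p$c2 * p$lambda[i, q]^2 / (p$c2 + p$tau^2 * p$lambda[i, q]^2)
    lp <- lp + stats::dnorm(p$B[i, q], 0, p$tau * sqrt(l2), log = TRUE)
    lp <- lp + log(2) + stats::dcauchy(p$lambda[i, q], 0, 1, log = TRUE)
  }
  for (j in seq_along(p$I))
    lp <- lp + stats::dnorm(p$I[j], p$I0, p$sigma_I, log = TRUE)
  lp <- lp + stats::dnorm(p$I0, 0, 1, log = TRUE)
  lp <- lp + log(2) + stats::dnorm(p$sigma_I, 0, 1, log = TRUE)
  lp <- lp + log(2) + stats::dnorm(p$sigma_g, 0, 1, log = TRUE)
  lp <- lp + stats::dgamma(p$nu, 2, rate = 1 / 10, log = TRUE)
  tau0 <- spec$p0 / (P * C - spec$p0) * p$sigma_g / sqrt(N)
  lp <- lp + log(2) + stats::dcauchy(p$tau, 0, tau0, log = TRUE)
  a <- spec$nu0 / 2; bb <- spec$nu0 * spec$s^2 / 2
  lp <- lp + a * log(bb) - lgamma(a) - (a + 1) * log(p$c2) - bb / p$c2
  if (extended) {
    l2b <- p$c2 * p$lambda_b^2 / (p$c2 + p$tau^2 * p$lambda_b^2)
    for (j in seq_along(p$b))
      lp <- lp + stats::dnorm(p$b[j], 0, p$tau * sqrt(l2b), log = TRUE)
    lp <- lp + log(2) + stats::dcauchy(p$lambda_b, 0, 1, log = TRUE)
  }
  unname(lp)
}

randomPoint <- function(C, P, J, extended = FALSE) {
  p <- list(B = matrix(rnorm(C * P, 0, 0.3), C, P,
                       dimnames = list(NULL, designColnames())),
            I0 = rnorm(1, 0, 0.5), I = rnorm(J, 0, 0.5),
            sigma_g = runif(1, 0.5, 1.5), sigma_I = runif(1, 0.2, 0.8),
            nu = runif(1, 3, 50), tau = runif(1, 0.01, 0.5),
            lambda = matrix(rexp(C * P) + 0.05, C, P), c2 = runif(1, 0.5, 3))
  if (extended) { p$b <- rnorm(J, 0, 0.1); p$lambda_b <- rexp(1) + 0.1 }
  p
}

smallDesign <- function(seed = 111) {
  co <- smallCohort(per_group = 1L, n_blocks = 2L, seed = seed)
  amps <- simulateTrialAmplitudes(co$trials, co$traits, co$truth,
                                  seed = seed)
  amps <- do.call(rbind, lapply(split(amps, amps$subject), utils::head, 10))
  buildDesignMatrix(amps, co$traits)
}

test_that("log joint density matches an independent brute-force oracle", {
  d <- smallDesign()
  expect_equal(length(d$subjects), 3L)
  expect_equal(nrow(d$X), 30L)
  set.seed(222)
  for (rep in 1:5) {
    p <- randomPoint(3, 11, 3)
    expect_equal(logJointDensity(p, d), bruteLogJoint(p, d, d$y),
                 tolerance = 1e-8)
  }
  ## extended variant too
  for (rep in 1:2) {
    p <- randomPoint(3, 11, 3, extended = TRUE)
    expect_equal(logJointDensity(p, d, extended = TRUE),
                 bruteLogJoint(p, d, d$y, extended = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("log joint is -Inf out of support and uses the t likelihood", {
  d <- smallDesign(113)
  set.seed(7)
  p <- randomPoint(3, 11, 3)
  p$sigma_g <- -1
  expect_identical(logJointDensity(p, d), -Inf)
  p$sigma_g <- 1
  p$tau <- 0
  expect_identical(logJointDensity(p, d), -Inf)
  ## likelihood term: difference in the log joint between two outcome
  ## vectors equals the difference in Student-t log densities
  p <- randomPoint(3, 11, 3)
  p$B[] <- 0; p$I[] <- 0; p$I0 <- 0; p$sigma_g <- 1; p$nu <- 1000
  y0 <- rep(0, nrow(d$X)); y1 <- y0; y1[1] <- 1.3
  diff <- logJointDensity(p, d, y = y1) - logJointDensity(p, d, y = y0)
  expect_equal(diff, stats::dt(1.3, 1000, log = TRUE) -
                 stats::dt(0, 1000, log = TRUE), tolerance = 1e-10)
})

test_that("the regularized scale approaches the slab as lambda grows", {
  lt2 <- trialERP:::lambdaTilde2
  expect_equal(0.1^2 * lt2(1e9, 0.1, 2.5), 2.5, tolerance = 1e-6)
  ## and approaches tau^2 lambda^2 for small lambda
  expect_lt(abs(0.1^2 * lt2(1e-4, 0.1, 2.5) - 1e-10), 1e-20)
})

test_that("sampling is deterministic given the seed", {
  d <- smallDesign(115)
  f1 <- fitHorseshoe(d, chains = 2, warmup = 50, samples = 30, seed = 77)
  f2 <- fitHorseshoe(d, chains = 2, warmup = 50, samples = 30, seed = 77)
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
  f3 <- fitHorseshoe(d, chains = 2, warmup = 50, samples = 30, seed = 78)
  expect_false(identical(posteriorDraws(f1)$B, posteriorDraws(f3)$B))
})

test_that("posterior draws respect positivity and finiteness invariants", {
  d <- smallDesign(117)
  fit <- fitHorseshoe(d, chains = 2, warmup = 100, samples = 60, seed = 5,
                      extended = TRUE)
  dr <- posteriorDraws(fit)
  for (nm in c("sigma_g", "sigma_I", "nu", "tau", "c2"))
    expect_true(all(dr[[nm]] > 0))
  expect_true(all(vapply(dr, function(x) all(is.finite(x)), logical(1))))
  expect_true(validObject(fit))
})

test_that("split-Rhat and ESS diagnostics react to constructed pathologies", {
  d <- smallDesign(119)
  fit <- fitHorseshoe(d, chains = 4, warmup = 50, samples = 250, seed = 2)
  ## iid chains: overwrite draws with white noise -> Rhat near 1
  fit@draws$sigma_g <- matrix(abs(rnorm(250 * 4)) + 1, 250, 4)
  dg <- diagnoseAndSummarize(fit)
  expect_lt(dg$summary$rhat[dg$summary$parameter == "sigma_g"], 1.01)
  ## one chain offset by +10 -> Rhat far above the 1.05 criterion
  fit@draws$sigma_g[, 2] <- fit@draws$sigma_g[, 2] + 10
  dg2 <- diagnoseAndSummarize(fit)
  expect_gt(dg2$summary$rhat[dg2$summary$parameter == "sigma_g"], 1.5)
  expect_false(dg2$rhat_ok)
  ## symmetric draws: median near 0, interval symmetric
  set.seed(1)
  fit@draws$I0 <- matrix(rnorm(250 * 4), 250, 4)
  dg3 <- diagnoseAndSummarize(fit)
  row <- dg3$summary[dg3$summary$parameter == "I0", ]
  expect_lt(abs(row$median), 0.1)
  expect_lt(abs(row$q2.5 + row$q97.5), 0.2)
})

test_that("posterior agrees with an independent MCMC backend (rjags)", {
  library(rjags)
  ## small, strong-signal dataset so both samplers pin the RT coefficients
  co <- smallCohort(per_group = 4L, n_blocks = 3L, seed = 131)
  B <- matrix(0, 3, 11, dimnames = list(c("gain", "loss", "control"),
                                        designColnames()))
  B[, "rt"] <- c(-0.5, -0.4, -0.3)
  truth <- groundTruth(12, B = B, slope_sd = 0, sigma_I = 0.3,
                       sigma_g = 0.6, nu = 30, seed = 131)
  co <- smallCohort(per_group = 4L, n_blocks = 3L, seed = 131, truth = truth)
  amps <- simulateTrialAmplitudes(co$trials, co$traits, co$truth, seed = 132)
  d <- buildDesignMatrix(amps, co$traits)
  fit <- fitHorseshoe(d, chains = 2, warmup = 800, samples = 500, seed = 3)
  ours <- coefMedians(fit)[, "rt"]

  sel <- lapply(1:3, function(i) which(d$cond == i))
  mod <- "
  model {
    eta1 <- X1 %*% B[1,]; eta2 <- X2 %*% B[2,]; eta3 <- X3 %*% B[3,]
    for (k in 1:n1) { y1[k] ~ dt(eta1[k] + I[s1[k]], prec_g, nu) }
    for (k in 1:n2) { y2[k] ~ dt(eta2[k] + I[s2[k]], prec_g, nu) }
    for (k in 1:n3) { y3[k] ~ dt(eta3[k] + I[s3[k]], prec_g, nu) }
    for (i in 1:3) { for (p in 1:11) {
      lam[i,p] ~ dt(0, 1, 1) T(0,)
      lt2[i,p] <- c2*lam[i,p]^2 / (c2 + tau^2*lam[i,p]^2)
      B[i,p] ~ dnorm(0, 1/(lt2[i,p]*tau^2))
    }}
    for (j in 1:J) { I[j] ~ dnorm(I0, 1/sigma_I^2) }
    I0 ~ dnorm(0, 1)
    sigma_I ~ dnorm(0, 1) T(0,)
    sigma_g ~ dnorm(0, 1) T(0,)
    prec_g <- 1/sigma_g^2
    nu ~ dgamma(2, 0.1)
    tau0 <- 9/(11*3 - 9) * sigma_g / sqrt(N)
    tau ~ dt(0, 1/tau0^2, 1) T(0,)
    ic2 ~ dgamma(10, 10)
    c2 <- 1/ic2
  }"
  dat <- list(y1 = d$y[sel[[1]]], y2 = d$y[sel[[2]]], y3 = d$y[sel[[3]]],
              X1 = d$X[sel[[1]], ], X2 = d$X[sel[[2]], ],
              X3 = d$X[sel[[3]], ],
              s1 = d$subj[sel[[1]]], s2 = d$subj[sel[[2]]],
              s3 = d$subj[sel[[3]]],
              n1 = length(sel[[1]]), n2 = length(sel[[2]]),
              n3 = length(sel[[3]]), J = length(d$subjects),
              N = nrow(d$X))
  ## start at a dispersed but unshrunk point so the Gibbs chain does not
  ## begin deep in the shrinkage funnel
  inits <- list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 42,
                tau = 0.2, lam = matrix(1, 3, 11), sigma_g = sd(d$y),
                sigma_I = 0.3, I0 = 0, nu = 20)
  jm <- rjags::jags.model(textConnection(mod), data = dat, n.chains = 1,
                          n.adapt = 500, quiet = TRUE, inits = inits)
  update(jm, 1500, progress.bar = "none")
  sm <- rjags::coda.samples(jm, "B", n.iter = 1500, progress.bar = "none")
  theirs <- summary(sm)$quantiles[c("B[1,1]", "B[2,1]", "B[3,1]"), "50%"]
  expect_lt(max(abs(ours - theirs)), 0.08)
})
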