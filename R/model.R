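#' Regularized-horseshoe prior specification
#'
#' Hyper-parameters of the hierarchical model's priors: the expected number
#' of non-zero coefficients `p0 = 9`, the slab degrees of freedom
#' `nu0 = 20` and scale `s = 1` (so non-zero coefficients follow roughly a
#' Student-t with 20 df and unit scale), a Gamma(2, rate 0.1) prior on the
#' residual degrees of freedom, half-normal(0,1) priors on the residual and
#' intercept scales and a normal(0,1) prior on the grand intercept.
#'
#' @param p0 expected non-zero coefficients (must be below `P * C`).
#' @param nu0 slab prior degrees of freedom.
#' @param s slab prior scale.
#' @param nu_shape,nu_rate Gamma prior on the Student-t degrees of freedom.
#' @return list of class `horseshoeSpec`.
#' @export
horseshoeSpec <- function(p0 = 9, nu0 = 20, s = 1,
                          nu_shape = 2, nu_rate = 0.1) {
  stopifnot(p0 > 0, nu0 > 0, s > 0)
  structure(list(p0 = p0, nu0 = nu0, s = s,
                 nu_shape = nu_shape, nu_rate = nu_rate),
            class = "horseshoeSpec")
}

## regularized local scale^2
lambdaTilde2 <- function(lambda, tau, c2) {
  c2 * lambda^2 / (c2 + tau^2 * lambda^2)
}

#' Log joint density of the hierarchical model
#'
#' Evaluates the (collapsed) log joint density of the horseshoe hierarchical
#' Student-t regression at a parameter point: the Student-t log likelihood
#' with location `B_i' x_k + I_j` (plus `b_j rt_k` in the extended variant)
#' and scale `sigma_g`, Gaussian priors on each coefficient with SD
#' `lambda_tilde * tau`, and the stated hyper-priors.  Out-of-support
#' parameter points (non-positive scales) return `-Inf` by contract.
#'
#' @param params named list: `B` (C x P), `I0`, `I` (per subject),
#'   `sigma_g`, `sigma_I`, `nu`, `tau`, `lambda` (C x P), `c2`, and for the
#'   extended variant `b` (per subject) and `lambda_b`.
#' @param design an `erpDesign` from [buildDesignMatrix()].
#' @param y outcome vector (defaults to `design$y`).
#' @param spec a [horseshoeSpec()].
#' @param extended include the per-subject RT-slope block.
#' @return log density (finite, or `-Inf` out of support).
#' @export
logJointDensity <- function(params, design, y = design$y,
                            spec = horseshoeSpec(), extended = FALSE) {
  p <- params
  scales <- c(p$sigma_g, p$sigma_I, p$nu, p$tau, p$c2, as.vector(p$lambda))
  if (extended) scales <- c(scales, p$lambda_b)
  if (any(!is.finite(scales)) || any(scales <= 0)) return(-Inf)

  X <- design$X
  N <- nrow(X); P <- ncol(X); C <- length(design$conditions)
  mu <- rowSums(X * p$B[design$cond, , drop = FALSE]) + p$I[design$subj]
  if (extended) mu <- mu + p$b[design$subj] * design$rt_z

  ll <- sum(stats::dt((y - mu) / p$sigma_g, df = p$nu, log = TRUE) -
              log(p$sigma_g))

  v <- p$tau^2 * lambdaTilde2(p$lambda, p$tau, p$c2)
  lp <- sum(stats::dnorm(p$B, 0, sqrt(v), log = TRUE))
  lp <- lp + sum(stats::dnorm(p$I, p$I0, p$sigma_I, log = TRUE))
  lp <- lp + stats::dnorm(p$I0, 0, 1, log = TRUE)
  lp <- lp + stats::dnorm(p$sigma_I, 0, 1, log = TRUE) + log(2)
  lp <- lp + stats::dnorm(p$sigma_g, 0, 1, log = TRUE) + log(2)
  lp <- lp + stats::dgamma(p$nu, spec$nu_shape, rate = spec$nu_rate, log = TRUE)
  lp <- lp + sum(stats::dcauchy(p$lambda, 0, 1, log = TRUE) + log(2))
  tau0 <- computeTau0(spec$p0, P, C, p$sigma_g, N)
  lp <- lp + stats::dcauchy(p$tau, 0, tau0, log = TRUE) + log(2)
  a <- spec$nu0 / 2; bb <- spec$nu0 * spec$s^2 / 2    # inverse-gamma on c2
  lp <- lp + a * log(bb) - lgamma(a) - (a + 1) * log(p$c2) - bb / p$c2
  if (extended) {
    vb <- p$tau^2 * lambdaTilde2(p$lambda_b, p$tau, p$c2)
    lp <- lp + sum(stats::dnorm(p$b, 0, sqrt(vb), log = TRUE))
    lp <- lp + stats::dcauchy(p$lambda_b, 0, 1, log = TRUE) + log(2)
  }
  unname(ll + lp)
}

#' Fit the hierarchical model by blocked Gibbs sampling
#'
#' Samples the posterior of the regularized-horseshoe hierarchical Student-t
#' regression.  The Student-t likelihood is augmented as a normal scale
#' mixture, so the coefficient blocks, subject intercepts and (in the
#' extended variant) subject RT slopes have conjugate Gaussian full
#' conditionals; the scale-type parameters are updated by univariate slice
#' sampling.  Chains run sequentially with over-dispersed initial values;
#' all randomness goes through R's RNG so results are reproducible given
#' `seed`.
#'
#' The extended variant adds mean-zero per-subject RT slopes with a
#' horseshoe-type prior (one shared local scale for the slope block).
#'
#' @param design an `erpDesign` from [buildDesignMatrix()].
#' @param y outcome vector (defaults to `design$y`).
#' @param spec a [horseshoeSpec()].
#' @param extended fit the random-RT-slope variant.
#' @param chains,warmup,samples,thin sampler settings; the defaults
#'   (4 chains, 1000 + 500) are desk-scale settings.
#' @param fullSettings use the full-scale sampler settings instead
#'   (8 chains with 8000 warmup + 1000 sampling iterations).
#' @param seed integer seed.
#' @return a [PosteriorFit-class].
#' @export
fitHorseshoe <- function(design, y = design$y, spec = horseshoeSpec(),
                         extended = FALSE, chains = 4L, warmup = 1000L,
                         samples = 500L, thin = 1L, fullSettings = FALSE,
                         seed = 1L) {
  if (fullSettings) { chains <- 8L; warmup <- 8000L; samples <- 1000L }
  X <- design$X
  N <- nrow(X); P <- ncol(X)
  C <- length(design$conditions); J <- length(design$subjects)
  if (length(y) != N) stop("y and design are not conformable")
  if (spec$p0 >= P * C) stop("p0 must be below P*C")

  draw_names <- c("B", "I", "I0", "sigma_g", "sigma_I", "nu", "tau", "c2",
                  "lambda", if (extended) c("b", "lambda_b"))
  out <- list()
  sdy <- stats::sd(y)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + 7919L * ch)
    init <- list(
      B = matrix(stats::rnorm(C * P, 0, 0.02), C, P),
      I = stats::rnorm(J, 0, 0.1 * sdy),
      b = numeric(J),
      I0 = stats::rnorm(1, 0, 0.1),
      sigma_g = sdy * stats::runif(1, 0.7, 1.1),
      sigma_I = sdy * stats::runif(1, 0.2, 0.6),
      nu = stats::runif(1, 5, 40),
      tau = computeTau0(spec$p0, P, C, sdy, N) * stats::runif(1, 0.5, 5),
      c2 = spec$s^2 * stats::runif(1, 0.5, 2),
      lam = matrix(stats::rexp(C * P, 1), C, P),
      lam_b = 1
    )
    res <- hs_gibbs_chain(y, X, as.integer(design$cond),
                          as.integer(design$subj), design$rt_z,
                          extended, C, P, J,
                          as.integer(warmup), as.integer(samples),
                          as.integer(thin),
                          spec$p0, spec$nu0, spec$s, init)
    out[[ch]] <- res
  }

  ## stack chains: iterations x chains (x ...)
  stack <- function(nm) {
    d1 <- out[[1]][[nm]]
    if (is.matrix(d1) && ncol(d1) > 1 || length(dim(d1)) == 3) {
      dd <- dim(d1)
      if (length(dd) == 2) {           # iterations x J
        arr <- array(NA_real_, c(dd[1], chains, dd[2]))
        for (ch in seq_len(chains)) arr[, ch, ] <- out[[ch]][[nm]]
        arr
      } else {                          # iterations x C x P
        arr <- array(NA_real_, c(dd[1], chains, dd[2], dd[3]))
        for (ch in seq_len(chains)) arr[, ch, , ] <- out[[ch]][[nm]]
        arr
      }
    } else {
      sapply(out, function(o) as.vector(o[[nm]]))
    }
  }
  draws <- stats::setNames(lapply(draw_names, stack), draw_names)

  new("PosteriorFit", draws = draws, chains = as.integer(chains),
      warmup = as.integer(warmup), samples = as.integer(samples),
      extended = extended,
      meta = list(predictors = colnames(X), conditions = design$conditions,
                  subjects = design$subjects, spec = spec,
                  seed = as.integer(seed)))
}

## split-Rhat for a single parameter: draws as iterations x chains
splitRhat <- function(mat) {
  n <- nrow(mat) %/% 2L
  if (n < 2L || ncol(mat) < 1L) return(NA_real_)
  halves <- cbind(mat[seq_len(n), , drop = FALSE],
                  mat[(nrow(mat) - n + 1):nrow(mat), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize a posterior fit with convergence diagnostics
#'
#' Per-parameter posterior medians, central 50% and 95% credible intervals,
#' split-Rhat and effective-sample-size ratios, plus overall pass/fail flags
#' at the Rhat < 1.05 and ESS ratio > 0.1 criteria.
#'
#' @param fit a [PosteriorFit-class] with at least 2 chains.
#' @param includeSubjects include per-subject intercepts (and slopes) rows.
#' @return list: `summary` (data.frame with one row per parameter),
#'   `rhat_ok`, `ess_ok`, `max_rhat`, `min_ess_ratio`.
#' @export
diagnoseAndSummarize <- function(fit, includeSubjects = FALSE) {
  if (fit@chains < 2L)
    warning("single chain: split-Rhat is not defined across chains")
  dr <- fit@draws
  conds <- fit@meta$conditions
  preds <- fit@meta$predictors

  mats <- list()
  for (i in seq_along(conds)) for (p in seq_along(preds))
    mats[[sprintf("B[%s,%s]", conds[i], preds[p])]] <- dr$B[, , i, p]
  for (nm in c("I0", "sigma_g", "sigma_I", "nu", "tau", "c2"))
    mats[[nm]] <- dr[[nm]]
  if (includeSubjects) {
    for (j in seq_along(fit@meta$subjects))
      mats[[sprintf("I[%s]", fit@meta$subjects[j])]] <- dr$I[, , j]
    if (fit@extended)
      for (j in seq_along(fit@meta$subjects))
        mats[[sprintf("b[%s]", fit@meta$subjects[j])]] <- dr$b[, , j]
  }

  n_total <- fit@samples * fit@chains
  rows <- lapply(names(mats), function(nm) {
    m <- matrix(mats[[nm]], nrow = fit@samples)
    v <- as.vector(m)
    q <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    ess <- tryCatch(
      sum(vapply(seq_len(ncol(m)), function(ch)
        as.numeric(coda::effectiveSize(coda::mcmc(m[, ch]))), numeric(1))),
      error = function(e) NA_real_)
    data.frame(parameter = nm, median = q[3], q2.5 = q[1], q25 = q[2],
               q75 = q[4], q97.5 = q[5],
               rhat = splitRhat(m), ess_ratio = ess / n_total,
               stringsAsFactors = FALSE)
  })
  s <- do.call(rbind, rows)
  list(summary = s,
       rhat_ok = all(is.na(s$rhat) | s$rhat < 1.05),
       ess_ok = all(is.na(s$ess_ratio) | s$ess_ratio > 0.1),
       max_rhat = suppressWarnings(max(s$rhat, na.rm = TRUE)),
       min_ess_ratio = suppressWarnings(min(s$ess_ratio, na.rm = TRUE)))
}

#' Posterior medians of the coefficient matrix
#'
#' @param fit a [PosteriorFit-class].
#' @return condition x predictor matrix of posterior medians.
#' @export
coefMedians <- function(fit) {
  conds <- fit@meta$conditions; preds <- fit@meta$predictors
  M <- matrix(NA_real_, length(conds), length(preds),
              dimnames = list(conds, preds))
  for (i in seq_along(conds)) for (p in seq_along(preds))
    M[i, p] <- stats::median(fit@draws$B[, , i, p])
  M
}

#' Central credible intervals of the coefficient matrix
#'
#' @param fit a [PosteriorFit-class].
#' @param level interval mass (default 0.95).
#' @return list of two condition x predictor matrices, `lower` and `upper`.
#' @export
coefIntervals <- function(fit, level = 0.95) {
  conds <- fit@meta$conditions; preds <- fit@meta$predictors
  a <- (1 - level) / 2
  lo <- hi <- matrix(NA_real_, length(conds), length(preds),
                     dimnames = list(conds, preds))
  for (i in seq_along(conds)) for (p in seq_along(preds)) {
    q <- stats::quantile(fit@draws$B[, , i, p], c(a, 1 - a), names = FALSE)
    lo[i, p] <- q[1]; hi[i, p] <- q[2]
  }
  list(lower = lo, upper = hi)
}
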