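#' Derive per-subject behavioral outcomes
#'
#' Four outcomes per subject: the initial log-odds correct-rejection rate,
#' the change in log-odds correct rejection, the change in mean response
#' time, and the intrinsic-motivation effort/enjoyment score.  "Initial" and
#' "change" are defined on bins of three successive blocks: initial = the
#' first bin, change = last bin minus first bin.  Correct-rejection counts
#' receive a continuity correction of 0.5 before the log-odds transform.
#'
#' @param trials the cohort trial table.
#' @param traits trait table carrying `imi_effort` (subjects with a missing
#'   score get `NA` outcomes and are dropped by the regression).
#' @param bin_blocks blocks per bin (default 3).
#' @return data.frame: `subject`, `condition`, `init_logodds_cr`,
#'   `change_logodds_cr`, `change_rt_s`, `imi_effort`.
#' @export
deriveOutcomes <- function(trials, traits, bin_blocks = 3L) {
  logodds <- function(k, n) log((k + 0.5) / (n - k + 0.5))
  subjects <- sort(unique(trials$subject))
  n_blocks <- max(trials$block)
  first_bin <- seq_len(bin_blocks)
  last_bin <- (n_blocks - bin_blocks + 1L):n_blocks

  rows <- lapply(subjects, function(s) {
    tr <- trials[trials$subject == s, , drop = FALSE]
    stat_of <- function(blocks) {
      tb <- tr[tr$block %in% blocks, , drop = FALSE]
      nogo <- tb[tb$type == "nogo", , drop = FALSE]
      hits <- tb[tb$type == "go" & tb$responded & tb$correct, , drop = FALSE]
      c(lo_cr = logodds(sum(!nogo$responded), nrow(nogo)),
        rt = mean(hits$rt_s))
    }
    a <- stat_of(first_bin); b <- stat_of(last_bin)
    data.frame(subject = s, condition = tr$condition[1],
               init_logodds_cr = a[["lo_cr"]],
               change_logodds_cr = b[["lo_cr"]] - a[["lo_cr"]],
               change_rt_s = b[["rt"]] - a[["rt"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ti <- match(out$subject, traits$subject)
  out$imi_effort <- if ("imi_effort" %in% names(traits))
    traits$imi_effort[ti] else NA_real_
  out
}

#' Predictor matrix for the behavioral regression
#'
#' Standardized promotion and prevention scores, gain and loss condition
#' indicators, and their four interactions (8 columns, all standardized).
#'
#' @param outcomes data.frame with `subject` and `condition`.
#' @param traits trait table with `promotion`, `prevention`.
#' @return matrix with 8 named columns, rows aligned with `outcomes`.
#' @export
behaviorPredictors <- function(outcomes, traits) {
  ti <- match(outcomes$subject, traits$subject)
  z <- function(x) (x - mean(x)) / stats::sd(x)
  prom <- traits$promotion[ti]; prev <- traits$prevention[ti]
  gain <- as.numeric(outcomes$condition == "gain")
  loss <- as.numeric(outcomes$condition == "loss")
  X <- cbind(prom = prom, prev = prev, gain = gain, loss = loss,
             "prom:gain" = prom * gain, "prom:loss" = prom * loss,
             "prev:gain" = prev * gain, "prev:loss" = prev * loss)
  apply(X, 2, z)
}

#' Fit the rank-constrained Bayesian multivariate regression
#'
#' Models the subject x outcome matrix as `(X A) W' + E` with a latent rank
#' `r` (default 1), Gaussian noise with per-outcome variances, standard
#' normal priors on the projection coefficients `A` and outcome loadings
#' `W`, and the prevention coefficient of the first latent dimension
#' constrained positive for identifiability (the likelihood is invariant to
#' a joint sign flip of `a` and `w`; the constraint selects one mode).
#' Sampling is by Gibbs: `A` and `W` columns have conjugate Gaussian full
#' conditionals; the noise scales are slice-sampled under half-normal
#' priors.
#'
#' @param outcomes data.frame from [deriveOutcomes()]; rows with missing
#'   values are dropped.
#' @param predictors matrix from [behaviorPredictors()].
#' @param rank number of latent dimensions.
#' @param chains,warmup,samples sampler settings.
#' @param seed integer seed.
#' @return list of class `rrrFit`: `A` (draws x K x rank), `W` (draws x
#'   M x rank), `sigma` (draws x M), `loglik` (draws x subjects, pointwise),
#'   `outcome_names`, `predictor_names`, `scaling`, `n`.
#' @export
fitReducedRank <- function(outcomes, predictors, rank = 1L, chains = 2L,
                           warmup = 500L, samples = 500L, seed = 1L) {
  ocols <- c("init_logodds_cr", "change_logodds_cr", "change_rt_s",
             "imi_effort")
  Y <- as.matrix(outcomes[, ocols])
  ok <- stats::complete.cases(Y) & stats::complete.cases(predictors)
  Y <- Y[ok, , drop = FALSE]
  X <- predictors[ok, , drop = FALSE]
  n <- nrow(Y); K <- ncol(X); M <- ncol(Y)
  if (n <= K) warning("fewer subjects than predictors: weakly identified fit")
  Ys <- scale(Y)                      # standardized outcomes
  prev_idx <- match("prev", colnames(X))

  XtX <- crossprod(X)
  n_save <- samples * chains
  A_dr <- array(NA_real_, c(n_save, K, rank))
  W_dr <- array(NA_real_, c(n_save, M, rank))
  sig_dr <- matrix(NA_real_, n_save, M)
  ll_dr <- matrix(NA_real_, n_save, n)

  s <- 0L
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + 104729L * ch)
    A <- matrix(stats::rnorm(K * rank, 0, 0.3), K, rank)
    W <- matrix(stats::rnorm(M * rank, 0, 0.3), M, rank)
    sig <- rep(1, M)
    for (it in seq_len(warmup + samples)) {
      for (r in seq_len(rank)) {
        ## residual excluding latent dimension r
        Er <- Ys - X %*% A[, -r, drop = FALSE] %*% t(W[, -r, drop = FALSE])
        ## A column r | W: conjugate MVN
        wsum <- sum(W[, r]^2 / sig^2)
        prec <- XtX * wsum + diag(K)
        rhs <- crossprod(X, Er %*% (W[, r] / sig^2))
        U <- chol(prec)
        mn <- backsolve(U, forwardsolve(t(U), rhs))
        A[, r] <- mn + backsolve(U, stats::rnorm(K))
        ## W column r | A: per-outcome scalar normals
        z <- as.vector(X %*% A[, r])
        zz <- sum(z^2)
        for (m in seq_len(M)) {
          prec_w <- zz / sig[m]^2 + 1
          mn_w <- sum(z * Er[, m]) / sig[m]^2 / prec_w
          W[m, r] <- stats::rnorm(1, mn_w, 1 / sqrt(prec_w))
        }
      }
      ## identifiability: prevention coefficient of dimension 1 positive
      if (A[prev_idx, 1] < 0) { A[, 1] <- -A[, 1]; W[, 1] <- -W[, 1] }
      ## noise scales (half-normal(0,1) prior, slice)
      Mu <- X %*% A %*% t(W)
      for (m in seq_len(M)) {
        ss <- sum((Ys[, m] - Mu[, m])^2)
        sig[m] <- sliceScalar(sig[m], function(sg) {
          if (sg <= 0) return(-Inf)
          -n * log(sg) - ss / (2 * sg^2) - sg^2 / 2
        }, w = 0.2, lower = 1e-8, upper = 20)
      }
      if (it > warmup) {
        s <- s + 1L
        A_dr[s, , ] <- A; W_dr[s, , ] <- W; sig_dr[s, ] <- sig
        ll_dr[s, ] <- rowSums(vapply(seq_len(M), function(m)
          stats::dnorm(Ys[, m], Mu[, m], sig[m], log = TRUE),
          numeric(n)))
      }
    }
  }
  dimnames(A_dr) <- list(NULL, colnames(X), NULL)
  dimnames(W_dr) <- list(NULL, ocols, NULL)
  structure(list(A = A_dr, W = W_dr, sigma = sig_dr, loglik = ll_dr,
                 outcome_names = ocols, predictor_names = colnames(X),
                 rank = rank, n = n,
                 scaling = list(center = attr(Ys, "scaled:center"),
                                scale = attr(Ys, "scaled:scale"))),
            class = "rrrFit")
}

## univariate stepping-out slice sampler (R-side)
sliceScalar <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                        max_steps = 50L) {
  logy <- logf(x0) - stats::rexp(1)
  u <- stats::runif(1, 0, w)
  L <- max(lower, x0 - u); R <- min(upper, x0 - u + w)
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > logy) { L <- max(lower, L - w); k <- k - 1 }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > logy) { R <- min(upper, R + w); k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

## generalized Pareto fit to positive tail excesses (profile-posterior
## method of Zhang & Stephens 2009)
gpdFit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0) return(list(k = Inf, sigma = NA_real_))
  m <- 30 + floor(sqrt(n))
  xq <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * xq)
  bs <- bs[bs > 0 & bs < 1 / x[n]]
  if (!length(bs)) return(list(k = Inf, sigma = NA_real_))
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- n * (log(bs / ks) + ks - 1)
  wts <- exp(L - max(L)); wts <- wts / sum(wts)
  b_hat <- sum(bs * wts)
  k_hat <- -mean(log1p(-b_hat * x))
  list(k = k_hat, sigma = k_hat / b_hat)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Computes the expected log pointwise predictive density under
#' leave-one-out cross-validation from a pointwise log-likelihood matrix,
#' smoothing the largest importance ratios per observation with a fitted
#' generalized Pareto tail.
#'
#' @param loglik draws x observations matrix of pointwise log likelihoods.
#' @return list: `elpd` (total), `pointwise` (per observation), `k_hat`
#'   (per-observation Pareto shape diagnostics), `warn` (TRUE when any
#'   `k_hat > 0.7`, indicating unstable importance weights).
#' @export
psisLoo <- function(loglik) {
  S <- nrow(loglik); n <- ncol(loglik)
  pointwise <- numeric(n); k_hat <- numeric(n)
  for (i in seq_len(n)) {
    lw <- -loglik[, i]
    lw <- lw - max(lw)
    ## smooth the top-M importance weights with a generalized Pareto tail
    M <- min(ceiling(0.2 * S), S - 1L)
    ord <- order(lw, decreasing = TRUE)
    tail_idx <- ord[seq_len(M)]
    cutoff <- exp(lw[ord[M + 1L]])
    o <- order(lw[tail_idx])                       # ascending within tail
    excess <- exp(lw[tail_idx][o]) - cutoff
    fit <- gpdFit(excess)
    k_hat[i] <- fit$k
    if (is.finite(fit$k) && fit$k < 1 && is.finite(fit$sigma) &&
        fit$sigma > 0 && abs(fit$k) > 1e-12) {
      p <- (seq_len(M) - 0.5) / M
      q <- cutoff + fit$sigma / fit$k * ((1 - p)^(-fit$k) - 1)
      lw[tail_idx[o]] <- log(q)
    }
    lw <- pmin(lw, 0)                              # never exceed the raw max
    lw <- lw - logSumExp(lw)
    pointwise[i] <- logSumExp(lw + loglik[, i])
  }
  list(elpd = sum(pointwise), pointwise = pointwise, k_hat = k_hat,
       warn = any(is.finite(k_hat) & k_hat > 0.7))
}

logSumExp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Compare latent ranks by cross-validated predictive density
#'
#' Compares two fitted ranks on identical data by PSIS-LOO expected log
#' predictive density; the lower rank is preferred unless the higher rank
#' improves the elpd by more than `se_mult` standard errors of the
#' pointwise difference.
#'
#' @param fit1,fit2 `rrrFit` objects on identical data (rank of `fit2`
#'   higher).
#' @param se_mult preference margin in SE units (default 2).
#' @return list: `preferred` rank, `elpd_diff` (fit2 - fit1), `se_diff`,
#'   `flagged` (unstable importance weights in either fit).
#' @export
compareRanks <- function(fit1, fit2, se_mult = 2) {
  l1 <- psisLoo(fit1$loglik); l2 <- psisLoo(fit2$loglik)
  d <- l2$pointwise - l1$pointwise
  elpd_diff <- sum(d)
  se_diff <- stats::sd(d) * sqrt(length(d))
  preferred <- if (elpd_diff > se_mult * se_diff) fit2$rank else fit1$rank
  list(preferred = preferred, elpd_diff = elpd_diff, se_diff = se_diff,
       elpd = c(rank1 = l1$elpd, rank2 = l2$elpd),
       flagged = l1$warn || l2$warn)
}

#' Posterior summary of the behavioral regression
#'
#' @param fit an `rrrFit`.
#' @param level credible-interval mass.
#' @return data.frame with one row per projection coefficient and loading:
#'   `parameter`, `median`, `lo`, `hi`.
#' @export
summarizeReducedRank <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  rows <- list()
  for (r in seq_len(fit$rank)) {
    for (k in seq_along(fit$predictor_names)) {
      v <- fit$A[, k, r]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = sprintf("a[%s,%d]", fit$predictor_names[k], r),
        median = stats::median(v),
        lo = unname(stats::quantile(v, a)),
        hi = unname(stats::quantile(v, 1 - a)))
    }
    for (m in seq_along(fit$outcome_names)) {
      v <- fit$W[, m, r]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = sprintf("w[%s,%d]", fit$outcome_names[m], r),
        median = stats::median(v),
        lo = unname(stats::quantile(v, a)),
        hi = unname(stats::quantile(v, 1 - a)))
    }
  }
  do.call(rbind, rows)
}
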