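# Shared fixtures, built in code at test time.

smallCohort <- function(per_group = 6L, n_blocks = 5L, seed = 101L,
                        truth = NULL) {
  cfg <- simConfig(group_sizes = c(gain = per_group, loss = per_group,
                                   control = per_group),
                   n_blocks = n_blocks, seed = seed)
  simulateCohort(cfg, truth = truth)
}

# trial table for a single subject with hand-set fields
handTrials <- function(subject = "S001", condition = "gain",
                       onset_s, rt_s, type = "go", block = 1L,
                       responded = TRUE, correct = TRUE) {
  n <- length(onset_s)
  data.frame(subject = subject, condition = condition,
             block = rep_len(block, n), trial = seq_len(n),
             type = rep_len(type, n), onset_s = onset_s,
             rt_s = rep_len(rt_s, n), responded = rep_len(responded, n),
             correct = rep_len(correct, n), stringsAsFactors = FALSE)
}

# a PosteriorFit whose draws all equal a fixed parameter point; used to
# exercise deterministic transforms (reliability formulas) with known truth
constantFit <- function(B, I, b, sigma_g, conditions, subjects,
                        n_iter = 8L, chains = 2L) {
  C <- nrow(B); P <- ncol(B); J <- length(I)
  arr4 <- function(m) {
    a <- array(NA_real_, c(n_iter, chains, dim(m)))
    for (it in seq_len(n_iter)) for (ch in seq_len(chains)) a[it, ch, , ] <- m
    a
  }
  arr3 <- function(v) {
    a <- array(NA_real_, c(n_iter, chains, length(v)))
    for (it in seq_len(n_iter)) for (ch in seq_len(chains)) a[it, ch, ] <- v
    a
  }
  sc <- function(x) matrix(x, n_iter, chains)
  draws <- list(B = arr4(B), I = arr3(I), I0 = sc(0),
                sigma_g = sc(sigma_g), sigma_I = sc(0.5), nu = sc(30),
                tau = sc(0.1), c2 = sc(1), lambda = arr4(matrix(1, C, P)),
                b = arr3(b), lambda_b = sc(1))
  new("PosteriorFit", draws = draws, chains = as.integer(chains),
      warmup = 0L, samples = as.integer(n_iter), extended = TRUE,
      meta = list(predictors = colnames(B), conditions = conditions,
                  subjects = subjects, spec = horseshoeSpec(), seed = 0L))
}

# analytic evoked matrix matching the raw-EEG generator's stimulus template
analyticEvoked <- function(params, span_s = c(0, 1.5)) {
  rate <- params$rate_hz
  chans <- params$channels
  nch <- length(chans)
  ev_topo <- stats::setNames(rep(-0.6, nch), chans)
  ev_topo[names(ev_topo) %in% c("Cz", "C3", "C4")] <- 0.8
  if (nch > 1) ev_topo <- ev_topo - mean(ev_topo)
  tmpl <- trialERP:::evokedTemplate(rate)
  n_span <- round((span_s[2] - span_s[1]) * rate)
  ev <- ev_topo %o% c(tmpl, numeric(max(0, n_span - length(tmpl))))[1:n_span]
  rownames(ev) <- chans
  attr(ev, "span_s") <- span_s
  ev
}

# analytic mean of a normal truncated to (lo, hi)
truncNormMean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}
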