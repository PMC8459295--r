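#' Simulation configuration for a go/no-go ERP cohort
#'
#' Bundles the study-design constants of the simulated cohort: three feedback
#' framing conditions (gain, loss, control), 20 blocks of 30 trials
#' (24 go / 6 no-go) per subject, per-condition response-time and trait
#' distributions, and per-condition miss and false-alarm rates.  Defaults
#' reproduce the cohort structure of the motivating study: group sizes
#' 26/35/30, hit RT means 0.40/0.43/0.46 s, and RFQ promotion/prevention
#' trait means and SDs per condition.
#'
#' Response times are drawn from a normal distribution truncated to
#' `(rt_min_s, rt_max_s]` (the task's 1-s response deadline).  Trait scores
#' are truncated to the RFQ 1-5 scale.
#'
#' @param group_sizes named integer vector, subjects per condition
#'   (gain, loss, control).
#' @param n_blocks,go_per_block,nogo_per_block task structure counts.
#' @param rt_mean_s,rt_sd_s per-condition hit response-time mean/SD (s).
#' @param fa_rt_mean_s,fa_rt_sd_s per-condition false-alarm RT mean/SD (s).
#' @param rt_min_s,rt_max_s truncation bounds for response times (s).
#' @param miss_rate,false_alarm_rate per-condition error probabilities.
#' @param trait_means,trait_sds lists with elements `promotion` and
#'   `prevention`, each a 3-vector of per-condition values (RFQ units).
#' @param imi_mean,imi_sd intrinsic-motivation effort/enjoyment score
#'   distribution (1-7 scale).
#' @param seed integer seed stored with the configuration.
#' @return A validated list of class `simConfig`.
#' @export
simConfig <- function(group_sizes = c(gain = 26L, loss = 35L, control = 30L),
                      n_blocks = 20L, go_per_block = 24L, nogo_per_block = 6L,
                      rt_mean_s = c(gain = 0.40, loss = 0.43, control = 0.46),
                      rt_sd_s = c(gain = 0.07, loss = 0.05, control = 0.06),
                      fa_rt_mean_s = c(gain = 0.35, loss = 0.36, control = 0.40),
                      fa_rt_sd_s = c(gain = 0.07, loss = 0.05, control = 0.06),
                      rt_min_s = 0.1, rt_max_s = 1.0,
                      miss_rate = c(gain = 0.047, loss = 0.022, control = 0.025),
                      false_alarm_rate = c(gain = 0.28, loss = 0.26, control = 0.27),
                      trait_means = list(promotion = c(4.0, 3.8, 3.8),
                                         prevention = c(3.3, 3.5, 3.2)),
                      trait_sds = list(promotion = c(0.6, 0.5, 0.6),
                                       prevention = c(0.9, 0.9, 0.8)),
                      imi_mean = 5.0, imi_sd = 1.0,
                      seed = 1L) {
  cfg <- list(group_sizes = group_sizes, n_blocks = as.integer(n_blocks),
              go_per_block = as.integer(go_per_block),
              nogo_per_block = as.integer(nogo_per_block),
              rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
              fa_rt_mean_s = fa_rt_mean_s, fa_rt_sd_s = fa_rt_sd_s,
              rt_min_s = rt_min_s, rt_max_s = rt_max_s,
              miss_rate = miss_rate, false_alarm_rate = false_alarm_rate,
              trait_means = trait_means, trait_sds = trait_sds,
              imi_mean = imi_mean, imi_sd = imi_sd,
              seed = as.integer(seed))
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (length(cfg$group_sizes) != 3L || any(cfg$group_sizes < 1L))
    stop("group_sizes must give a positive count for each of 3 conditions")
  rates <- c(cfg$miss_rate, cfg$false_alarm_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("miss_rate and false_alarm_rate must lie in [0, 1]")
  if (cfg$go_per_block < 1L || cfg$nogo_per_block < 0L)
    stop("trial counts per block must be positive")
  if (cfg$rt_min_s >= cfg$rt_max_s)
    stop("rt_min_s must be below rt_max_s")
  for (tr in c("promotion", "prevention")) {
    if (length(cfg$trait_means[[tr]]) != 3L || length(cfg$trait_sds[[tr]]) != 3L)
      stop("trait_means and trait_sds need one value per condition")
  }
  invisible(cfg)
}

condLevels <- function() c("gain", "loss", "control")

## truncated-normal sampler via inverse CDF
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Ground-truth parameters for the trial-amplitude generator
#'
#' Builds the coefficient matrix and subject-level random effects that the
#' amplitude generator treats as truth.  The default coefficient matrix
#' places the reported condition-wise RT effects (-0.15, -0.17, -0.08 for
#' gain/loss/control) in the RT column and the reported interaction effects
#' (gain RT x Prom -0.05, loss RT x Prom -0.01, loss RT x ErrN 0.02, and the
#' three-way RT x Prom x ErrN terms 0.01 / 0.08 / -0.01) in their columns;
#' all other coefficients are zero.  Units are standardized (coefficients of
#' z-scored predictors on the z-scored amplitude).
#'
#' @param n_subjects number of subjects (for the random intercepts/slopes).
#' @param B optional condition x 11 coefficient matrix overriding the default.
#' @param I0 grand intercept (standardized units).
#' @param sigma_I SD of subject random intercepts.
#' @param slope_sd SD of subject random RT slopes (0 = no random slopes).
#' @param sigma_g residual scale of the Student-t noise.
#' @param nu Student-t degrees of freedom of the residuals.
#' @param seed integer seed for drawing the random effects.
#' @return A list of class `groundTruth` with elements `B`, `I0`, `I`, `b`,
#'   `sigma_g`, `nu`, `sigma_I`.
#' @export
groundTruth <- function(n_subjects, B = NULL, I0 = 0, sigma_I = 0.45,
                        slope_sd = 0.05, sigma_g = 0.85, nu = 8, seed = 1L) {
  if (is.null(B)) {
    B <- matrix(0, 3, 11, dimnames = list(condLevels(), designColnames()))
    B[, "rt"] <- c(-0.15, -0.17, -0.08)
    B["gain", "rt:prom"] <- -0.05
    B["loss", "rt:prom"] <- -0.01
    B["loss", "rt:errn"] <- 0.02
    B[, "rt:prom:errn"] <- c(0.01, 0.08, -0.01)
  }
  stopifnot(ncol(B) == 11L, sigma_g > 0, nu > 0, sigma_I >= 0)
  set.seed(seed)
  I <- stats::rnorm(n_subjects, I0, sigma_I)
  b <- if (slope_sd > 0) stats::rnorm(n_subjects, 0, slope_sd) else numeric(n_subjects)
  structure(list(B = B, I0 = I0, I = I, b = b, sigma_g = sigma_g,
                 nu = nu, sigma_I = sigma_I),
            class = "groundTruth")
}

#' Simulate a go/no-go cohort: trials and traits
#'
#' Generates the behavioral side of a cohort: a trial table (subject,
#' condition, block, trial type, onset, response time, correctness) and a
#' participant trait table (RFQ promotion/prevention scores, miss counts,
#' IMI effort/enjoyment score).  Go trials are hits (with a truncated-normal
#' RT) or misses (no response); no-go trials are correct rejections or false
#' alarms (with a faster RT distribution).  Trial onsets follow the task
#' timeline (1-s response window, 0.5-s feedback, 1-2-s inter-stimulus
#' interval), so the tables can drive the raw-EEG generator directly.
#'
#' @param config a [simConfig()] list.
#' @param truth optional [groundTruth()]; built with defaults when `NULL`.
#' @return list with elements `trials` (data.frame), `traits` (data.frame),
#'   `truth` (the ground-truth list).
#' @examples
#' cohort <- simulateCohort(simConfig(seed = 42))
#' table(cohort$trials$type) / sum(cohort$config$group_sizes)
#' @export
simulateCohort <- function(config = simConfig(), truth = NULL) {
  validateSimConfig(config)
  set.seed(config$seed)
  conds <- condLevels()
  n_subj <- sum(config$group_sizes)
  subj_cond <- rep(conds, times = config$group_sizes)

  if (is.null(truth))
    truth <- groundTruth(n_subjects = n_subj, seed = config$seed)
  if (length(truth$I) != n_subj)
    stop("ground truth was built for a different number of subjects")

  ## traits (truncated to the 1-5 RFQ scale)
  ci <- match(subj_cond, conds)
  traits <- data.frame(
    subject = sprintf("S%03d", seq_len(n_subj)),
    condition = subj_cond,
    promotion = rtrunc_norm(n_subj, config$trait_means$promotion[ci],
                            config$trait_sds$promotion[ci], 1, 5),
    prevention = rtrunc_norm(n_subj, config$trait_means$prevention[ci],
                             config$trait_sds$prevention[ci], 1, 5),
    imi_effort = rtrunc_norm(n_subj, config$imi_mean, config$imi_sd, 1, 7),
    stringsAsFactors = FALSE
  )

  per_block <- config$go_per_block + config$nogo_per_block
  n_trials <- config$n_blocks * per_block

  trial_list <- vector("list", n_subj)
  for (j in seq_len(n_subj)) {
    cond <- subj_cond[j]
    type <- unlist(lapply(seq_len(config$n_blocks), function(bl)
      sample(c(rep("go", config$go_per_block),
               rep("nogo", config$nogo_per_block)))))
    block <- rep(seq_len(config$n_blocks), each = per_block)
    is_go <- type == "go"

    responded <- logical(n_trials)
    responded[is_go] <- stats::runif(sum(is_go)) >= config$miss_rate[[cond]]
    responded[!is_go] <- stats::runif(sum(!is_go)) < config$false_alarm_rate[[cond]]
    correct <- ifelse(is_go, responded, !responded)

    rt <- rep(NA_real_, n_trials)
    n_hit <- sum(is_go & responded)
    n_fa <- sum(!is_go & responded)
    rt[is_go & responded] <- rtrunc_norm(n_hit, config$rt_mean_s[[cond]],
                                         config$rt_sd_s[[cond]],
                                         config$rt_min_s, config$rt_max_s)
    rt[!is_go & responded] <- rtrunc_norm(n_fa, config$fa_rt_mean_s[[cond]],
                                          config$fa_rt_sd_s[[cond]],
                                          config$rt_min_s, config$rt_max_s)

    ## onsets: 1 s response window + 0.5 s feedback + U(1,2) s fixation
    gaps <- 1.0 + 0.5 + stats::runif(n_trials, 1, 2)
    onset <- 1.0 + cumsum(c(0, gaps[-n_trials]))

    trial_list[[j]] <- data.frame(
      subject = traits$subject[j], condition = cond, block = block,
      trial = seq_len(n_trials), type = type, onset_s = onset,
      rt_s = rt, responded = responded, correct = correct,
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL

  miss <- tapply(trials$type == "go" & !trials$responded, trials$subject, sum)
  traits$miss_count <- as.integer(miss[traits$subject])

  list(trials = trials, traits = traits, truth = truth, config = config)
}

#' Generate single-trial amplitudes from the hierarchical model
#'
#' Draws trial-level component amplitudes from the generating linear model:
#' standardized amplitude = B_i' x_k + b_j rt_k + I_j + Student-t noise of
#' scale `sigma_g`, where x_k is the 11-column standardized design vector
#' (built with the same rules as the fitting stage).  The standardized
#' amplitude is mapped to microvolts by an affine transform whose defaults
#' match the reported grand-mean CRN (-1.17 uV, SD 0.76) and ERN
#' (-5.90 uV, SD 4.59) scales.
#'
#' CRN amplitudes are generated for correct (hit) go trials; ERN amplitudes
#' for false-alarm no-go trials.
#'
#' @param trials,traits tables from [simulateCohort()].
#' @param truth a [groundTruth()] list.
#' @param kind "CRN" (default) or "ERN".
#' @param mean_uV,sd_uV affine map from standardized amplitude to microvolts;
#'   defaults depend on `kind`.
#' @param seed integer seed for the noise draws.
#' @return data.frame with one row per usable trial: `subject`, `condition`,
#'   `block`, `trial`, `kind`, `rt_s`, `amp_z` (standardized, noise-free scale
#'   `amp_z_true` also included), `amplitude_uV`, `usable`.
#' @export
simulateTrialAmplitudes <- function(trials, traits, truth,
                                    kind = c("CRN", "ERN"),
                                    mean_uV = NULL, sd_uV = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(mean_uV)) mean_uV <- if (kind == "CRN") -1.17 else -5.90
  if (is.null(sd_uV)) sd_uV <- if (kind == "CRN") 0.76 else 4.59
  keep <- if (kind == "CRN") {
    trials$type == "go" & trials$responded & trials$correct
  } else {
    trials$type == "nogo" & trials$responded
  }
  tk <- trials[keep, , drop = FALSE]
  if (!nrow(tk)) stop("no qualifying trials for kind ", kind)
  if (!all(tk$subject %in% traits$subject))
    stop("trial rows reference subjects missing from the trait table")

  amps0 <- data.frame(subject = tk$subject, condition = tk$condition,
                      block = tk$block, trial = tk$trial, kind = kind,
                      rt_s = tk$rt_s, amplitude_uV = 0,
                      usable = TRUE, stringsAsFactors = FALSE)
  dm <- buildDesignMatrix(amps0, traits, standardizeOutcome = FALSE)

  jidx <- match(tk$subject, sort(unique(tk$subject)))
  if (length(truth$I) < max(jidx))
    stop("ground truth has fewer subjects than the trial table")
  cidx <- match(tk$condition, rownames(truth$B))
  if (anyNA(cidx)) stop("trial condition not present in truth$B")

  mu <- rowSums(dm$X * truth$B[cidx, , drop = FALSE]) +
    truth$b[jidx] * dm$X[, "rt"] + truth$I[jidx]
  set.seed(seed)
  noise <- truth$sigma_g * stats::rt(nrow(tk), df = truth$nu)
  z <- mu + noise

  out <- amps0
  out$amp_z_true <- mu
  out$amp_z <- z
  out$amplitude_uV <- mean_uV + sd_uV * z
  out
}

#' Parameters of the raw-EEG generator
#'
#' Defaults emulate a small fronto-central montage around FCz sampled at
#' 256 Hz: a stimulus-locked evoked template (P1/N1/P3-like), a
#' response-locked negativity template peaking 20 ms after the response,
#' 1/f background noise, optional 60-Hz line noise, and a configurable rate
#' of injected common-mode broadband artifact segments.
#'
#' The response-locked template is stored with unit peak amplitude; when a
#' trial is injected, the template is scaled so that its mean over the
#' peak +/- 50 ms window equals the trial's ground-truth amplitude, matching
#' the window-mean amplitude measure used downstream.
#'
#' @param rate_hz sampling rate.
#' @param channels channel labels; must include FCz.
#' @param crn_peak_ms latency of the response-locked negativity peak.
#' @param crn_sd_ms Gaussian width of the negativity.
#' @param noise_rms_uV RMS of the 1/f background per channel.
#' @param noise_exponent spectral exponent of the background (power ~ 1/f^a).
#' @param line_noise_uV amplitude of 60-Hz line noise (0 disables).
#' @param artifact_rate expected fraction of 0.5-s segments replaced by
#'   common-mode broadband artifact.
#' @param artifact_gain amplitude multiplier for injected artifacts.
#' @param crn_topo,evoked_topo optional named spatial profiles over
#'   `channels` (defaults: zero-mean patterns, response-locked maximal at
#'   FCz, evoked maximal centro-parietally).
#' @return list of class `eegSimParams`.
#' @export
eegSimParams <- function(rate_hz = 256,
                         channels = c("F3", "Fz", "F4", "FC3", "FCz", "FC4",
                                      "C3", "Cz", "C4"),
                         crn_peak_ms = 20, crn_sd_ms = 25,
                         noise_rms_uV = 0.3, noise_exponent = 1,
                         line_noise_uV = 0, artifact_rate = 0,
                         artifact_gain = 8, crn_topo = NULL,
                         evoked_topo = NULL) {
  if (!"FCz" %in% channels) stop("channel set must include FCz")
  p <- list(rate_hz = rate_hz, channels = channels,
            crn_peak_ms = crn_peak_ms, crn_sd_ms = crn_sd_ms,
            noise_rms_uV = noise_rms_uV, noise_exponent = noise_exponent,
            line_noise_uV = line_noise_uV, artifact_rate = artifact_rate,
            artifact_gain = artifact_gain, crn_topo = crn_topo,
            evoked_topo = evoked_topo)
  class(p) <- "eegSimParams"
  p
}

## stimulus-locked evoked template over 0..0.8 s (microvolts)
evokedTemplate <- function(rate_hz) {
  t <- seq(0, 0.8, by = 1 / rate_hz)
  uv <- 3 * exp(-((t - 0.120) / 0.030)^2 / 2) -
    4 * exp(-((t - 0.180) / 0.035)^2 / 2) +
    5 * exp(-((t - 0.350) / 0.080)^2 / 2)
  uv
}

## response-locked negativity template, unit (negative) peak at peak_ms
crnTemplate <- function(rate_hz, peak_ms = 20, sd_ms = 25,
                        span_ms = c(-100, 200)) {
  t <- seq(span_ms[1], span_ms[2], by = 1000 / rate_hz)
  list(t_ms = t, uv = -exp(-((t - peak_ms) / sd_ms)^2 / 2))
}

## 1/f ("pink") noise via spectral shaping, unit RMS
pinkNoise <- function(n, exponent = 1) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))              # avoid DC blowup
  f <- pmin(f, n - f + 1)                # two-sided symmetric frequencies
  shaped <- sp / (f^(exponent / 2))
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a continuous raw-EEG recording for one subject
#'
#' Builds a continuous multichannel recording in which each responded trial
#' contributes (a) the stimulus-locked evoked template at stimulus onset on
#' every channel and (b) the response-locked negativity template at the
#' response sample, scaled to that trial's ground-truth amplitude, with a
#' fronto-central spatial profile maximal at FCz.  The background is 1/f
#' noise, independent across channels, plus optional line noise.  Artifact
#' segments (identical broadband noise on all channels, scaled up) are
#' injected at the configured rate and their positions returned.
#'
#' @param trials trial table rows for a single subject.
#' @param amps amplitude table ([simulateTrialAmplitudes()]) for that subject.
#' @param params an [eegSimParams()] list.
#' @param seed integer seed.
#' @return list: `recording` (an [EEGRecording-class]), `artifacts`
#'   (data.frame of injected half-open sample intervals; zero rows when none).
#' @export
simulateRawEEG <- function(trials, amps, params = eegSimParams(), seed = 1L) {
  subj <- unique(trials$subject)
  if (length(subj) != 1L)
    stop("simulateRawEEG generates one subject's recording at a time")
  amps <- amps[amps$subject == subj, , drop = FALSE]
  rate <- params$rate_hz
  chans <- params$channels
  nch <- length(chans)

  dur_s <- max(trials$onset_s) + 2.0
  if (any(diff(sort(trials$onset_s)) < 1.0))
    stop("trial onsets overlap: scheduling error")
  n <- ceiling(dur_s * rate)

  set.seed(seed)
  dat <- matrix(0, nch, n, dimnames = list(chans, NULL))
  if (params$noise_rms_uV > 0)
    for (ch in seq_len(nch))
      dat[ch, ] <- params$noise_rms_uV * pinkNoise(n, params$noise_exponent)
  if (params$line_noise_uV > 0) {
    tt <- (seq_len(n) - 1) / rate
    line <- params$line_noise_uV * sin(2 * pi * 60 * tt)
    dat <- sweep(dat, 2, line, `+`)
  }

  ## Spatial profiles: maximal at FCz (response-locked) / centro-parietal
  ## (stimulus-evoked), each with zero mean over the montage.  Scalp
  ## potentials average to ~0 over a whole-head cap, so a zero-mean profile
  ## keeps the average reference from attenuating the injected components.
  topo <- params$crn_topo
  if (is.null(topo)) {
    topo <- stats::setNames(rep(-0.75, nch), chans)
    topo["FCz"] <- 1
    topo[names(topo) %in% c("Fz", "Cz")] <- 0.55
    topo[names(topo) %in% c("FC3", "FC4")] <- 0.45
  }
  if (is.null(params$crn_topo) && nch > 1) {
    topo <- topo - mean(topo)
    topo <- topo / topo["FCz"]
  }
  ev_topo <- params$evoked_topo
  if (is.null(ev_topo)) {
    ev_topo <- stats::setNames(rep(-0.6, nch), chans)
    ev_topo[names(ev_topo) %in% c("Cz", "C3", "C4")] <- 0.8
    if (nch > 1) ev_topo <- ev_topo - mean(ev_topo)
  }

  ev <- evokedTemplate(rate)
  crn <- crnTemplate(rate, params$crn_peak_ms, params$crn_sd_ms)
  ## normalize on the realized (rounded) sample grid so the downstream
  ## window-mean measure recovers the nominal amplitude exactly
  crn_offs <- round(crn$t_ms / 1000 * rate)
  t_actual <- crn_offs / rate * 1000
  win <- t_actual >= params$crn_peak_ms - 50 &
    t_actual <= params$crn_peak_ms + 50
  crn_scale <- mean(crn$uv[win])          # negative; window-mean of template

  events <- data.frame(sample = integer(), code = character())
  amp_of <- stats::setNames(amps$amplitude_uV, paste0(amps$trial))
  for (r in seq_len(nrow(trials))) {
    on_smp <- round(trials$onset_s[r] * rate) + 1L
    idx <- on_smp:(on_smp + length(ev) - 1L)
    ok <- idx >= 1 & idx <= n
    dat[, idx[ok]] <- dat[, idx[ok]] + ev_topo %o% ev[ok]
    events <- rbind(events, data.frame(
      sample = on_smp, code = paste0("stim_", trials$type[r])))
    if (isTRUE(trials$responded[r]) && !is.na(trials$rt_s[r])) {
      resp_smp <- round((trials$onset_s[r] + trials$rt_s[r]) * rate) + 1L
      events <- rbind(events, data.frame(sample = resp_smp, code = "response"))
      a <- amp_of[paste0(trials$trial[r])]
      if (!is.na(a)) {
        ridx <- resp_smp + crn_offs
        ok <- ridx >= 1 & ridx <= n
        ## scale so the window-mean of the injected waveform equals `a`
        dat[, ridx[ok]] <- dat[, ridx[ok]] +
          topo %o% (crn$uv[ok] * (a / crn_scale))
      }
    }
  }
  events <- events[order(events$sample), ]

  artifacts <- data.frame(start = integer(), end = integer())
  if (params$artifact_rate > 0) {
    seg_len <- round(0.5 * rate)
    n_seg <- floor(n / seg_len)
    hit <- which(stats::runif(n_seg) < params$artifact_rate)
    for (s in hit) {
      i0 <- (s - 1L) * seg_len + 1L
      burst <- params$artifact_gain * params$noise_rms_uV *
        stats::rnorm(seg_len)
      dat[, i0:(i0 + seg_len - 1L)] <-
        dat[, i0:(i0 + seg_len - 1L)] + rep(1, nch) %o% burst
      artifacts <- rbind(artifacts,
                         data.frame(start = i0, end = i0 + seg_len))
    }
  }

  rec <- EEGRecording(dat, rate = rate, labels = chans, events = events)
  list(recording = rec, artifacts = artifacts)
}

#' Simulate item-level questionnaire responses with a target reliability
#'
#' Generates a respondents x items matrix under an exchangeable one-factor
#' model whose population Cronbach's alpha equals `alpha`: each item is
#' `sqrt(rho) * T + sqrt(1 - rho) * e` with `rho = alpha / (k - alpha (k-1))`.
#' Used to exercise the internal-consistency estimator with a known target.
#'
#' @param n respondents.
#' @param k items.
#' @param alpha target population Cronbach's alpha (0 < alpha < 1).
#' @param mean,sd location and scale applied to each item.
#' @param seed integer seed.
#' @return numeric matrix, n x k.
#' @export
simulateTraitItems <- function(n, k, alpha, mean = 3.5, sd = 1, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, k >= 2)
  rho <- alpha / (k - alpha * (k - 1))
  set.seed(seed)
  T <- stats::rnorm(n)
  items <- sqrt(rho) * matrix(T, n, k) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
  mean + sd * items
}
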