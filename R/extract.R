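sampleAt <- function(time_s, rate) as.integer(round(time_s * rate)) + 1L

## qualifying trial rows for a component kind
qualifyingTrials <- function(trials, kind, purpose = c("epoch", "evoked")) {
  purpose <- match.arg(purpose)
  if (kind == "CRN") {
    trials[trials$type == "go" & trials$responded & trials$correct, ,
           drop = FALSE]
  } else if (purpose == "evoked") {
    trials[trials$type == "nogo", , drop = FALSE]   # all no-go trials
  } else {
    trials[trials$type == "nogo" & trials$responded, , drop = FALSE]
  }
}

#' Per-subject stimulus-locked evoked average
#'
#' Averages stimulus-aligned activity over a fixed span (default 0-1.5 s
#' after onset).  For the CRN the averaging set is all of the subject's
#' correct go responses; for the ERN it is all no-go trials (not only false
#' alarms), because false alarms are too rare to estimate the
#' stimulus-evoked activity.
#'
#' @param rec the subject's [EEGRecording-class].
#' @param trials that subject's trial table rows.
#' @param kind "CRN" or "ERN".
#' @param span_s stimulus-locked span (seconds from onset).
#' @return channels x samples matrix (the evoked average), with attributes
#'   `span_s` and `n_trials`.
#' @export
evokedAverage <- function(rec, trials, kind = c("CRN", "ERN"),
                          span_s = c(0, 1.5)) {
  kind <- match.arg(kind)
  q <- qualifyingTrials(trials, kind, "evoked")
  if (!nrow(q)) stop("no qualifying trials for the ", kind, " evoked average")
  rate <- samplingRate(rec)
  dat <- recData(rec)
  n_span <- as.integer(round((span_s[2] - span_s[1]) * rate))
  acc <- matrix(0, nrow(dat), n_span)
  used <- 0L
  for (r in seq_len(nrow(q))) {
    i0 <- sampleAt(q$onset_s[r] + span_s[1], rate)
    idx <- i0:(i0 + n_span - 1L)
    if (idx[1] < 1L || idx[n_span] > ncol(dat)) next
    acc <- acc + dat[, idx]
    used <- used + 1L
  }
  if (!used) stop("no qualifying trial fits within the recording")
  out <- acc / used
  rownames(out) <- channelLabels(rec)
  attr(out, "span_s") <- span_s
  attr(out, "n_trials") <- used
  out
}

#' Extract response-locked single-trial epochs
#'
#' For each qualifying trial (correct go responses for the CRN; false alarms
#' for the ERN) the subject's stimulus-locked evoked average is subtracted
#' in stimulus alignment, a -500..+500 ms epoch is cut around the button
#' press, and the epoch is baseline-corrected by the per-channel mean over
#' 500-400 ms pre-response.  Trials whose epoch overlaps a bad segment or
#' runs outside the recording are dropped and listed in the rejection log.
#'
#' @param rec the subject's (cleaned) [EEGRecording-class].
#' @param trials that subject's trial table rows.
#' @param evoked matrix from [evokedAverage()] (same subject and kind).
#' @param kind "CRN" or "ERN".
#' @param epoch_s epoch bounds in seconds relative to the response.
#' @param baseline_s baseline window in seconds relative to the response.
#' @return an [EpochSet-class].
#' @export
extractResponseEpochs <- function(rec, trials, evoked,
                                  kind = c("CRN", "ERN"),
                                  epoch_s = c(-0.5, 0.5),
                                  baseline_s = c(-0.5, -0.4)) {
  kind <- match.arg(kind)
  q <- qualifyingTrials(trials, kind, "epoch")
  rate <- samplingRate(rec)
  dat <- recData(rec)
  span_s <- attr(evoked, "span_s")
  if (is.null(span_s)) span_s <- c(0, 1.5)

  rel <- seq(round(epoch_s[1] * rate), round(epoch_s[2] * rate))
  times_ms <- rel / rate * 1000
  bs <- badSegments(rec)

  keep <- list(); ids <- integer(); rej <- list()
  for (r in seq_len(nrow(q))) {
    if (is.na(q$rt_s[r])) next
    resp <- sampleAt(q$onset_s[r] + q$rt_s[r], rate)
    idx <- resp + rel
    if (idx[1] < 1L || idx[length(idx)] > ncol(dat)) {
      rej[[length(rej) + 1L]] <- data.frame(trial = q$trial[r],
                                            reason = "out_of_bounds")
      next
    }
    if (nrow(bs) &&
        any(bs[, 1] < idx[length(idx)] + 1L & bs[, 2] > idx[1])) {
      rej[[length(rej) + 1L]] <- data.frame(trial = q$trial[r],
                                            reason = "bad_segment")
      next
    }
    ep <- dat[, idx, drop = FALSE]
    ## subtract the evoked average in stimulus-locked alignment
    on_smp <- sampleAt(q$onset_s[r] + span_s[1], rate)
    off <- idx - on_smp + 1L                  # column into evoked
    ok <- off >= 1L & off <= ncol(evoked)
    ep[, ok] <- ep[, ok] - evoked[, off[ok], drop = FALSE]
    ## baseline correction
    base_sel <- times_ms >= baseline_s[1] * 1000 &
      times_ms <= baseline_s[2] * 1000
    ep <- ep - rowMeans(ep[, base_sel, drop = FALSE])
    keep[[length(keep) + 1L]] <- ep
    ids <- c(ids, q$trial[r])
  }

  nch <- nrow(dat)
  wf <- array(NA_real_, c(length(keep), nch, length(times_ms)))
  for (i in seq_along(keep)) wf[i, , ] <- keep[[i]]
  rejections <- if (length(rej)) do.call(rbind, rej)
                else data.frame(trial = integer(), reason = character())
  new("EpochSet", waveforms = wf, times = times_ms,
      trialIds = as.integer(ids),
      subject = as.character(unique(trials$subject)[1]),
      kind = kind, channels = channelLabels(rec), rejections = rejections)
}

#' Grand-average response-locked waveform
#'
#' Averages each subject's mean epoch at one channel, then averages over
#' subjects.
#'
#' @param epochsList list of [EpochSet-class] objects (one per subject).
#' @param channel channel label (default FCz).
#' @return list: `mean` (microvolt vector), `times_ms`.
#' @export
grandAverage <- function(epochsList, channel = "FCz") {
  per_subj <- lapply(epochsList, function(ep) {
    ci <- match(channel, ep@channels)
    if (is.na(ci)) stop("channel ", channel, " missing from an EpochSet")
    if (dim(ep@waveforms)[1] == 0L) return(NULL)
    colMeans(ep@waveforms[, ci, , drop = FALSE][, 1, , drop = TRUE],
             na.rm = TRUE)
  })
  per_subj <- per_subj[!vapply(per_subj, is.null, logical(1))]
  if (!length(per_subj)) stop("no epochs available for the grand average")
  m <- colMeans(do.call(rbind, per_subj))
  list(mean = m, times_ms = epochsList[[1]]@times)
}

#' Locate the component window around the grand-mean negative peak
#'
#' Finds the time of the minimum of the grand-mean waveform within the
#' search range (0-200 ms post-response by default; ties broken by the
#' earliest minimum) and returns a window of plus and minus 50 ms around it.
#'
#' @param grand grand-mean waveform (microvolt vector), e.g. from
#'   [grandAverage()].
#' @param times_ms time axis of `grand` in ms relative to the response.
#' @param search_ms search range for the negative peak.
#' @param half_width_ms half-width of the returned window.
#' @return list of class `componentWindow`: `peak_ms`, `start_ms`, `end_ms`.
#' @export
findComponentWindow <- function(grand, times_ms, search_ms = c(0, 200),
                                half_width_ms = 50) {
  if (!all(is.finite(grand))) stop("grand mean contains non-finite values")
  sel <- which(times_ms >= search_ms[1] & times_ms <= search_ms[2])
  if (!length(sel)) stop("search range outside the epoch time axis")
  peak <- times_ms[sel][which.min(grand[sel])]
  structure(list(peak_ms = peak, start_ms = peak - half_width_ms,
                 end_ms = peak + half_width_ms),
            class = "componentWindow")
}

#' Single-trial window-mean amplitudes
#'
#' One amplitude per trial: the time-mean of the epoch waveform at one
#' channel over the component window (the window mean, not the peak, is
#' used because the average over time is an unbiased amplitude estimate).
#'
#' @param epochs an [EpochSet-class].
#' @param window a `componentWindow` from [findComponentWindow()].
#' @param channel channel label (default FCz).
#' @return data.frame: `trial`, `amplitude_uV`.
#' @export
meanAmplitude <- function(epochs, window, channel = "FCz") {
  ci <- match(channel, epochs@channels)
  if (is.na(ci)) stop("channel ", channel, " not present in the epochs")
  if (window$start_ms < min(epochs@times) ||
      window$end_ms > max(epochs@times))
    stop("component window extends beyond the epoch time span")
  sel <- epochs@times >= window$start_ms & epochs@times <= window$end_ms
  n_tr <- dim(epochs@waveforms)[1]
  amp <- vapply(seq_len(n_tr), function(i)
    mean(epochs@waveforms[i, ci, sel]), numeric(1))
  data.frame(trial = epochs@trialIds, amplitude_uV = amp)
}

#' Assemble a single-trial amplitude table
#'
#' Applies [meanAmplitude()] to each subject's epochs and joins trial
#' metadata (condition, block, response time).
#'
#' @param epochsList list of [EpochSet-class] objects.
#' @param window a `componentWindow`.
#' @param trials the cohort trial table.
#' @param channel channel label.
#' @return data.frame: `subject`, `condition`, `block`, `trial`, `kind`,
#'   `rt_s`, `amplitude_uV`, `usable`.
#' @export
amplitudeTable <- function(epochsList, window, trials, channel = "FCz") {
  out <- lapply(epochsList, function(ep) {
    a <- meanAmplitude(ep, window, channel)
    tr <- trials[trials$subject == ep@subject, , drop = FALSE]
    mi <- match(a$trial, tr$trial)
    data.frame(subject = ep@subject, condition = tr$condition[mi],
               block = tr$block[mi], trial = a$trial, kind = ep@kind,
               rt_s = tr$rt_s[mi], amplitude_uV = a$amplitude_uV,
               usable = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply subject- and trial-retention criteria
#'
#' Two rules: (1) subjects with a false-alarm rate of 83% or more on 10 or
#' more blocks are excluded entirely (inattention screen); (2) for the ERN,
#' subjects with fewer than `min_error_trials` usable error trials are
#' excluded from the ERN set (they remain usable for the CRN).
#'
#' @param amps amplitude table ([amplitudeTable()] or the simulator's).
#' @param trials the cohort trial table (for per-block false-alarm rates).
#' @param min_error_trials minimum usable error trials for the ERN (6).
#' @param fa_rate_thresh per-block false-alarm rate threshold (0.83).
#' @param fa_min_blocks number of high-FA blocks triggering exclusion (10).
#' @return list: `amps` (filtered table), `exclusions` (data.frame
#'   `subject`, `rule`, `detail`).
#' @export
applyTrialCriteria <- function(amps, trials, min_error_trials = 6L,
                               fa_rate_thresh = 0.83, fa_min_blocks = 10L) {
  excl <- list()

  ## rule 1: sustained high false-alarm rate -> drop subject entirely
  nogo <- trials[trials$type == "nogo", , drop = FALSE]
  if (nrow(nogo)) {
    fa_blocks <- tapply(nogo$responded, list(nogo$subject, nogo$block), mean)
    n_high <- rowSums(fa_blocks >= fa_rate_thresh, na.rm = TRUE)
    drop_all <- names(n_high)[n_high >= fa_min_blocks]
    for (s in drop_all)
      excl[[length(excl) + 1L]] <- data.frame(
        subject = s, rule = "high_false_alarm_rate",
        detail = sprintf("FA rate >= %.0f%% on %d blocks",
                         100 * fa_rate_thresh, n_high[[s]]))
    amps <- amps[!amps$subject %in% drop_all, , drop = FALSE]
  }

  ## rule 2: ERN requires >= min_error_trials usable error trials
  ern <- amps[amps$kind == "ERN" & amps$usable, , drop = FALSE]
  if (nrow(ern)) {
    n_err <- table(ern$subject)
    few <- names(n_err)[n_err < min_error_trials]
    for (s in few)
      excl[[length(excl) + 1L]] <- data.frame(
        subject = s, rule = "too_few_error_trials",
        detail = sprintf("%d usable error trials", n_err[[s]]))
    amps <- amps[!(amps$kind == "ERN" & amps$subject %in% few), ,
                 drop = FALSE]
  }

  exclusions <- if (length(excl)) do.call(rbind, excl)
                else data.frame(subject = character(), rule = character(),
                                detail = character())
  list(amps = amps, exclusions = exclusions)
}
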