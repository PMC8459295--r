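#' Butterworth filtering of a continuous recording
#'
#' Applies one cleaning-stage filter to every channel.  Defaults follow the
#' pipeline's reduction settings: a 0.2-Hz second-order high-pass, a
#' 58-62-Hz second-order band-stop, and a 30-Hz sixth-order low-pass applied
#' in two passes (forward and reverse) for zero net phase.
#'
#' @param rec an [EEGRecording-class].
#' @param stage "highpass", "bandstop" or "lowpass".
#' @param cutoff_hz cutoff (scalar, or length-2 band for the band-stop).
#' @param order filter order.
#' @param twoPass apply forward-reverse (zero-phase) filtering; default TRUE
#'   only for the low-pass stage.
#' @return the filtered [EEGRecording-class].
#' @export
filterContinuous <- function(rec,
                             stage = c("highpass", "bandstop", "lowpass"),
                             cutoff_hz = NULL, order = NULL, twoPass = NULL) {
  stage <- match.arg(stage)
  fs <- samplingRate(rec)
  defaults <- switch(stage,
    highpass = list(cutoff = 0.2, order = 2L, two = FALSE, type = "high"),
    bandstop = list(cutoff = c(58, 62), order = 2L, two = FALSE, type = "stop"),
    lowpass = list(cutoff = 30, order = 6L, two = TRUE, type = "low"))
  if (is.null(cutoff_hz)) cutoff_hz <- defaults$cutoff
  if (is.null(order)) order <- defaults$order
  if (is.null(twoPass)) twoPass <- defaults$two
  if (any(cutoff_hz >= fs / 2))
    stop("filter cutoff at or above the Nyquist frequency (", fs / 2, " Hz)")

  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = defaults$type)
  dat <- recData(rec)
  for (ch in seq_len(nrow(dat))) {
    x <- dat[ch, ]
    dat[ch, ] <- if (twoPass) signal::filtfilt(bf, x)
                 else as.numeric(signal::filter(bf, x))
  }
  rec@data <- dat
  rec@log <- c(rec@log, sprintf("%s(%s Hz, order %d%s)", stage,
                                paste(cutoff_hz, collapse = "-"), order,
                                if (twoPass) ", two-pass" else ""))
  validObject(rec)
  rec
}

#' Approximate 2-d montage positions for fronto-central 10-10 labels
#'
#' Schematic positions on a unit head (nose up) for a 25-channel
#' fronto-central subset of the 10-10 system, used to define interpolation
#' neighborhoods.
#'
#' @return data.frame: `label`, `x`, `y`.
#' @export
montagePositions <- function() {
  g <- expand.grid(xi = -2:2, yi = 2:-2)
  rows <- c("F", "FC", "C", "CP", "P")
  cols <- c("3", "1", "z", "2", "4")
  lab <- paste0(rows[match(g$yi, 2:-2)], cols[match(g$xi, -2:2)])
  data.frame(label = lab, x = g$xi * 0.2, y = g$yi * 0.2,
             stringsAsFactors = FALSE)
}

#' Montage neighbor sets
#'
#' Neighbors are channels within `radius` of each other on the schematic
#' montage (immediate grid neighbors at the default radius).
#'
#' @param labels channel labels to consider.
#' @param radius neighborhood radius on the unit-head layout.
#' @return named list mapping each label to its neighbor labels.
#' @export
montageNeighbors <- function(labels, radius = 0.29) {
  pos <- montagePositions()
  pos <- pos[match(labels, pos$label), ]
  if (anyNA(pos$x))
    stop("unknown montage labels: ",
         paste(labels[is.na(pos$x)], collapse = ", "))
  d <- as.matrix(stats::dist(pos[, c("x", "y")]))
  out <- lapply(seq_along(labels), function(i) {
    labels[d[i, ] > 0 & d[i, ] <= radius]
  })
  stats::setNames(out, labels)
}

#' Interpolate bad channels from montage neighbors
#'
#' Replaces each listed channel by the unweighted mean of its montage
#' neighbors at every sample; other channels are untouched.
#'
#' @param rec an [EEGRecording-class].
#' @param bad character vector of channel labels to interpolate.
#' @return the repaired [EEGRecording-class].
#' @export
interpolateChannels <- function(rec, bad) {
  if (!length(bad)) return(rec)
  labels <- channelLabels(rec)
  if (!all(bad %in% labels))
    stop("bad channels not in recording: ",
         paste(setdiff(bad, labels), collapse = ", "))
  nb <- montageNeighbors(labels)
  dat <- recData(rec)
  repaired <- recData(rec)
  for (ch in bad) {
    good_nb <- setdiff(nb[[ch]], bad)
    if (length(good_nb) < 2L)
      stop("channel ", ch, " has fewer than 2 usable montage neighbors")
    repaired[ch, ] <- colMeans(dat[good_nb, , drop = FALSE])
  }
  rec@data <- repaired
  rec@log <- c(rec@log, paste0("interpolate(", paste(bad, collapse = ","), ")"))
  rec
}

#' Flag noisy channel candidates
#'
#' Automated replacement for visual channel screening: a channel is flagged
#' when its robust SD (median absolute deviation) exceeds `k` times the
#' median robust SD over channels.
#'
#' @param rec an [EEGRecording-class].
#' @param k multiplier on the median robust SD (default 5).
#' @return character vector of flagged channel labels.
#' @export
flagNoisyChannels <- function(rec, k = 5) {
  s <- apply(recData(rec), 1, stats::mad)
  channelLabels(rec)[s > k * stats::median(s)]
}

#' Re-reference to the channel average
#'
#' Subtracts the across-channel mean at every sample, so the channel mean is
#' zero everywhere afterwards.
#'
#' @param rec an [EEGRecording-class] with at least 2 channels.
#' @return the re-referenced [EEGRecording-class].
#' @export
rereferenceAverage <- function(rec) {
  dat <- recData(rec)
  if (nrow(dat) < 2L) stop("average reference needs at least 2 channels")
  rec@data <- sweep(dat, 2, colMeans(dat))
  rec@log <- c(rec@log, "average-reference")
  rec
}

#' Detect bad segments by cross-channel spectral correlation
#'
#' Divides the recording into non-overlapping segments (0.5 s by default),
#' computes each channel's spectrum by discrete Fourier transform over the
#' analysis band (1-100 Hz amplitude spectra by default), Pearson-correlates
#' the spectra of every channel pair, and averages over pairs to score each
#' segment.  Segments whose score deviates from the mean score by more than
#' `z_thresh` standard deviations (two-sided) are flagged and appended to
#' the recording's bad-segment list.
#'
#' @param rec an [EEGRecording-class] with at least 2 channels and at least
#'   2 full segments.
#' @param seg_len_s segment length in seconds.
#' @param z_thresh flagging threshold in SD units (default 1.8).
#' @param band_hz analysis band for the spectra.
#' @param spectrum "amplitude" (default), "power" or "log".
#' @return list: `scores` (data.frame `segment`, `start`, `end`, `score`,
#'   `flagged`; intervals are half-open samples) and `recording` (input with
#'   flagged intervals appended to its bad segments).
#' @export
detectBadSegments <- function(rec, seg_len_s = 0.5, z_thresh = 1.8,
                              band_hz = c(1, 100),
                              spectrum = c("amplitude", "power", "log")) {
  spectrum <- match.arg(spectrum)
  dat <- recData(rec)
  if (nrow(dat) < 2L) stop("segment detector needs at least 2 channels")
  fs <- samplingRate(rec)
  L <- round(seg_len_s * fs)
  n_seg <- floor(ncol(dat) / L)
  if (n_seg < 2L) stop("recording shorter than 2 segments")

  freqs <- (seq_len(L) - 1) * fs / L
  keep <- freqs >= band_hz[1] & freqs <= min(band_hz[2], fs / 2)

  score <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1L) * L + 1L):(s * L)
    sp <- abs(stats::mvfft(t(dat[, idx])))[keep, , drop = FALSE]
    sp <- switch(spectrum, amplitude = sp, power = sp^2, log = log(sp + 1e-12))
    cc <- stats::cor(sp)
    score[s] <- mean(cc[upper.tri(cc)])
  }
  mu <- mean(score); sdv <- stats::sd(score)
  flagged <- if (is.finite(sdv) && sdv > 0)
    abs(score - mu) > z_thresh * sdv else rep(FALSE, n_seg)

  starts <- (seq_len(n_seg) - 1L) * L + 1L
  scores <- data.frame(segment = seq_len(n_seg), start = starts,
                       end = starts + L, score = score, flagged = flagged)
  if (any(flagged)) {
    add <- cbind(start = starts[flagged], end = starts[flagged] + L)
    rec@badSegments <- mergeIntervals(rbind(rec@badSegments, add))
    validObject(rec)
  }
  rec@log <- c(rec@log, sprintf("segment-scan(%gs, %.1f SD): %d flagged",
                                seg_len_s, z_thresh, sum(flagged)))
  list(scores = scores, recording = rec)
}

## merge possibly-overlapping half-open intervals
mergeIntervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (r in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[r, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], iv[r, 2])
    } else out <- rbind(out, iv[r, , drop = FALSE])
  }
  colnames(out) <- c("start", "end")
  out
}

#' Run the standard cleaning chain
#'
#' Convenience wrapper enforcing the cleaning order: high-pass, band-stop,
#' channel interpolation, average reference, segment scoring, low-pass.
#' (Ocular cleaning is a pluggable external step between re-referencing and
#' segment scoring and is not performed here.)
#'
#' @param rec an [EEGRecording-class].
#' @param badChannels labels to interpolate (default: automatic flagging).
#' @param z_thresh segment-flagging threshold.
#' @return the cleaned [EEGRecording-class] with bad segments recorded.
#' @export
preprocessRecording <- function(rec, badChannels = NULL, z_thresh = 1.8) {
  rec <- filterContinuous(rec, "highpass")
  rec <- filterContinuous(rec, "bandstop")
  if (is.null(badChannels)) badChannels <- flagNoisyChannels(rec)
  if (length(badChannels)) rec <- interpolateChannels(rec, badChannels)
  rec <- rereferenceAverage(rec)
  rec <- detectBadSegments(rec, z_thresh = z_thresh)$recording
  filterContinuous(rec, "lowpass")
}
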