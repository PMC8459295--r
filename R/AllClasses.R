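#' @import methods
NULL

#' Continuous multichannel EEG recording
#'
#' Container for a continuous EEG recording: a channels-by-samples voltage
#' matrix in microvolts, the sampling rate, 10-10 channel labels, an event
#' table, and a set of half-open bad-segment sample intervals accumulated by
#' the cleaning stages.
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot rate sampling rate in Hz.
#' @slot labels character vector of unique channel labels (10-10 names).
#' @slot events data.frame with columns `sample` (1-based sample index,
#'   sorted) and `code` (character event code).
#' @slot badSegments two-column integer matrix of half-open sample intervals
#'   `[start, end)`, non-overlapping and within bounds.
#' @slot log character vector recording the processing steps applied.
#'
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    rate = "numeric",
    labels = "character",
    events = "data.frame",
    badSegments = "matrix",
    log = "character"
  ),
  prototype(
    events = data.frame(sample = integer(), code = character()),
    badSegments = matrix(integer(), ncol = 2,
                         dimnames = list(NULL, c("start", "end"))),
    log = character()
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (nrow(object@data) != length(object@labels))
    msg <- c(msg, "nrow(data) must equal length(labels)")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  ev <- object@events
  if (!all(c("sample", "code") %in% names(ev)))
    msg <- c(msg, "events must have columns 'sample' and 'code'")
  else if (nrow(ev) > 1L && is.unsorted(ev$sample))
    msg <- c(msg, "events must be sorted by sample")
  bs <- object@badSegments
  if (ncol(bs) != 2L)
    msg <- c(msg, "badSegments must have two columns")
  else if (nrow(bs) > 0L) {
    if (any(bs[, 1] >= bs[, 2]))
      msg <- c(msg, "badSegments intervals must be non-empty half-open [start, end)")
    if (any(bs[, 1] < 1L) || any(bs[, 2] > ncol(object@data) + 1L))
      msg <- c(msg, "badSegments out of recording bounds")
    o <- order(bs[, 1])
    if (nrow(bs) > 1L && any(bs[o, 1][-1] < bs[o, 2][-nrow(bs)]))
      msg <- c(msg, "badSegments must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param rate sampling rate (Hz).
#' @param labels channel labels; defaults to rownames of `data`.
#' @param events event data.frame (`sample`, `code`).
#' @param badSegments two-column matrix of half-open sample intervals.
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, rate, labels = rownames(data),
                         events = data.frame(sample = integer(),
                                             code = character()),
                         badSegments = matrix(integer(), ncol = 2)) {
  if (is.null(labels)) stop("channel labels are required")
  data <- as.matrix(data)
  rownames(data) <- labels
  badSegments <- matrix(as.integer(badSegments), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))
  new("EEGRecording", data = data, rate = rate, labels = labels,
      events = events, badSegments = badSegments)
}

#' @describeIn EEGRecording-class number of samples
#' @param x,object an `EEGRecording`
#' @export
setMethod("ncol", "EEGRecording", function(x) ncol(x@data))

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", length(object@labels), "channels x",
      ncol(object@data), "samples @", object@rate, "Hz\n")
  cat("  channels:", paste(utils::head(object@labels, 10), collapse = " "),
      if (length(object@labels) > 10) "..." else "", "\n")
  cat("  events:", nrow(object@events),
      "| bad segments:", nrow(object@badSegments), "\n")
  if (length(object@log))
    cat("  processing:", paste(object@log, collapse = " -> "), "\n")
})

#' @rdname accessors
#' @param rec an [EEGRecording-class]
#' @return `recData`: the channels x samples voltage matrix.
#' @export
recData <- function(rec) rec@data

#' @rdname accessors
#' @return `samplingRate`: the sampling rate in Hz.
#' @export
samplingRate <- function(rec) rec@rate

#' @rdname accessors
#' @return `channelLabels`: character vector of channel labels.
#' @export
channelLabels <- function(rec) rec@labels

#' @rdname accessors
#' @return `eventTable`: the event data.frame.
#' @export
eventTable <- function(rec) rec@events

#' Recording accessors
#'
#' Small accessor functions for [EEGRecording-class] slots.
#'
#' @name accessors
#' @rdname accessors
#' @return `badSegments`: two-column matrix of half-open bad-sample intervals.
#' @export
badSegments <- function(rec) rec@badSegments

#' Set of response-locked single-trial epochs
#'
#' Trials x channels x time array of response-locked waveforms for one
#' subject, with a millisecond time axis relative to the button press.
#' Epochs are baseline-corrected on construction; trials whose epoch
#' overlapped a bad segment (or ran off the recording) are absent and listed
#' in the rejection log.
#'
#' @slot waveforms numeric array, trials x channels x time (microvolts).
#' @slot times numeric vector of epoch times in ms relative to the response.
#' @slot trialIds integer ids of the retained trials.
#' @slot subject subject identifier.
#' @slot kind "CRN" or "ERN".
#' @slot channels channel labels (second array dimension).
#' @slot rejections data.frame (`trial`, `reason`) of dropped trials.
#' @export
setClass("EpochSet",
  representation(
    waveforms = "array",
    times = "numeric",
    trialIds = "integer",
    subject = "character",
    kind = "character",
    channels = "character",
    rejections = "data.frame"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@waveforms)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "waveforms must be a 3-d array")
  else {
    if (d[1] != length(object@trialIds))
      msg <- c(msg, "dim 1 of waveforms must match trialIds")
    if (d[2] != length(object@channels))
      msg <- c(msg, "dim 2 of waveforms must match channels")
    if (d[3] != length(object@times))
      msg <- c(msg, "dim 3 of waveforms must match times")
  }
  if (!object@kind %in% c("CRN", "ERN"))
    msg <- c(msg, "kind must be 'CRN' or 'ERN'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@waveforms)
  cat(sprintf("EpochSet (%s), subject %s: %d trials x %d channels x %d samples\n",
              object@kind, object@subject, d[1], d[2], d[3]))
  cat(sprintf("  time %g..%g ms relative to response; %d trials rejected\n",
              min(object@times), max(object@times), nrow(object@rejections)))
})

#' @rdname epoch-accessors
#' @param x an [EpochSet-class]
#' @return `epochArray`: the trials x channels x time array.
#' @export
epochArray <- function(x) x@waveforms

#' Epoch accessors
#' @name epoch-accessors
#' @rdname epoch-accessors
#' @return `epochTimes`: the time axis in ms relative to the response.
#' @export
epochTimes <- function(x) x@times

#' Posterior draws from the hierarchical model
#'
#' Draws for all parameters of the horseshoe hierarchical Student-t
#' regression, stored per chain, together with the metadata needed to label
#' them (condition levels, predictor names, subject ids) and the sampler
#' settings.
#'
#' @slot draws named list of draw arrays; matrices are iterations x chains,
#'   4-d arrays are iterations x chains x condition x predictor, 3-d arrays
#'   iterations x chains x subject.
#' @slot chains number of chains.
#' @slot warmup warmup iterations per chain (discarded).
#' @slot samples retained iterations per chain.
#' @slot extended TRUE if the model includes per-subject RT slopes.
#' @slot meta list: `predictors`, `conditions`, `subjects`, `spec`, `seed`.
#' @export
setClass("PosteriorFit",
  representation(
    draws = "list",
    chains = "integer",
    warmup = "integer",
    samples = "integer",
    extended = "logical",
    meta = "list"
  )
)

setValidity("PosteriorFit", function(object) {
  msg <- character()
  need <- c("B", "I", "I0", "sigma_g", "sigma_I", "nu", "tau", "c2", "lambda")
  if (!all(need %in% names(object@draws)))
    msg <- c(msg, paste("draws must contain:", paste(need, collapse = ", ")))
  else {
    for (nm in c("sigma_g", "tau", "c2"))
      if (any(object@draws[[nm]] <= 0))
        msg <- c(msg, paste(nm, "draws must be positive"))
    if (!all(vapply(object@draws, function(d) all(is.finite(d)), logical(1))))
      msg <- c(msg, "all draws must be finite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PosteriorFit", function(object) {
  cat(sprintf("PosteriorFit (%s model): %d chains x %d draws (+%d warmup)\n",
              if (object@extended) "extended" else "basic",
              object@chains, object@samples, object@warmup))
  cat(sprintf("  %d conditions x %d predictors, %d subjects\n",
              length(object@meta$conditions), length(object@meta$predictors),
              length(object@meta$subjects)))
})

#' @rdname fit-accessors
#' @param fit a [PosteriorFit-class]
#' @return `posteriorDraws`: the named list of draw arrays.
#' @export
posteriorDraws <- function(fit) fit@draws

#' Posterior fit accessors
#' @name fit-accessors
#' @rdname fit-accessors
#' @param parameter one of the scalar parameter names
#' @return `scalarDraws`: all post-warmup draws of a scalar parameter,
#'   pooled across chains.
#' @export
scalarDraws <- function(fit, parameter) as.vector(fit@draws[[parameter]])

#' Generalizability-theory reliability report
#'
#' Subject-level internal consistency coefficients and group-level
#' fixed-effects dependability curves computed from an extended-model
#' posterior, plus the retention threshold applied downstream.
#'
#' @slot subjects data.frame: per subject `subject`, `condition`, `n_trials`,
#'   `sigma_m2`, `sigma_e2`, `phi` (posterior mean), `phi_lo`, `phi_hi`.
#' @slot groups named list (per condition) of data.frames with columns `S`,
#'   `phi`, `phi_lo`, `phi_hi` and an attribute `components` holding the
#'   posterior-mean variance components and the harmonic-mean trial count.
#' @slot threshold retention threshold on subject internal consistency.
#' @export
setClass("ReliabilityReport",
  representation(
    subjects = "data.frame",
    groups = "list",
    threshold = "numeric"
  )
)

setValidity("ReliabilityReport", function(object) {
  msg <- character()
  s <- object@subjects
  need <- c("subject", "n_trials", "sigma_m2", "sigma_e2", "phi")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste("subjects must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(stats::na.omit(c(s$sigma_m2, s$sigma_e2)) < 0))
      msg <- c(msg, "variance components must be non-negative")
    if (any(stats::na.omit(s$phi) < 0 | stats::na.omit(s$phi) > 1))
      msg <- c(msg, "phi must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReliabilityReport", function(object) {
  cat(sprintf("ReliabilityReport: %d subjects, %d group curves, threshold %.2f\n",
              nrow(object@subjects), length(object@groups), object@threshold))
  n_low <- sum(object@subjects$phi < object@threshold, na.rm = TRUE)
  cat(sprintf("  %d subject(s) below threshold\n", n_low))
})
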