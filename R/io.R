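## ---- EDF/BDF I/O -----------------------------------------------------------
## Fixed-layout European Data Format: 256-byte global header, 256 bytes per
## signal, then 16-bit little-endian samples record by record.  BDF (the
## BioSemi 24-bit variant) is supported for reading.

padField <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording as EDF
#'
#' Continuous signals only; one-second data records; the last record is
#' zero-padded.  Events are not embedded (keep them in a TSV sidecar; see
#' [readRecordingEDF()]).
#'
#' @param rec an [EEGRecording-class] with an integer sampling rate.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRecordingEDF <- function(rec, path) {
  dat <- recData(rec)
  fs <- samplingRate(rec)
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(dat)
  n_rec <- ceiling(ncol(dat) / fs)
  pad <- n_rec * fs - ncol(dat)
  if (pad > 0) dat <- cbind(dat, matrix(0, ns, pad))

  pmin <- floor(apply(dat, 1, min)); pmax <- ceiling(apply(dat, 1, max))
  same <- pmax <= pmin
  pmax[same] <- pmin[same] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8), padField("synthetic subject", 80),
    padField("synthetic recording", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * (1 + ns), 8), padField("", 44),
    padField(n_rec, 8), padField(1, 8), padField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    padField(channelLabels(rec), 16), padField(rep("AgAgCl", ns), 80),
    padField(rep("uV", ns), 8), padField(pmin, 8), padField(pmax, 8),
    padField(rep(dmin, ns), 8), padField(rep(dmax, ns), 8),
    padField(rep("", ns), 80), padField(rep(fs, ns), 8),
    padField(rep("", ns), 32))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((dat[ch, idx] - pmin[ch]) * scale[ch]) + dmin
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

readInt24 <- function(raw3) {
  n <- length(raw3) / 3
  m <- matrix(as.integer(raw3), 3, n)
  v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
  v - (v >= 8388608) * 16777216
}

#' Read an EDF or BDF recording
#'
#' Parses the fixed-layout header and sample records, converts to physical
#' units (microvolts assumed), and attaches events from an optional TSV
#' sidecar with columns `sample` and `code`.
#'
#' @param path an EDF (16-bit) or BDF (24-bit BioSemi) file.
#' @param events optional path to an events TSV, or an events data.frame.
#' @return an [EEGRecording-class].
#' @export
readRecordingEDF <- function(path, events = NULL) {
  if (!file.exists(path)) stop("cannot read recording: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 1)
  magic <- rawToChar(readBin(con, "raw", 7))
  is_bdf <- as.integer(first) == 255L && magic == "BIOSEMI"
  grab <- function(width) {
    trimws(rawToChar(readBin(con, "raw", width)))
  }
  grab(80); grab(80); grab(8); grab(8)
  hdr_bytes <- as.integer(grab(8)); grab(44)
  n_rec <- as.integer(grab(8))
  rec_dur <- as.numeric(grab(8))
  ns <- as.integer(grab(4))
  if (is.na(ns) || ns < 1) stop("truncated header in ", path, " at offset 252")

  labels <- trimws(vapply(seq_len(ns), function(i) grab(16), character(1)))
  grabN <- function(width) vapply(seq_len(ns), function(i) grab(width),
                                  character(1))
  grabN(80); grabN(8)
  pmin <- as.numeric(grabN(8)); pmax <- as.numeric(grabN(8))
  dmin <- as.numeric(grabN(8)); dmax <- as.numeric(grabN(8))
  grabN(80)
  spr <- as.integer(grabN(8))
  grabN(32)
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur

  bytes_per <- if (is_bdf) 3L else 2L
  dat <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- if (is_bdf) {
        readInt24(readBin(con, "raw", 3L * spr[ch]))
      } else {
        readBin(con, "integer", spr[ch], size = 2, signed = TRUE,
                endian = "little")
      }
      if (length(dig) < spr[ch])
        stop("truncated data in ", path, " at record ", r,
             " (offset ", hdr_bytes + (r - 1) * sum(spr) * bytes_per, ")")
      phys <- (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) *
        (pmax[ch] - pmin[ch]) + pmin[ch]
      dat[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }

  ev <- data.frame(sample = integer(), code = character())
  if (!is.null(events)) {
    ev <- if (is.character(events))
      utils::read.delim(events, stringsAsFactors = FALSE) else events
    if (!all(c("sample", "code") %in% names(ev)))
      stop("events table needs columns 'sample' and 'code'")
    ev <- ev[order(ev$sample), ]
  }
  EEGRecording(dat, rate = fs, labels = labels, events = ev)
}

## ---- tables ---------------------------------------------------------------

#' Write a table as TSV (and read it back)
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeTableTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTableTSV
#' @export
readTableTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

## ---- pipeline configuration ------------------------------------------------

pipelineDefaults <- function() {
  list(
    seed = 1L,
    sim = list(group_sizes = c(gain = 26L, loss = 35L, control = 30L),
               n_blocks = 20L, eeg_subjects = 0L),
    filters = list(highpass_hz = 0.2, highpass_order = 2L,
                   bandstop_hz = c(58, 62), bandstop_order = 2L,
                   lowpass_hz = 30, lowpass_order = 6L),
    segments = list(seg_len_s = 0.5, z_thresh = 1.8, band_hz = c(1, 100),
                    spectrum = "amplitude"),
    epochs = list(epoch_s = c(-0.5, 0.5), baseline_s = c(-0.5, -0.4),
                  span_s = c(0, 1.5), search_ms = c(0, 200),
                  half_width_ms = 50, channel = "FCz"),
    criteria = list(min_error_trials = 6L, fa_rate_thresh = 0.83,
                    fa_min_blocks = 10L),
    model = list(p0 = 9, nu0 = 20, s = 1, chains = 4L, warmup = 1000L,
                 samples = 500L, full_settings = FALSE),
    reliability = list(threshold = 0.8,
                       S_grid = c(5, 10, 15, 20, 26, 30, 35, 40, 50, 75, 100),
                       max_draws = 400L)
  )
}

mergeConfig <- function(defaults, overrides, path = "") {
  for (nm in names(overrides)) {
    key <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", key)
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- mergeConfig(defaults[[nm]], overrides[[nm]], key)
    } else if (!is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      ## YAML readers hand named vectors back as lists
      v <- unlist(overrides[[nm]])
      storage.mode(v) <- storage.mode(defaults[[nm]])
      defaults[[nm]] <- v
    } else {
      v <- overrides[[nm]]
      if (is.numeric(v) && is.numeric(defaults[[nm]]))
        storage.mode(v) <- storage.mode(defaults[[nm]])
      defaults[[nm]] <- v
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' All numeric constants of every stage, with the pipeline's defaults
#' (filter cutoffs and orders, 0.5-s segments with the 1.8-SD rule,
#' +/-500 ms epochs with a -500..-400 ms baseline, 50-ms window half-width,
#' 6-trial minimum, .8 reliability threshold, p0 = 9, nu0 = 20, s = 1, and
#' the sampler settings).  Unknown keys are rejected.
#'
#' @param overrides named list of overrides (possibly nested).
#' @param seed integer seed for the whole run.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(overrides = list(), seed = 1L) {
  cfg <- mergeConfig(pipelineDefaults(), overrides)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks that every constant of every stage is present (a hand-edited
#' configuration missing a key is rejected with the key's name) and that no
#' unknown keys appear.
#'
#' @param config a configuration list.
#' @return the config, invisibly; errors otherwise.
#' @export
validatePipelineConfig <- function(config) {
  checkKeys <- function(defaults, cfg, path = "") {
    for (nm in names(defaults)) {
      key <- if (nzchar(path)) paste0(path, "$", nm) else nm
      if (!nm %in% names(cfg) || is.null(cfg[[nm]]))
        stop("configuration is missing required key: ", key)
      if (is.list(defaults[[nm]]))
        checkKeys(defaults[[nm]], cfg[[nm]], key)
    }
    for (nm in setdiff(names(cfg), names(defaults))) {
      key <- if (nzchar(path)) paste0(path, "$", nm) else nm
      stop("unknown configuration key: ", key)
    }
  }
  checkKeys(pipelineDefaults(), config)
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config a `pipelineConfig`.
#' @return `readPipelineConfig`: the validated configuration;
#'   `writePipelineConfig`: `path`, invisibly.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- if (!is.null(raw$seed)) raw$seed else 1L
  raw$seed <- NULL
  pipelineConfig(overrides = raw, seed = seed)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  ## named atomic vectors must become maps, or YAML drops their names
  toYaml <- function(x) {
    if (is.list(x)) lapply(x, toYaml)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(toYaml(unclass(config)), path)
  invisible(path)
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writePipelineConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

## ---- pipeline driver --------------------------------------------------------

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages on a synthetic cohort: simulate (trials,
#' traits, trial amplitudes), optionally raw-EEG generation + cleaning +
#' extraction for a few subjects, the hierarchical model fit (basic and
#' extended), the reliability report with subject retention, the behavioral
#' reduced-rank regression, and summary tables.  Every run writes a
#' `MANIFEST.json` sidecar carrying the configuration hash and seed; given
#' the same configuration the outputs are identical.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory (created).
#' @param stages subset of
#'   `c("simulate", "extract", "fit", "reliability", "behavior", "report")`.
#' @return the output directory, invisibly; summary objects as attributes.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = tempfile("run"),
                        stages = c("simulate", "extract", "fit",
                                   "reliability", "behavior", "report")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    if (is.data.frame(x)) utils::write.csv(x, p, row.names = FALSE)
    else jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    files <<- c(files, name)
    p
  }

  scfg <- simConfig(group_sizes = config$sim$group_sizes,
                    n_blocks = config$sim$n_blocks, seed = config$seed)
  cohort <- simulateCohort(scfg)
  amps <- simulateTrialAmplitudes(cohort$trials, cohort$traits, cohort$truth,
                                  seed = config$seed + 1L)
  results <- list()
  if ("simulate" %in% stages) {
    writeTableTSV(cohort$trials, file.path(out_dir, "trials.tsv"))
    writeTableTSV(cohort$traits, file.path(out_dir, "traits.tsv"))
    writeTableTSV(amps, file.path(out_dir, "amplitudes.tsv"))
    files <- c(files, "trials.tsv", "traits.tsv", "amplitudes.tsv")
  }

  if ("extract" %in% stages && config$sim$eeg_subjects > 0L) {
    subjects <- utils::head(unique(cohort$trials$subject),
                            config$sim$eeg_subjects)
    extracted <- list()
    for (s in subjects) {
      tr <- cohort$trials[cohort$trials$subject == s, ]
      sim <- simulateRawEEG(tr, amps, seed = config$seed +
                              match(s, subjects))
      rec <- preprocessRecording(sim$recording,
                                 z_thresh = config$segments$z_thresh)
      ev <- evokedAverage(rec, tr, "CRN", span_s = config$epochs$span_s)
      extracted[[s]] <- extractResponseEpochs(rec, tr, ev, "CRN",
                                              config$epochs$epoch_s,
                                              config$epochs$baseline_s)
    }
    ga <- grandAverage(extracted, config$epochs$channel)
    win <- findComponentWindow(ga$mean, ga$times_ms,
                               config$epochs$search_ms,
                               config$epochs$half_width_ms)
    ext_amps <- amplitudeTable(extracted, win, cohort$trials,
                               config$epochs$channel)
    emit(ext_amps, "extracted_amplitudes.csv")
    emit(list(peak_ms = win$peak_ms, start_ms = win$start_ms,
              end_ms = win$end_ms), "component_window.json")
    results$window <- win
  }

  crit <- applyTrialCriteria(amps, cohort$trials,
                             config$criteria$min_error_trials,
                             config$criteria$fa_rate_thresh,
                             config$criteria$fa_min_blocks)
  crn <- crit$amps[crit$amps$kind == "CRN", ]
  design <- buildDesignMatrix(crn, cohort$traits)
  spec <- horseshoeSpec(config$model$p0, config$model$nu0, config$model$s)

  if ("fit" %in% stages) {
    fit <- fitHorseshoe(design, spec = spec, chains = config$model$chains,
                        warmup = config$model$warmup,
                        samples = config$model$samples,
                        fullSettings = config$model$full_settings,
                        seed = config$seed)
    diag <- diagnoseAndSummarize(fit)
    emit(diag$summary, "posterior_summary.csv")
    results$fit <- fit
    results$diagnostics <- diag
  }

  if ("reliability" %in% stages) {
    efit <- fitHorseshoe(design, spec = spec, extended = TRUE,
                         chains = config$model$chains,
                         warmup = config$model$warmup,
                         samples = config$model$samples,
                         seed = config$seed + 2L)
    report <- reliabilityReport(efit, design,
                                threshold = config$reliability$threshold,
                                S_grid = config$reliability$S_grid,
                                max_draws = config$reliability$max_draws)
    emit(report@subjects, "reliability_subjects.csv")
    emit(lapply(report@groups, function(g)
      c(as.list(attr(g, "components")), list(curve = g))),
      "reliability_groups.json")
    ret <- retainSubjects(report)
    emit(data.frame(subject = ret$retained), "retained_subjects.csv")
    results$reliability <- report
  }

  if ("behavior" %in% stages) {
    outcomes <- deriveOutcomes(cohort$trials, cohort$traits)
    preds <- behaviorPredictors(outcomes, cohort$traits)
    rrr <- fitReducedRank(outcomes, preds, seed = config$seed + 3L)
    emit(summarizeReducedRank(rrr), "behavior_rrr_summary.csv")
    emit(outcomes, "behavior_outcomes.csv")
    results$rrr <- rrr
  }

  if ("report" %in% stages) {
    emit(rtCrnCorrelations(crn)$by_condition, "rt_crn_correlations.csv")
    emit(binnedBehaviorSummary(cohort$trials, reps = 500L,
                               seed = config$seed + 4L),
         "binned_behavior.csv")
    emit(crit$exclusions, "exclusions.csv")
  }

  manifest <- list(config_hash = configHash(config), seed = config$seed,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(out_dir, "results") <- results
  invisible(out_dir)
}
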