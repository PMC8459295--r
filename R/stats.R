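#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param items respondents x items numeric matrix (>= 2 items).
#' @return the alpha coefficient.
#' @export
cronbachAlpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2L) stop("Cronbach's alpha needs at least 2 items")
  total_var <- stats::var(rowSums(items))
  if (!is.finite(total_var) || total_var == 0)
    stop("zero total-score variance: alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Cronbach's alpha with a percentile bootstrap interval
#'
#' Resamples respondents (rows) with replacement and reports the percentile
#' confidence interval of the alpha coefficient.
#'
#' @param items respondents x items numeric matrix (>= 3 respondents).
#' @param reps bootstrap repetitions (default 5000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list: `alpha`, `ci` (length-2), `reps`.
#' @export
cronbachAlphaBoot <- function(items, reps = 5000L, level = 0.95, seed = 1L) {
  items <- as.matrix(items)
  if (nrow(items) < 3L) stop("bootstrap needs at least 3 respondents")
  a <- cronbachAlpha(items)
  set.seed(seed)
  n <- nrow(items)
  boots <- vapply(seq_len(reps), function(r) {
    cronbachAlpha(items[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(1))
  alo <- (1 - level) / 2
  list(alpha = a,
       ci = unname(stats::quantile(boots, c(alo, 1 - alo), na.rm = TRUE)),
       reps = reps)
}

#' Per-subject response-time/amplitude correlations
#'
#' Pearson correlations between raw (unstandardized) response time and
#' amplitude within each subject, ignoring all other predictors, with
#' per-condition median and quartiles.
#'
#' @param amps amplitude table with `subject`, `condition`, `rt_s`,
#'   `amplitude_uV`.
#' @param min_trials subjects with fewer trials are flagged, not correlated.
#' @return list: `subjects` (data.frame `subject`, `condition`, `n`, `r`,
#'   `flagged`), `by_condition` (data.frame `condition`, `median_r`, `q25`,
#'   `q75`, `n_subjects`).
#' @export
rtCrnCorrelations <- function(amps, min_trials = 3L) {
  subjects <- sort(unique(amps$subject))
  rows <- lapply(subjects, function(s) {
    a <- amps[amps$subject == s, , drop = FALSE]
    n <- nrow(a)
    flagged <- n < min_trials || stats::sd(a$rt_s) == 0 ||
      stats::sd(a$amplitude_uV) == 0
    r <- if (flagged) NA_real_ else stats::cor(a$rt_s, a$amplitude_uV)
    data.frame(subject = s, condition = a$condition[1], n = n, r = r,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  subj <- do.call(rbind, rows)
  by_cond <- do.call(rbind, lapply(split(subj, subj$condition), function(g) {
    r <- g$r[!is.na(g$r)]
    data.frame(condition = g$condition[1],
               median_r = stats::median(r),
               q25 = unname(stats::quantile(r, 0.25)),
               q75 = unname(stats::quantile(r, 0.75)),
               n_subjects = length(r), stringsAsFactors = FALSE)
  }))
  rownames(by_cond) <- NULL
  list(subjects = subj, by_condition = by_cond)
}

#' Block-binned behavioral summaries with bootstrap intervals
#'
#' Pools blocks into bins (three successive blocks by default; a shorter
#' remainder bin is kept and flagged), then per condition and bin reports
#' the hit rate, correct-rejection rate and mean hit response time with
#' percentile-bootstrap confidence intervals over subjects.
#'
#' @param trials the cohort trial table.
#' @param bin_blocks blocks per bin.
#' @param reps bootstrap repetitions.
#' @param level confidence level.
#' @param seed integer seed.
#' @return data.frame: `condition`, `bin`, `blocks`, `partial`, `measure`,
#'   `mean`, `lo`, `hi`.
#' @export
binnedBehaviorSummary <- function(trials, bin_blocks = 3L, reps = 10000L,
                                  level = 0.95, seed = 1L) {
  n_blocks <- max(trials$block)
  bin_of <- (trials$block - 1L) %/% bin_blocks + 1L
  n_bins <- max(bin_of)
  partial <- tabulate(unique(cbind(bin_of, trials$block))[, 1],
                      nbins = n_bins) < bin_blocks
  trials$bin <- bin_of
  alo <- (1 - level) / 2
  set.seed(seed)

  out <- list()
  for (cond in unique(trials$condition)) {
    tc <- trials[trials$condition == cond, , drop = FALSE]
    subjects <- unique(tc$subject)
    for (b in seq_len(n_bins)) {
      tb <- tc[tc$bin == b, , drop = FALSE]
      if (!nrow(tb)) { warning("empty bin ", b, " in ", cond); next }
      per_subj <- t(vapply(subjects, function(s) {
        ts <- tb[tb$subject == s, , drop = FALSE]
        go <- ts[ts$type == "go", , drop = FALSE]
        nogo <- ts[ts$type == "nogo", , drop = FALSE]
        c(hit = mean(go$responded),
          cr = if (nrow(nogo)) mean(!nogo$responded) else NA,
          rt = mean(go$rt_s[go$responded], na.rm = TRUE))
      }, numeric(3)))
      for (meas in colnames(per_subj)) {
        v <- per_subj[, meas]
        bm <- vapply(seq_len(reps), function(r)
          mean(v[sample.int(length(v), replace = TRUE)], na.rm = TRUE),
          numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, bin = b,
          blocks = paste(range(tb$block), collapse = "-"),
          partial = partial[b], measure = meas,
          mean = mean(v, na.rm = TRUE),
          lo = unname(stats::quantile(bm, alo)),
          hi = unname(stats::quantile(bm, 1 - alo)),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
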