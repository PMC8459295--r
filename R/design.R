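#' Predictor column names of the trial-level design matrix
#'
#' Four standardized base predictors (response time, promotion strength,
#' prevention strength, miss-error count) plus every two- and three-way
#' interaction that does not involve both promotion and prevention,
#' giving exactly 11 columns.
#'
#' @return character vector of length 11.
#' @export
designColnames <- function() {
  c("rt", "prom", "prev", "errn",
    "rt:prom", "rt:prev", "rt:errn", "prom:errn", "prev:errn",
    "rt:prom:errn", "rt:prev:errn")
}

#' Build the standardized trial-level design matrix
#'
#' Base predictors (RT, promotion, prevention, per-subject miss count) are
#' z-scored over all trials in the analysis set; interaction columns are
#' elementwise products of the z-scored bases (not re-standardized).  The
#' outcome amplitude is z-scored over the same set.  The subject's miss
#' count is broadcast to all of that subject's trials.
#'
#' @param amps amplitude table: columns `subject`, `condition`, `rt_s`,
#'   `amplitude_uV` (rows are the analysis set, e.g. after exclusions).
#' @param traits trait table: columns `subject`, `promotion`, `prevention`,
#'   `miss_count`.
#' @param standardizeOutcome z-score the amplitude outcome (set `FALSE` when
#'   only the predictor matrix is needed, e.g. inside the simulator).
#' @return list of class `erpDesign`: `X` (trials x 11 matrix), `y`
#'   (z-scored amplitude), `cond`/`subj` (1-based indices), `conditions`,
#'   `subjects`, `rt_z` (the standardized RT column), `scaling` (means/sds
#'   used, for mapping back to original units).
#' @export
buildDesignMatrix <- function(amps, traits, standardizeOutcome = TRUE) {
  need <- c("subject", "condition", "rt_s", "amplitude_uV")
  if (!all(need %in% names(amps)))
    stop("amps must have columns: ", paste(need, collapse = ", "))
  ti <- match(amps$subject, traits$subject)
  if (anyNA(ti))
    stop("every trial's subject needs a row in the trait table")
  for (col in c("promotion", "prevention", "miss_count"))
    if (!col %in% names(traits)) stop("traits must have column ", col)

  zscore <- function(x, what) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("zero variance in base predictor '", what, "': cannot standardize")
    (x - mean(x)) / s
  }
  base <- cbind(
    rt = zscore(amps$rt_s, "rt"),
    prom = zscore(traits$promotion[ti], "prom"),
    prev = zscore(traits$prevention[ti], "prev"),
    errn = zscore(as.numeric(traits$miss_count[ti]), "errn")
  )
  X <- cbind(base,
             "rt:prom" = base[, "rt"] * base[, "prom"],
             "rt:prev" = base[, "rt"] * base[, "prev"],
             "rt:errn" = base[, "rt"] * base[, "errn"],
             "prom:errn" = base[, "prom"] * base[, "errn"],
             "prev:errn" = base[, "prev"] * base[, "errn"],
             "rt:prom:errn" = base[, "rt"] * base[, "prom"] * base[, "errn"],
             "rt:prev:errn" = base[, "rt"] * base[, "prev"] * base[, "errn"])
  colnames(X) <- designColnames()

  conditions <- condLevels()[condLevels() %in% unique(amps$condition)]
  if (!length(conditions)) conditions <- sort(unique(amps$condition))
  subjects <- sort(unique(amps$subject))
  ymu <- mean(amps$amplitude_uV); ysd <- stats::sd(amps$amplitude_uV)
  if (standardizeOutcome && (!is.finite(ysd) || ysd == 0))
    stop("zero variance in outcome amplitude")

  structure(list(
    X = X,
    y = if (standardizeOutcome) (amps$amplitude_uV - ymu) / ysd
        else amps$amplitude_uV,
    cond = match(amps$condition, conditions),
    subj = match(amps$subject, subjects),
    conditions = conditions,
    subjects = subjects,
    rt_z = X[, "rt"],
    scaling = list(y_mean = ymu, y_sd = ysd,
                   rt_mean = mean(amps$rt_s), rt_sd = stats::sd(amps$rt_s))
  ), class = "erpDesign")
}

#' Global-shrinkage reference scale of the regularized horseshoe
#'
#' Computes `tau0 = p0 / (P C - p0) * sigma_g / sqrt(N)`, the half-Cauchy
#' prior scale of the global shrinkage parameter given the expected number
#' of non-zero coefficients `p0` among the `P x C` coefficients and `N`
#' trials.
#'
#' @param p0 expected number of non-zero coefficients.
#' @param P predictors per condition.
#' @param C number of conditions.
#' @param sigma_g residual scale.
#' @param N total number of trials.
#' @return the scale tau0.
#' @examples
#' computeTau0(p0 = 9, P = 11, C = 3, sigma_g = 1, N = 1)  # 9/24 = 0.375
#' @export
computeTau0 <- function(p0, P, C, sigma_g, N) {
  if (N <= 0) stop("N must be positive")
  if (p0 >= P * C) stop("p0 must be below the total coefficient count P*C")
  p0 / (P * C - p0) * sigma_g / sqrt(N)
}
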