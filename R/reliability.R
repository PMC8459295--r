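## population-style variance (divide by n): matches a draw-wise
## deterministic transform of the posterior sample
popVar <- function(x) mean((x - mean(x))^2)

## predicted values for one posterior draw of the extended model
drawPredictions <- function(fit, design, it, ch) {
  B <- fit@draws$B[it, ch, , ]
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  fixed <- rowSums(design$X * B[design$cond, , drop = FALSE])
  I <- fit@draws$I[it, ch, ]
  subj_part <- I[design$subj]
  if (fit@extended) {
    b <- fit@draws$b[it, ch, ]
    subj_part <- subj_part + b[design$subj] * design$rt_z
  }
  list(fixed = fixed, subj = subj_part, yhat = fixed + subj_part)
}

## iterate over a thinned set of (iteration, chain) draw indices
drawIndex <- function(fit, max_draws) {
  total <- fit@samples * fit@chains
  use <- min(max_draws, total)
  sel <- unique(round(seq(1, total, length.out = use)))
  data.frame(it = ((sel - 1L) %% fit@samples) + 1L,
             ch = ((sel - 1L) %/% fit@samples) + 1L)
}

#' Subject-level internal consistency
#'
#' For each posterior draw of the extended model, the subject's true-score
#' variance `sigma_m^2 = Var(Yhat)` over that subject's trials and residual
#' variance `sigma_e^2 = Var(Y - Yhat)` give the internal-consistency
#' coefficient `phi_j = sigma_m^2 / (sigma_m^2 + sigma_e^2 / n_j)`; the
#' draw-wise coefficients are summarized by their mean and central 95%
#' interval.
#'
#' @param fit an extended-model [PosteriorFit-class].
#' @param design the `erpDesign` the model was fit to.
#' @param y outcome vector (defaults to `design$y`).
#' @param max_draws number of posterior draws used (thinned evenly).
#' @return data.frame: `subject`, `n_trials`, `sigma_m2`, `sigma_e2`
#'   (posterior means), `phi`, `phi_lo`, `phi_hi`, `flagged` (TRUE when
#'   `n_trials < 2` leaves phi undefined).
#' @export
subjectInternalConsistency <- function(fit, design, y = design$y,
                                       max_draws = 400L) {
  if (!fit@extended)
    stop("internal consistency requires the extended (random-RT-slope) fit")
  J <- length(design$subjects)
  idx <- drawIndex(fit, max_draws)
  jsplit <- split(seq_along(design$subj), design$subj)
  n_j <- lengths(jsplit)[as.character(seq_len(J))]
  n_j[is.na(n_j)] <- 0L

  phis <- matrix(NA_real_, nrow(idx), J)
  sm2 <- se2 <- matrix(NA_real_, nrow(idx), J)
  for (d in seq_len(nrow(idx))) {
    pr <- drawPredictions(fit, design, idx$it[d], idx$ch[d])
    res <- y - pr$yhat
    for (j in seq_len(J)) {
      jj <- jsplit[[as.character(j)]]
      if (length(jj) < 2L) next
      sm2[d, j] <- popVar(pr$yhat[jj])
      se2[d, j] <- popVar(res[jj])
      phis[d, j] <- sm2[d, j] / (sm2[d, j] + se2[d, j] / length(jj))
    }
  }
  data.frame(
    subject = design$subjects,
    n_trials = as.integer(n_j),
    sigma_m2 = colMeans(sm2),
    sigma_e2 = colMeans(se2),
    phi = colMeans(phis),
    phi_lo = apply(phis, 2, function(x) unname(stats::quantile(x, 0.025,
                                                               na.rm = TRUE))),
    phi_hi = apply(phis, 2, function(x) unname(stats::quantile(x, 0.975,
                                                               na.rm = TRUE))),
    flagged = n_j < 2L,
    stringsAsFactors = FALSE
  )
}

#' Group-level fixed-effects dependability curves
#'
#' Per condition and posterior draw, the variance of the fixed-effect
#' predictions `sigma_G^2 = Var(B_i' x_k)`, the subject-level variance
#' `sigma_s^2 = Var(b_j rt_k + I_j)` and the residual variance
#' `sigma_e^2 = Var(Y - Yhat)` give the dependability of group-level
#' estimates as a function of the number of subjects `S`:
#' `phi_G(S) = sigma_G^2 / (sigma_G^2 + (sigma_s^2 + sigma_e^2 / n_hat) / S)`,
#' where `n_hat` is the harmonic-mean trial count per subject in the group.
#'
#' @param fit an extended-model [PosteriorFit-class].
#' @param design the `erpDesign` the model was fit to.
#' @param y outcome vector.
#' @param S_grid subject counts at which to evaluate the curve.
#' @param max_draws number of posterior draws used.
#' @return named list (one element per condition): data.frame `S`, `phi`,
#'   `phi_lo`, `phi_hi`, with attribute `components` (posterior-mean
#'   `sigma_G2`, `sigma_s2`, `sigma_e2`, `n_hat`).  Conditions with no
#'   trials are skipped with a warning.
#' @export
fixedEffectsDependability <- function(fit, design, y = design$y,
                                      S_grid = c(5, 10, 15, 20, 26, 30, 35,
                                                 40, 50, 75, 100),
                                      max_draws = 400L) {
  if (!fit@extended)
    stop("dependability requires the extended (random-RT-slope) fit")
  idx <- drawIndex(fit, max_draws)
  out <- list()
  for (i in seq_along(design$conditions)) {
    cname <- design$conditions[i]
    ii <- which(design$cond == i)
    if (!length(ii)) {
      warning("condition ", cname, " has no trials; skipped")
      next
    }
    nh <- 1 / mean(1 / table(design$subj[ii]))     # harmonic mean trials
    curves <- array(NA_real_, c(nrow(idx), length(S_grid)))
    comp <- matrix(NA_real_, nrow(idx), 3)
    for (d in seq_len(nrow(idx))) {
      pr <- drawPredictions(fit, design, idx$it[d], idx$ch[d])
      sG2 <- popVar(pr$fixed[ii])
      ss2 <- popVar(pr$subj[ii])
      se2 <- popVar((y - pr$yhat)[ii])
      comp[d, ] <- c(sG2, ss2, se2)
      curves[d, ] <- sG2 / (sG2 + (ss2 + se2 / nh) / S_grid)
    }
    df <- data.frame(
      S = S_grid,
      phi = colMeans(curves),
      phi_lo = apply(curves, 2, stats::quantile, 0.025, names = FALSE),
      phi_hi = apply(curves, 2, stats::quantile, 0.975, names = FALSE)
    )
    attr(df, "components") <- c(sigma_G2 = mean(comp[, 1]),
                                sigma_s2 = mean(comp[, 2]),
                                sigma_e2 = mean(comp[, 3]), n_hat = nh)
    out[[cname]] <- df
  }
  out
}

#' Assemble a reliability report
#'
#' @param fit an extended-model [PosteriorFit-class].
#' @param design the `erpDesign` the model was fit to.
#' @param y outcome vector.
#' @param threshold retention threshold on subject internal consistency.
#' @param S_grid subject counts for the dependability curves.
#' @param max_draws posterior draws used for both analyses.
#' @return a [ReliabilityReport-class].
#' @export
reliabilityReport <- function(fit, design, y = design$y, threshold = 0.8,
                              S_grid = c(5, 10, 15, 20, 26, 30, 35, 40, 50,
                                         75, 100),
                              max_draws = 400L) {
  subj <- subjectInternalConsistency(fit, design, y, max_draws)
  cond_of <- vapply(seq_along(design$subjects), function(j) {
    design$conditions[design$cond[match(j, design$subj)]]
  }, character(1))
  subj$condition <- cond_of
  grp <- fixedEffectsDependability(fit, design, y, S_grid, max_draws)
  new("ReliabilityReport", subjects = subj, groups = grp,
      threshold = threshold)
}

#' Retain subjects by internal consistency
#'
#' Subjects whose posterior-mean internal consistency falls below the
#' threshold (default .8) are excluded from the final model.
#'
#' @param report a [ReliabilityReport-class] (or the subject data.frame).
#' @param threshold retention threshold; defaults to the report's.
#' @return list: `retained` (character vector), `excluded` (data.frame
#'   `subject`, `phi`).
#' @export
retainSubjects <- function(report, threshold = NULL) {
  s <- if (is(report, "ReliabilityReport")) report@subjects else report
  if (is.null(threshold))
    threshold <- if (is(report, "ReliabilityReport")) report@threshold else 0.8
  low <- !is.na(s$phi) & s$phi < threshold
  list(retained = s$subject[!low],
       excluded = data.frame(subject = s$subject[low], phi = s$phi[low],
                             stringsAsFactors = FALSE))
}
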