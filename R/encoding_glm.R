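#' Design matrix for the outcome x time Poisson GLM
#'
#' Predictors: an intercept, the trial outcome coded water = 0 / sucrose = 1,
#' the trial number (a proxy for elapsed time, entered untransformed), and
#' their interaction. With this coding a positive interaction coefficient
#' means the time slope for sucrose exceeds the time slope for water.
#'
#' @param outcomes character vector, `"sucrose"` or `"water"`.
#' @param trial_numbers integer vector, same length.
#' @return list: `X` (n x 4 matrix with columns `(Intercept)`, `outcome`,
#'   `time`, `outcome_time`), `rank_deficient` (logical), `collinear`
#'   (names of degenerate columns, if any).
#' @export
build_design <- function(outcomes, trial_numbers) {
  if (length(outcomes) != length(trial_numbers))
    stop("outcomes and trial_numbers must have equal length")
  bad <- setdiff(unique(outcomes), c("sucrose", "water"))
  if (length(bad))
    stop("outcomes must be 'sucrose' or 'water'; got: ",
         paste(bad, collapse = ", "))
  o <- as.numeric(outcomes == "sucrose")
  X <- cbind(`(Intercept)` = 1, outcome = o, time = trial_numbers,
             outcome_time = o * trial_numbers)
  qr_rank <- qr(X)$rank
  collinear <- character(0)
  if (qr_rank < ncol(X)) {
    # name columns with no variation (the usual cause: single-outcome data)
    v <- apply(X[, -1, drop = FALSE], 2, function(col) stats::var(col) == 0)
    collinear <- names(v)[v]
    if (!length(collinear)) collinear <- "unknown (general collinearity)"
  }
  list(X = X, rank_deficient = qr_rank < ncol(X), collinear = collinear)
}

#' Fit the per-neuron Poisson GLM on forced-trial window counts
#'
#' Log-link Poisson regression of unsmoothed window spike counts on outcome,
#' time (trial number) and outcome x time, fitted by iteratively reweighted
#' least squares to convergence. Per-coefficient two-sided Wald p-values are
#' reported, along with a deviance-based pseudo-R-squared
#' (1 - residual deviance / null deviance).
#'
#' @param counts non-negative integer window counts.
#' @param outcomes,trial_numbers per-trial predictors (see
#'   [build_design()]).
#' @param neuron_id,window labels carried into the result.
#' @return list of class `glm_fit`: `coefficients`, `p_values`,
#'   `pseudo_r2`, `n_trials`, `converged`, `neuron_id`, `window`.
#' @export
fit_poisson_glm <- function(counts, outcomes, trial_numbers,
                            neuron_id = NA_character_,
                            window = NA_character_) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  d <- build_design(outcomes, trial_numbers)
  if (d$rank_deficient)
    stop("design is rank deficient; degenerate columns: ",
         paste(d$collinear, collapse = ", "))
  df <- data.frame(count = counts,
                   outcome = d$X[, "outcome"],
                   time = d$X[, "time"])
  fit <- stats::glm(count ~ outcome * time, family = stats::poisson(),
                    data = df,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  sm <- summary(fit)$coefficients
  cf <- stats::setNames(sm[, "Estimate"],
                        c("intercept", "outcome", "time", "outcome_time"))
  pv <- stats::setNames(sm[, "Pr(>|z|)"],
                        c("intercept", "outcome", "time", "outcome_time"))
  structure(list(coefficients = cf, p_values = pv,
                 pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
                 n_trials = length(counts), converged = fit$converged,
                 neuron_id = neuron_id, window = window),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> neuron ", x$neuron_id, " (", x$window, " window), ",
      x$n_trials, " trials, pseudo-R2 = ", signif(x$pseudo_r2, 3),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  tab <- data.frame(estimate = signif(x$coefficients, 4),
                    p = signif(x$p_values, 3))
  print(tab)
  invisible(x)
}

#' Classify a neuron from its GLM fit
#'
#' A predictor is flagged significant when its Wald p-value falls below
#' `cutoff` (default 0.05, uncorrected, per neuron). A neuron counts as an
#' "outcome x time" neuron when the interaction is significant AND its
#' coefficient is positive — i.e. its time slope is more positive for
#' sucrose than for water, the direction in which activity tracks the
#' session-long shift toward sucrose.
#'
#' @param fit a `glm_fit`.
#' @param cutoff significance cutoff (default 0.05).
#' @return list of class `neuron_class`: `sig` (named logical per
#'   predictor), `outcome_time_positive`, `outcome_time_neuron`.
#' @export
classify_neuron <- function(fit, cutoff = 0.05) {
  sig <- fit$p_values[c("outcome", "time", "outcome_time")] < cutoff
  pos <- unname(fit$coefficients["outcome_time"] > 0)
  structure(list(sig = sig,
                 outcome_time_positive = pos,
                 outcome_time_neuron = unname(sig["outcome_time"]) && pos),
            class = "neuron_class")
}

#' Chi-squared comparison of classified-neuron proportions
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the 2 x 2
#' table of classified / unclassified neurons in two tasks or windows.
#'
#' @param count_a,n_a classified count and total in group A.
#' @param count_b,n_b classified count and total in group B.
#' @return list: `statistic`, `p_value`, `proportions`.
#' @export
proportion_comparison <- function(count_a, n_a, count_b, n_b) {
  if (count_a > n_a || count_b > n_b)
    stop("counts cannot exceed totals")
  tab <- matrix(c(count_a, n_a - count_a, count_b, n_b - count_b),
                nrow = 2,
                dimnames = list(c("classified", "other"), c("A", "B")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared test undefined: zero margin in the 2x2 table")
  ts <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ts$statistic), p_value = ts$p.value,
       proportions = c(A = count_a / n_a, B = count_b / n_b))
}

#' GLM classification of every neuron in a session
#'
#' Runs [extract_counts()], [fit_poisson_glm()] and [classify_neuron()] for
#' each neuron in one analysis window. Forced trials are used; the reward
#' window additionally requires the animal in the port at delivery (the
#' standard inclusion rule); the cue window does not.
#'
#' @param session a `vp_session`.
#' @param window `"cue"` or `"reward"`.
#' @param cutoff significance cutoff.
#' @return data.frame, one row per neuron: coefficients, p-values,
#'   pseudo-R2, significance flags and the outcome x time classification.
#' @export
classify_session <- function(session, window = c("reward", "cue"),
                             cutoff = 0.05) {
  window <- match.arg(window)
  rows <- lapply(names(session$spikes), function(nid) {
    cm <- extract_counts(session, nid, window)
    fit <- tryCatch(
      fit_poisson_glm(cm$counts, cm$outcomes, cm$trial_numbers,
                      neuron_id = nid, window = window),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(neuron_id = nid, window = window,
                        b_intercept = NA_real_, b_outcome = NA_real_,
                        b_time = NA_real_, b_outcome_time = NA_real_,
                        p_outcome = NA_real_, p_time = NA_real_,
                        p_outcome_time = NA_real_, pseudo_r2 = NA_real_,
                        converged = FALSE, sig_outcome = NA,
                        sig_time = NA, sig_outcome_time = NA,
                        outcome_time_neuron = NA))
    }
    cl <- classify_neuron(fit, cutoff)
    data.frame(neuron_id = nid, window = window,
               b_intercept = unname(fit$coefficients["intercept"]),
               b_outcome = unname(fit$coefficients["outcome"]),
               b_time = unname(fit$coefficients["time"]),
               b_outcome_time = unname(fit$coefficients["outcome_time"]),
               p_outcome = unname(fit$p_values["outcome"]),
               p_time = unname(fit$p_values["time"]),
               p_outcome_time = unname(fit$p_values["outcome_time"]),
               pseudo_r2 = fit$pseudo_r2,
               converged = fit$converged,
               sig_outcome = unname(cl$sig["outcome"]),
               sig_time = unname(cl$sig["time"]),
               sig_outcome_time = unname(cl$sig["outcome_time"]),
               outcome_time_neuron = cl$outcome_time_neuron)
  })
  do.call(rbind, rows)
}
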