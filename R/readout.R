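#' Logistic fit to the session's choice behavior
#'
#' Fits `L(t) = 1 / (1 + exp(-k (t - t0)))` by nonlinear least squares to
#' the raw 0/1 choice sequence (water = 0, sucrose = 1) over the session's
#' choice trials, giving the behavioral estimates of preference steepness
#' and indifference point, with asymptotic standard errors.
#'
#' @param session a `vp_session`.
#' @param min_choices minimum number of recorded choices required.
#' @return list of class `behavior_logistic`: `k`, `t0`, `se_k`, `se_t0`,
#'   `curve` (fitted L(t) over all trials 1..t_end), `n_choices`,
#'   `identifiable`, `extrapolated` (TRUE when t0 falls outside
#'   [1, t_end]).
#' @export
fit_behavioral_logistic <- function(session, min_choices = 10) {
  tr <- session$trials
  ch <- which(tr$trial_type == "choice" & !is.na(tr$chosen))
  if (length(ch) < min_choices)
    stop("need at least ", min_choices, " choice trials with choices")
  t <- tr$trial_number[ch]
  y <- as.numeric(tr$chosen[ch] == "sucrose")
  t_end <- nrow(tr)
  if (length(unique(y)) == 1) {
    return(structure(list(k = NA_real_, t0 = NA_real_, se_k = NA_real_,
                          se_t0 = NA_real_,
                          curve = rep(mean(y), t_end),
                          n_choices = length(y), identifiable = FALSE,
                          extrapolated = NA),
                     class = "behavior_logistic"))
  }
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(-k * (t - t0))), data = df,
                      start = list(k = 0.1, t0 = stats::median(t)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to direct least squares on the same objective
    obj <- function(th) sum((y - 1 / (1 + exp(-th[1] * (t - th[2]))))^2)
    op <- stats::optim(c(0.1, stats::median(t)), obj, method = "Nelder-Mead")
    k <- op$par[1]; t0 <- op$par[2]; se <- c(NA_real_, NA_real_)
  } else {
    cf <- summary(fit)$coefficients
    k <- cf["k", "Estimate"]; t0 <- cf["t0", "Estimate"]
    se <- cf[, "Std. Error"]
  }
  curve <- 1 / (1 + exp(-k * (seq_len(t_end) - t0)))
  structure(list(k = k, t0 = t0, se_k = unname(se[1]),
                 se_t0 = unname(se[2]), curve = curve,
                 n_choices = length(y), identifiable = TRUE,
                 extrapolated = t0 < 1 || t0 > t_end),
            class = "behavior_logistic")
}

#' @export
print.behavior_logistic <- function(x, ...) {
  if (!x$identifiable) {
    cat("<behavior_logistic> non-identifiable (all choices identical)\n")
    return(invisible(x))
  }
  cat("<behavior_logistic> k = ", signif(x$k, 4), " +/- ",
      signif(x$se_k, 3), ", t0 = ", signif(x$t0, 5), " +/- ",
      signif(x$se_t0, 3), " trials (n = ", x$n_choices, " choices)",
      if (x$extrapolated) " [t0 extrapolated]", "\n", sep = "")
  invisible(x)
}

#' Neural estimate of behavioral preference from a mixed-model fit
#'
#' The logistic parameters (k, t0) recovered by fitting the mixed
#' (satiety-weighted preference) model to one neuron's reward activity
#' define that neuron's estimate of the session's preference trajectory:
#' the session-normalized logistic over trials 1..t_end. The fitted t0 is
#' the neuron's estimate of the indifference point.
#'
#' @param fit an `scm_fit` for the mixed model.
#' @param t_end total trials (default: from the fit).
#' @return list of class `neural_preference`: `neuron curve` in [0, 1]
#'   (`curve`), `indifference` (= fitted t0), `low_confidence` (TRUE when
#'   the fit ended on a parameter bound), `satiety_dominated` (TRUE when
#'   the fitted w is 0).
#' @export
neural_preference <- function(fit, t_end = fit$t_end) {
  if (!inherits(fit, "scm_fit") || fit$model != "mixed")
    stop("neural_preference requires a mixed-model scm_fit")
  p <- fit$params
  curve <- pref_covariate(p$k, p$t0, t_end)
  structure(list(curve = curve, indifference = p$t0,
                 k = p$k,
                 low_confidence = any(fit$at_bound),
                 satiety_dominated = isTRUE(p$w <= 1e-6)),
            class = "neural_preference")
}

#' Agreement between neural and behavioral preference estimates
#'
#' For each neuron, the Spearman rank correlation between its preference
#' curve and the behavioral logistic curve over trials 1..t_end (unit
#' spacing), and the absolute difference between its indifference point and
#' the behavioral one. A constant curve has no defined rank correlation and
#' yields `NA`.
#'
#' @param estimates list of `neural_preference` objects (optionally named
#'   by neuron).
#' @param behavior_fit a `behavior_logistic`.
#' @return data.frame: `neuron_id`, `rho`, `delta_indifference`.
#' @export
neuron_behavior_agreement <- function(estimates, behavior_fit) {
  ids <- names(estimates) %||% as.character(seq_along(estimates))
  bcurve <- behavior_fit$curve
  rows <- lapply(seq_along(estimates), function(i) {
    est <- estimates[[i]]
    rho <- if (stats::sd(est$curve) == 0 || stats::sd(bcurve) == 0)
      NA_real_
    else suppressWarnings(stats::cor(est$curve, bcurve,
                                     method = "spearman"))
    data.frame(neuron_id = ids[i], rho = rho,
               delta_indifference = abs(est$indifference - behavior_fit$t0))
  })
  do.call(rbind, rows)
}

#' Spearman correlation between reward activity and preference
#'
#' Correlates a neuron's reward-window spike counts on forced trials of one
#' outcome with the behavioral preference for that outcome: sucrose trials
#' against p(t) and water trials against 1 - p(t).
#'
#' @param counts a `count_matrix` (reward window).
#' @param preference a `preference_curve` from [smoothed_preference()].
#' @param outcome `"sucrose"` or `"water"`.
#' @param min_trials minimum forced trials required (default 5).
#' @return Spearman rho, or `NA` when the counts are constant.
#' @export
firing_preference_correlation <- function(counts, preference, outcome,
                                          min_trials = 5) {
  sel <- counts$outcomes == outcome
  if (sum(sel) < min_trials)
    stop("need at least ", min_trials, " forced ", outcome, " trials")
  p <- preference$p[match(counts$trial_numbers[sel],
                          preference$trial_number)]
  if (outcome == "water") p <- 1 - p
  cc <- counts$counts[sel]
  if (stats::sd(cc) == 0 || stats::sd(p) == 0) return(NA_real_)
  suppressWarnings(stats::cor(cc, p, method = "spearman"))
}

#' Spearman correlation between cue activity and press latency
#'
#' Correlates cue-window spike counts with natural-log lever-press latency
#' across all trials (forced and choice) on which both are defined.
#'
#' @param counts a `count_matrix` (cue window, all trial types).
#' @param latencies data.frame from [log_latency()].
#' @param min_trials minimum trials required (default 5).
#' @return Spearman rho, or `NA` when either input is constant.
#' @export
cue_latency_correlation <- function(counts, latencies, min_trials = 5) {
  m <- match(counts$trial_numbers, latencies$trial_number)
  ok <- !is.na(m)
  if (sum(ok) < min_trials)
    stop("need at least ", min_trials, " trials with both quantities")
  cc <- counts$counts[ok]
  ll <- latencies$log_latency[m[ok]]
  if (stats::sd(cc) == 0 || stats::sd(ll) == 0) return(NA_real_)
  suppressWarnings(stats::cor(cc, ll, method = "spearman"))
}

#' Wilcoxon rank-sum contrast between two neuron groups
#'
#' Two-sided two-sample rank-sum test, used to compare agreement statistics
#' (or correlations) between outcome x time neurons and the remaining
#' population.
#'
#' @param values_a,values_b numeric vectors (NAs dropped).
#' @return list: `statistic` (rank-sum W), `p_value`, `n_a`, `n_b`.
#' @export
group_contrast <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b))
}
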