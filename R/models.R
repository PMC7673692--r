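#' Spike-count model families
#'
#' Five Poisson spike-count models describe how a neuron's reward-window
#' spike count evolves over a session in which the animal's preference
#' between sucrose and water shifts with satiety:
#'
#' \describe{
#'   \item{unmodulated}{constant rate equal to the mean count across trials,
#'     \eqn{s(t) \sim Poisson(\bar{s})}; no free parameters.}
#'   \item{satiety}{a linear decline in motivation,
#'     \eqn{Sat(t) = 1 - t/t_{end}}, driving a log-linear rate
#'     \eqn{\lambda(t) = \exp(a \cdot Sat(t) + b)}; free parameters (a, b).}
#'   \item{preference}{a logistic in trial number,
#'     \eqn{L(t) = 1/(1+e^{-k(t - t_0)})}, min-max normalized to [0, 1]
#'     across all trials 1..t_end of the session, inverted (1 - value) on
#'     water trials; \eqn{\lambda(t) = \exp(a \cdot Pref(t) + b)}; free
#'     parameters (a, b, k, t0).}
#'   \item{mixed}{satiety-weighted preference
#'     \eqn{SWP(t) = w \cdot Pref(t) + (1-w) \cdot Sat(t)};
#'     \eqn{\lambda(t) = \exp(a \cdot SWP(t) + b)}; free parameters
#'     (a, b, k, t0, w).}
#'   \item{licks}{an alternative in which the per-trial total lick count,
#'     min-max normalized over included trials, predicts the rate; free
#'     parameters (a, b).}
#' }
#'
#' The gain `a` is constrained positive in all models that have it, so each
#' covariate is read as a value-like signal the neuron tracks positively.
#'
#' @name spike_count_models
#' @keywords internal
NULL

model_names <- c("unmodulated", "satiety", "preference", "mixed", "licks")

free_params <- function(model) {
  switch(model,
         unmodulated = character(0),
         satiety = c("a", "b"),
         preference = c("a", "b", "k", "t0"),
         mixed = c("a", "b", "k", "t0", "w"),
         licks = c("a", "b"),
         stop("unknown model: ", model))
}

# Session-normalized preference covariate on the sucrose convention:
# logistic over all trials 1..t_end, min-max normalized to [0,1].
# Water trials use 1 - value.
pref_covariate <- function(k, t0, t_end) {
  t_all <- seq_len(t_end)
  L <- 1 / (1 + exp(-k * (t_all - t0)))
  rng <- range(L)
  if (diff(rng) < 1e-12) return(rep(0.5, t_end))
  (L - rng[1]) / (rng[2] - rng[1])
}

sat_covariate <- function(t_end) 1 - seq_len(t_end) / t_end

#' Expected spike count per trial under a spike-count model
#'
#' Evaluates the model rate \eqn{\lambda(t)} (expected spikes in the analysis
#' window) for each requested trial. The preference covariate is computed
#' over the full session range `1..t_end` and then indexed at the requested
#' trials, so sucrose and water trials share a single session-wide curve.
#'
#' @param model one of `"unmodulated"`, `"satiety"`, `"preference"`,
#'   `"mixed"`, `"licks"`.
#' @param params named list/vector: `a`, `b` and, as the model requires, `k`,
#'   `t0`, `w`, `sbar`; the licks model additionally needs `lick_norm`, the
#'   normalized per-trial lick counts aligned with `trial_numbers`.
#' @param trial_numbers integer trials in `1..t_end`.
#' @param outcomes character, `"sucrose"` or `"water"` per trial (any
#'   non-sucrose label is treated as the to-be-inverted outcome).
#' @param t_end total number of completed trials in the session.
#' @return numeric vector of rates, one per trial.
#' @export
model_rate <- function(model, params, trial_numbers, outcomes, t_end) {
  model <- match.arg(model, model_names)
  p <- as.list(params)
  if (any(trial_numbers < 1 | trial_numbers > t_end))
    stop("trial_numbers must lie in 1..t_end")
  n <- length(trial_numbers)
  switch(model,
    unmodulated = rep(p$sbar, n),
    satiety = {
      sat <- sat_covariate(t_end)[trial_numbers]
      exp(p$a * sat + p$b)
    },
    preference = {
      pref <- pref_covariate(p$k, p$t0, t_end)[trial_numbers]
      pref <- ifelse(outcomes == "sucrose", pref, 1 - pref)
      exp(p$a * pref + p$b)
    },
    mixed = {
      pref <- pref_covariate(p$k, p$t0, t_end)[trial_numbers]
      pref <- ifelse(outcomes == "sucrose", pref, 1 - pref)
      sat <- sat_covariate(t_end)[trial_numbers]
      swp <- p$w * pref + (1 - p$w) * sat
      exp(p$a * swp + p$b)
    },
    licks = {
      if (is.null(p$lick_norm) || length(p$lick_norm) != n)
        stop("licks model requires lick_norm aligned with trial_numbers")
      exp(p$a * p$lick_norm + p$b)
    })
}

#' Negative Poisson log-likelihood of a spike-count model
#'
#' \eqn{-\sum_t \log P(s(t) | \lambda(t))} with Poisson observation model and
#' rates from [model_rate()]. Returns `Inf` (not an error) when a zero rate
#' meets a positive count.
#'
#' @inheritParams model_rate
#' @param counts non-negative integer spike counts aligned with
#'   `trial_numbers`.
#' @return scalar negative log-likelihood.
#' @export
neg_loglik <- function(model, params, counts, trial_numbers, outcomes, t_end) {
  if (length(counts) == 0) return(0)
  lam <- model_rate(model, params, trial_numbers, outcomes, t_end)
  ll <- stats::dpois(counts, lam, log = TRUE)
  if (any(!is.finite(ll))) return(Inf)
  -sum(ll)
}

# Objective and analytic gradient for the constrained MLE. The negative
# log-likelihood is Sum(lambda - c * log lambda) + const with
# log lambda = a * X(t; k, t0, w) + b, so the gradient is
# Sum((lambda - c) * d log lambda / d theta). The normalized preference
# covariate N(t) = (L(t) - L(1)) / (L(t_end) - L(1)) is differentiated
# through the normalization (k > 0 makes L increasing, so the session
# extremes sit at t = 1 and t = t_end). log-rates are clamped at +/-50 to
# keep the objective finite for extreme offsets.
make_objective <- function(model, counts, trial_numbers, outcomes, t_end,
                           lick_norm = NULL) {
  pn <- free_params(model)
  sgn <- ifelse(outcomes == "sucrose", 1, -1)  # water inverts the covariate
  sat <- sat_covariate(t_end)[trial_numbers]
  tt <- trial_numbers

  pref_parts <- function(k, t0) {
    # normalized covariate and its k/t0 derivatives at the fitted trials
    Lf <- function(t) 1 / (1 + exp(-k * (t - t0)))
    L <- Lf(tt); L1 <- Lf(1); LE <- Lf(t_end)
    den <- LE - L1
    if (abs(den) < 1e-12) {
      z <- numeric(length(tt))
      return(list(N = rep(0.5, length(tt)), dk = z, dt0 = z))
    }
    dLk <- function(t, L) (t - t0) * L * (1 - L)
    dLt0 <- function(L) -k * L * (1 - L)
    N <- (L - L1) / den
    dk <- ((dLk(tt, L) - dLk(1, L1)) - N * (dLk(t_end, LE) - dLk(1, L1))) /
      den
    dt0 <- ((dLt0(L) - dLt0(L1)) - N * (dLt0(LE) - dLt0(L1))) / den
    list(N = N, dk = dk, dt0 = dt0)
  }

  covariate <- function(theta) {
    p <- as.list(theta); names(p) <- pn
    switch(model,
      satiety = list(X = sat, dX = NULL),
      licks = list(X = lick_norm, dX = NULL),
      preference = {
        pp <- pref_parts(p$k, p$t0)
        Ns <- ifelse(sgn > 0, pp$N, 1 - pp$N)
        list(X = Ns, dX = list(k = sgn * pp$dk, t0 = sgn * pp$dt0))
      },
      mixed = {
        pp <- pref_parts(p$k, p$t0)
        Ns <- ifelse(sgn > 0, pp$N, 1 - pp$N)
        list(X = p$w * Ns + (1 - p$w) * sat,
             dX = list(k = p$w * sgn * pp$dk, t0 = p$w * sgn * pp$dt0,
                       w = Ns - sat))
      })
  }

  fn <- function(theta) {
    p <- as.list(theta); names(p) <- pn
    cv <- covariate(theta)
    eta <- pmin(pmax(p$a * cv$X + p$b, -50), 50)
    lam <- exp(eta)
    sum(lam - counts * eta)
  }
  gr <- function(theta) {
    p <- as.list(theta); names(p) <- pn
    cv <- covariate(theta)
    eta <- pmin(pmax(p$a * cv$X + p$b, -50), 50)
    lam <- exp(eta)
    r <- lam - counts
    g <- c(a = sum(r * cv$X), b = sum(r))
    for (nm in names(cv$dX)) g[nm] <- p$a * sum(r * cv$dX[[nm]])
    g[pn]
  }
  list(fn = fn, gr = gr)
}

# Parameter bounds for constrained optimization. The gain must be strictly
# positive; wide outer bounds are flagged if a fit ends on one.
param_bounds <- function(model, t_end) {
  pn <- free_params(model)
  lower <- c(a = 1e-6, b = -Inf, k = 1e-3, t0 = 1, w = 0)[pn]
  upper <- c(a = 10, b = Inf, k = 5, t0 = t_end, w = 1)[pn]
  list(lower = lower, upper = upper)
}

# Random starting values; ranges span all regimes used by the simulator.
random_start <- function(model, counts, t_end) {
  pn <- free_params(model)
  cmax <- max(c(counts, 1))
  vals <- c(a = stats::runif(1, 0.01, 5),
            b = stats::runif(1, log(0.1), log(cmax + 1)),
            k = stats::runif(1, 0.01, 1),
            t0 = stats::runif(1, 1, t_end),
            w = stats::runif(1, 0, 1))
  vals[pn]
}

#' Fit a spike-count model by constrained multi-start maximum likelihood
#'
#' Minimizes [neg_loglik()] with a bound-constrained quasi-Newton method
#' (`optim(method = "L-BFGS-B")`) from `n_starts` random starting points,
#' keeping the best converged result. Bounds: a in (0, 10], w in [0, 1],
#' t0 in [1, t_end], k in [1e-3, 5], b unbounded. The unmodulated model has
#' the closed-form solution `sbar = mean(counts)` and needs no optimization.
#'
#' @inheritParams neg_loglik
#' @param model model family name.
#' @param n_starts number of random starts (default 20).
#' @param seed optional integer seed making the random starts reproducible.
#' @param lick_counts per-trial total lick counts (licks model only).
#' @param start optional named vector used as an additional (first) start,
#'   e.g. a warm start from a fit to a superset of the data.
#' @return object of class `scm_fit`: fields `model`, `params` (named list
#'   including `sbar`), `loglik`, `n_trials`, `n_starts_converged`,
#'   `at_bound` (named logical), plus the data needed by methods.
#' @export
fit_mle <- function(model, counts, trial_numbers, outcomes, t_end,
                    n_starts = 20, seed = NULL, lick_counts = NULL,
                    start = NULL) {
  model <- match.arg(model, model_names)
  pn <- free_params(model)
  if (length(counts) < max(2 * length(pn), 1))
    stop("too few trials (", length(counts), ") to fit the ", model, " model")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  sbar <- mean(counts)

  lick_norm <- NULL
  if (model == "licks") {
    if (is.null(lick_counts) || length(lick_counts) != length(counts))
      stop("licks model requires lick_counts aligned with counts")
    if (isTRUE(attr(lick_counts, "prenormalized"))) {
      lick_norm <- as.numeric(lick_counts)
    } else {
      rng <- range(lick_counts)
      if (diff(rng) == 0)
        stop("degenerate covariate: lick counts are constant")
      lick_norm <- (lick_counts - rng[1]) / (rng[2] - rng[1])
    }
  }

  if (model == "unmodulated") {
    params <- list(sbar = sbar)
    ll <- -neg_loglik(model, params, counts, trial_numbers, outcomes, t_end)
    return(new_scm_fit(model, params, ll, counts, trial_numbers, outcomes,
                       t_end, n_starts_converged = NA_integer_,
                       at_bound = logical(0), lick_norm = lick_norm))
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  b <- param_bounds(model, t_end)
  ob <- make_objective(model, counts, trial_numbers, outcomes, t_end,
                       lick_norm)
  obj <- ob$fn
  grad <- ob$gr
  starts <- lapply(seq_len(n_starts), function(i)
    random_start(model, counts, t_end))
  if (!is.null(start)) starts <- c(list(start[pn]), starts)
  best <- NULL
  n_conv <- 0L
  for (s0 in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s0, b$lower), b$upper), obj, gr = grad,
                   method = "L-BFGS-B", lower = b$lower, upper = b$upper,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all ", length(starts), " starts failed for the ", model, " model")
  theta <- best$par
  names(theta) <- pn
  tol <- 1e-6
  at_bound <- (is.finite(b$lower) & theta <= b$lower + tol) |
    (is.finite(b$upper) & theta >= b$upper - tol)
  names(at_bound) <- pn
  params <- c(as.list(theta), list(sbar = sbar))
  # the optimizer drops the log(c!) constant; report the exact likelihood
  p_full <- params
  p_full$lick_norm <- lick_norm
  ll <- -neg_loglik(model, p_full, counts, trial_numbers, outcomes, t_end)
  new_scm_fit(model, params, ll, counts, trial_numbers, outcomes,
              t_end, n_starts_converged = n_conv, at_bound = at_bound,
              lick_norm = lick_norm)
}

new_scm_fit <- function(model, params, loglik, counts, trial_numbers,
                        outcomes, t_end, n_starts_converged, at_bound,
                        lick_norm = NULL) {
  structure(list(model = model, params = params, loglik = loglik,
                 n_trials = length(counts), t_end = t_end,
                 counts = counts, trial_numbers = trial_numbers,
                 outcomes = outcomes, lick_norm = lick_norm,
                 n_starts_converged = n_starts_converged,
                 at_bound = at_bound),
            class = "scm_fit")
}

#' @export
print.scm_fit <- function(x, ...) {
  cat("<scm_fit> ", x$model, " model, ", x$n_trials, " trials\n", sep = "")
  cat("  logLik: ", format(x$loglik, digits = 6), "\n", sep = "")
  cf <- coef(x)
  if (length(cf))
    cat("  params: ", paste(names(cf), signif(cf, 4), sep = " = ",
                            collapse = ", "), "\n", sep = "")
  if (length(x$at_bound) && any(x$at_bound))
    cat("  note: parameter(s) at bound: ",
        paste(names(x$at_bound)[x$at_bound], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.scm_fit <- function(object, ...) {
  pn <- free_params(object$model)
  if (!length(pn)) return(c(sbar = object$params$sbar))
  unlist(object$params[pn])
}

#' @export
logLik.scm_fit <- function(object, ...) {
  structure(object$loglik, df = length(free_params(object$model)),
            nobs = object$n_trials, class = "logLik")
}

#' Predicted trial rates from a fitted spike-count model
#'
#' @param object an `scm_fit`.
#' @param newdata optional list/data.frame with `trial_numbers` and
#'   `outcomes`; default = the fitted trials. Not available for the licks
#'   model (its covariate is tied to the fitted trials).
#' @param ... unused.
#' @return expected spike count per trial.
#' @export
predict.scm_fit <- function(object, newdata = NULL, ...) {
  p <- object$params
  p$lick_norm <- object$lick_norm
  if (is.null(newdata)) {
    return(model_rate(object$model, p, object$trial_numbers,
                      object$outcomes, object$t_end))
  }
  if (object$model == "licks")
    stop("licks model predictions are only defined on the fitted trials")
  model_rate(object$model, p, newdata$trial_numbers, newdata$outcomes,
             object$t_end)
}

#' @export
residuals.scm_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  lam <- predict(object)
  r <- object$counts - lam
  if (type == "pearson") r <- r / sqrt(lam)
  r
}

#' Simulate spike counts from a fitted spike-count model
#' @param object an `scm_fit`.
#' @param nsim number of replicate count vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `nsim` integer vectors (length = fitted trials).
#' @export
simulate.scm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lam <- predict(object)
  lapply(seq_len(nsim), function(i) stats::rpois(length(lam), lam))
}

#' Cross-validated likelihood of a spike-count model
#'
#' Repeatedly splits the included trials into a random 80/20 train/test
#' partition, refits the model on the training trials and evaluates the mean
#' per-trial held-out log-likelihood on the test trials; returns the mean
#' across repetitions (default 50). The per-trial log scale makes the value
#' comparable across splits and neurons.
#'
#' @inheritParams fit_mle
#' @param n_reps number of random splits (default 50).
#' @param train_frac fraction of trials used for fitting (default 0.8).
#' @param n_starts random starts for each training fit; the full-data
#'   estimate (fitted internally) is always added as a warm start, so small
#'   values remain reliable inside cross-validation.
#' @param seed integer seed controlling both the splits and the starts.
#' @param splits optional list of integer train-index vectors, one per
#'   repetition, overriding the random splits; [compare_models()] uses this
#'   to score every candidate model on the same partitions, which removes
#'   split-to-split noise from the between-model comparison.
#' @return scalar: mean held-out per-trial log-likelihood.
#' @export
cross_validated_likelihood <- function(model, counts, trial_numbers, outcomes,
                                       t_end, n_reps = 50, train_frac = 0.8,
                                       n_starts = 20, seed = NULL,
                                       lick_counts = NULL, splits = NULL) {
  n <- length(counts)
  if (n < 5) stop("need at least 5 trials for cross-validation")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(splits)) n_reps <- length(splits)
  if (model == "licks" && !is.null(lick_counts) &&
      !isTRUE(attr(lick_counts, "prenormalized"))) {
    # normalize once over the full included-trial set so train and test
    # splits share the covariate scale
    rng <- range(lick_counts)
    if (diff(rng) == 0) stop("degenerate covariate: lick counts are constant")
    lick_counts <- (lick_counts - rng[1]) / (rng[2] - rng[1])
    attr(lick_counts, "prenormalized") <- TRUE
  }
  full <- fit_mle(model, counts, trial_numbers, outcomes, t_end,
                  n_starts = max(n_starts, 5),
                  seed = if (is.null(seed)) NULL else derive_seed(seed, 1),
                  lick_counts = lick_counts)
  warm <- if (length(free_params(model))) coef(full) else NULL
  n_train <- max(round(train_frac * n), 1)
  rep_vals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    tr_idx <- if (is.null(splits)) sort(sample.int(n, n_train))
    else splits[[r]]
    te_idx <- setdiff(seq_len(n), tr_idx)
    if (!length(te_idx)) te_idx <- tr_idx  # degenerate tiny-n guard
    lc_tr <- NULL
    if (model == "licks") {
      lc_tr <- lick_counts[tr_idx]
      attr(lc_tr, "prenormalized") <- TRUE
    }
    fit <- fit_mle(model, counts[tr_idx], trial_numbers[tr_idx],
                   outcomes[tr_idx], t_end, n_starts = n_starts,
                   lick_counts = lc_tr, start = warm)
    p <- fit$params
    if (model == "licks") p$lick_norm <- as.numeric(lick_counts[te_idx])
    nll <- neg_loglik(model, p, counts[te_idx], trial_numbers[te_idx],
                      outcomes[te_idx], t_end)
    rep_vals[r] <- -nll / length(te_idx)
  }
  mean(rep_vals)
}

#' Select the best spike-count model by cross-validated likelihood
#'
#' @param cv_logliks named numeric vector of cross-validated likelihoods,
#'   one per candidate model (names from the model family).
#' @return the winning model name; exact ties go to the model with fewer
#'   free parameters.
#' @export
select_model <- function(cv_logliks) {
  stopifnot(length(cv_logliks) >= 2, !is.null(names(cv_logliks)))
  best <- max(cv_logliks)
  cand <- names(cv_logliks)[cv_logliks == best]
  if (length(cand) == 1) return(cand)
  npar <- vapply(cand, function(m) length(free_params(m)), integer(1))
  cand[which.min(npar)]
}

#' Fit the lick-count alternative model
#'
#' Convenience wrapper around [fit_mle()] for the model in which the
#' normalized per-trial total lick count predicts the spike count.
#'
#' @inheritParams fit_mle
#' @return an `scm_fit`.
#' @export
fit_licks_model <- function(counts, lick_counts, trial_numbers, outcomes,
                            t_end, n_starts = 20, seed = NULL) {
  fit_mle("licks", counts, trial_numbers, outcomes, t_end,
          n_starts = n_starts, seed = seed, lick_counts = lick_counts)
}

#' Fit and compare spike-count models for one neuron
#'
#' Fits each candidate model to the same included trials by multi-start
#' maximum likelihood, computes its cross-validated likelihood, and selects
#' the winner. This is the per-neuron model comparison at the center of the
#' analysis.
#'
#' @inheritParams cross_validated_likelihood
#' @param models candidate model names (default: the four spike-count
#'   models; add `"licks"` and supply `lick_counts` to include the lick
#'   alternative).
#' @return object of class `scm_selection`: `fits` (named list of
#'   `scm_fit`), `cv_loglik` (named numeric), `best` (model name).
#' @export
compare_models <- function(counts, trial_numbers, outcomes, t_end,
                           models = c("unmodulated", "satiety",
                                      "preference", "mixed"),
                           n_reps = 50, train_frac = 0.8, n_starts = 20,
                           cv_n_starts = 2, seed = NULL,
                           lick_counts = NULL) {
  models <- match.arg(models, model_names, several.ok = TRUE)
  n <- length(counts)
  n_train <- max(round(train_frac * n), 1)
  if (!is.null(seed)) set.seed(derive_seed(seed, 99))
  splits <- lapply(seq_len(n_reps), function(r)
    sort(sample.int(n, n_train)))
  fits <- list(); cvs <- numeric(0)
  for (i in seq_along(models)) {
    m <- models[i]
    lc <- if (m == "licks") lick_counts else NULL
    sd_i <- if (is.null(seed)) NULL else derive_seed(seed, i)
    fits[[m]] <- fit_mle(m, counts, trial_numbers, outcomes, t_end,
                         n_starts = n_starts, seed = sd_i, lick_counts = lc)
    cvs[m] <- cross_validated_likelihood(
      m, counts, trial_numbers, outcomes, t_end,
      train_frac = train_frac, n_starts = cv_n_starts,
      seed = if (is.null(seed)) NULL else derive_seed(seed, 100 + i),
      lick_counts = lc, splits = splits)
  }
  structure(list(fits = fits, cv_loglik = cvs, best = select_model(cvs)),
            class = "scm_selection")
}

#' @export
print.scm_selection <- function(x, ...) {
  cat("<scm_selection> best model:", x$best, "\n")
  tab <- data.frame(model = names(x$cv_loglik),
                    cv_loglik = round(x$cv_loglik, 4),
                    loglik_full = round(vapply(x$fits, `[[`, numeric(1),
                                               "loglik"), 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
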