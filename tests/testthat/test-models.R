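# independent oracle: rate sequences written out directly from the model
# definitions, bypassing model_rate / make_objective
oracle_rate <- function(model, p, tn, out, t_end) {
  sat <- 1 - tn / t_end
  L_all <- function(k, t0) 1 / (1 + exp(-k * (seq_len(t_end) - t0)))
  switch(model,
    unmodulated = rep(p$sbar, length(tn)),
    satiety = exp(p$a * sat + p$b),
    preference = {
      L <- L_all(p$k, p$t0)
      N <- (L - min(L)) / (max(L) - min(L))
      x <- ifelse(out == "sucrose", N[tn], 1 - N[tn])
      exp(p$a * x + p$b)
    },
    mixed = {
      L <- L_all(p$k, p$t0)
      N <- (L - min(L)) / (max(L) - min(L))
      x <- p$w * ifelse(out == "sucrose", N[tn], 1 - N[tn]) +
        (1 - p$w) * sat
      exp(p$a * x + p$b)
    })
}

oracle_nll <- function(model, p, counts, tn, out, t_end) {
  lam <- oracle_rate(model, p, tn, out, t_end)
  -sum(counts * log(lam) - lam - lfactorial(counts))
}

test_that("model rates satisfy the closed-form boundary identities", {
  t_end <- 100
  tn <- 1:100
  out <- rep(c("sucrose", "water"), 50)
  # satiety covariate: 0 at t_end, 0.5 at t_end/2
  lam <- model_rate("satiety", list(a = 1, b = 0), tn, out, t_end)
  expect_equal(lam[t_end], exp(0))        # Sat(t_end) = 0
  expect_equal(lam[t_end / 2], exp(0.5))  # Sat(t_end/2) = 0.5
  # raw logistic at t0 is 0.5, and sucrose/water raw values sum to 1
  k <- 0.2; t0 <- 40
  L <- 1 / (1 + exp(-k * (tn - t0)))
  expect_equal(L[t0], 0.5)
  expect_equal(L + (1 - L), rep(1, t_end))
  # normalization hits exactly 0 and 1 at the session extremes
  N <- vpref:::pref_covariate(k, t0, t_end)
  expect_identical(range(N), c(0, 1))
  # mixed boundaries: w = 1 is preference, w = 0 is satiety
  p <- list(a = 1.3, b = 0.4, k = k, t0 = t0)
  expect_equal(model_rate("mixed", c(p, w = 1), tn, out, t_end),
               model_rate("preference", p, tn, out, t_end))
  expect_equal(model_rate("mixed", c(p, w = 0), tn, out, t_end),
               model_rate("satiety", p[c("a", "b")], tn, out, t_end))
  expect_error(model_rate("satiety", list(a = 1, b = 0), c(0, 5), out[1:2],
                          t_end), "1..t_end")
})

test_that("model_rate agrees with the directly transcribed model formulas", {
  sched <- base_schedule()
  inc <- included_trials(sched)
  t_end <- nrow(sched)
  cases <- list(
    list("unmodulated", list(sbar = 3.7)),
    list("satiety", list(a = 2, b = 0.5)),
    list("preference", list(a = 1.5, b = 0.2, k = 0.12, t0 = 80)),
    list("mixed", list(a = 1.5, b = 0.5, k = 0.15, t0 = 75, w = 0.7)))
  for (cs in cases) {
    expect_equal(
      model_rate(cs[[1]], cs[[2]], inc$trial_numbers, inc$outcomes, t_end),
      oracle_rate(cs[[1]], cs[[2]], inc$trial_numbers, inc$outcomes, t_end),
      tolerance = 1e-12, info = cs[[1]])
  }
})

test_that("neg_loglik equals direct Poisson PMF summation and is additive", {
  counts <- c(1L, 2L, 3L)
  tn <- c(10L, 20L, 30L)
  out <- c("sucrose", "water", "sucrose")
  v <- neg_loglik("unmodulated", list(sbar = 2), counts, tn, out, 100)
  expect_equal(v, -sum(log(dpois(counts, 2))), tolerance = 1e-12)
  expect_equal(neg_loglik("unmodulated", list(sbar = 2), integer(0),
                          integer(0), character(0), 100), 0)
  v2 <- neg_loglik("unmodulated", list(sbar = 2), rep(counts, 2),
                   rep(tn, 2), rep(out, 2), 100)
  expect_equal(v2, 2 * v, tolerance = 1e-12)
  # zero rate with positive count gives Inf, not an error
  expect_equal(neg_loglik("unmodulated", list(sbar = 0), 1L, 1L, "sucrose",
                          10), Inf)
})

test_that("the unmodulated MLE is exactly the sample mean count", {
  set.seed(2)
  counts <- rpois(25, 3.2)
  fit <- fit_mle("unmodulated", counts, seq_along(counts),
                 rep("sucrose", 25), 25)
  expect_identical(fit$params$sbar, mean(counts))
  expect_equal(fit$loglik, sum(dpois(counts, mean(counts), log = TRUE)))
})

test_that("multi-start MLE matches a dense grid-search oracle on small
          satiety instances", {
  sched <- base_schedule()
  set.seed(5)
  for (r in 1:5) {
    n <- 25
    keep <- sort(sample(which(sched$in_port_at_delivery &
                                sched$trial_type == "forced_uncertain"), n))
    tn <- sched$trial_number[keep]; out <- sched$outcome[keep]
    lam <- oracle_rate("satiety", list(a = 1.5, b = 0.6), tn, out, 150)
    counts <- rpois(n, lam)
    fit <- fit_mle("satiety", counts, tn, out, 150, n_starts = 10,
                   seed = r)
    grid <- expand.grid(a = seq(0.01, 5, length.out = 60),
                        b = seq(-2, 3, length.out = 60))
    gvals <- mapply(function(a, b)
      oracle_nll("satiety", list(a = a, b = b), counts, tn, out, 150),
      grid$a, grid$b)
    expect_gte(fit$loglik, -min(gvals) - 1e-3)
  }
})

test_that("mixed-model parameters are recovered from simulated neurons", {
  sched <- base_schedule()
  truth <- list(a = 1.5, b = 0.5, k = 0.15, t0 = 75, w = 0.7)
  est <- t(vapply(1:12, function(r) {
    d <- draw_counts("mixed", truth, sched, seed = 500 + r)
    coef(fit_mle("mixed", d$counts, d$trial_numbers, d$outcomes, d$t_end,
                 n_starts = 20, seed = r))
  }, numeric(5)))
  expect_lt(abs(median(est[, "t0"]) - 75), 10)
  expect_lt(abs(median(est[, "w"]) - 0.7), 0.15)
  expect_lt(abs(median(est[, "a"]) - 1.5), 0.5)
})

test_that("the mixed likelihood dominates its nested submodels on any
          data", {
  sched <- base_schedule()
  for (gen in c("satiety", "preference")) {
    p <- list(a = 1.8, b = 0.4, k = 0.2, t0 = 60, w = 0.5)[
      c("a", "b", if (gen == "preference") c("k", "t0"))]
    d <- draw_counts(gen, p, sched, seed = 77)
    sub <- fit_mle(gen, d$counts, d$trial_numbers, d$outcomes, d$t_end,
                   n_starts = 10, seed = 1)
    mix <- fit_mle("mixed", d$counts, d$trial_numbers, d$outcomes, d$t_end,
                   n_starts = 20, seed = 1)
    expect_gte(mix$loglik, sub$loglik - 1e-4)
  }
})

test_that("cross-validated likelihood is deterministic under a fixed seed
          and approaches the analytic expectation for homogeneous data", {
  sched <- base_schedule()
  d <- draw_counts("unmodulated", list(sbar = 4), sched, seed = 9)
  cv1 <- cross_validated_likelihood("unmodulated", d$counts,
                                    d$trial_numbers, d$outcomes, d$t_end,
                                    n_reps = 20, seed = 31)
  cv2 <- cross_validated_likelihood("unmodulated", d$counts,
                                    d$trial_numbers, d$outcomes, d$t_end,
                                    n_reps = 20, seed = 31)
  expect_identical(cv1, cv2)
  # E[log Poisson(c; 4)] under c ~ Poisson(4)
  cs <- 0:60
  analytic <- sum(dpois(cs, 4) * dpois(cs, 4, log = TRUE))
  expect_lt(abs(cv1 - analytic), 0.15)
})

test_that("model selection prefers the generating family and breaks ties by
          parsimony", {
  expect_equal(select_model(c(unmodulated = -2.0, mixed = -1.5)), "mixed")
  expect_equal(select_model(c(unmodulated = -2.0, satiety = -2.0)),
               "unmodulated")
  expect_equal(select_model(c(mixed = -1.0, preference = -1.0)),
               "preference")
  sched <- base_schedule()
  d <- draw_counts("mixed", list(a = 2, b = 0.5, k = 0.15, t0 = 75,
                                 w = 0.7), sched, seed = 123)
  wins <- vapply(1:8, function(r) {
    sel <- compare_models(d$counts, d$trial_numbers, d$outcomes, d$t_end,
                          models = c("unmodulated", "mixed"),
                          cv_n_starts = 1, seed = r)
    sel$best == "mixed"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("the licks model behaves like its siblings and detects a lick-
          driven neuron", {
  sched <- base_schedule()
  inc <- included_trials(sched)
  n <- length(inc$trial_numbers)
  set.seed(41)
  licks <- rpois(n, 20 + 10 * sin(seq_len(n) / 8))
  ln <- (licks - min(licks)) / (max(licks) - min(licks))
  counts <- rpois(n, exp(1.2 * ln + 0.6))
  fit <- fit_licks_model(counts, licks, inc$trial_numbers, inc$outcomes,
                         nrow(sched), n_starts = 10, seed = 2)
  expect_gt(coef(fit)["a"], 0.5)
  expect_error(fit_licks_model(counts, rep(3, n), inc$trial_numbers,
                               inc$outcomes, nrow(sched)),
               "degenerate covariate")
  # lick-driven neuron wins selection over the mixed alternative
  sel <- compare_models(counts, inc$trial_numbers, inc$outcomes,
                        nrow(sched),
                        models = c("unmodulated", "mixed", "licks"),
                        cv_n_starts = 1, seed = 6, lick_counts = licks)
  expect_equal(sel$best, "licks")
})

test_that("scm_fit methods are mutually consistent", {
  sched <- base_schedule()
  d <- draw_counts("satiety", list(a = 1.5, b = 0.6), sched, seed = 15)
  fit <- fit_mle("satiety", d$counts, d$trial_numbers, d$outcomes, d$t_end,
                 n_starts = 10, seed = 3)
  lam <- predict(fit)
  expect_equal(as.numeric(logLik(fit)),
               sum(dpois(d$counts, lam, log = TRUE)))
  expect_equal(residuals(fit, "response"), d$counts - lam)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_length(sims[[1]], fit$n_trials)
  expect_output(print(fit), "satiety")
  # too few trials for the parameter count is refused
  expect_error(fit_mle("mixed", d$counts[1:6], d$trial_numbers[1:6],
                       d$outcomes[1:6], d$t_end), "too few trials")
})
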