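choice_session_from_logistic <- function(k, t0, n_trials = 150, seed = 1) {
  sched <- simulate_schedule(n_trials, "uncertain_outcome", seed = seed)
  sched <- simulate_choices(sched, k, t0, seed = seed + 1)
  vp_session(list(session_id = "b", task = "uncertain_outcome",
                  n_trials = n_trials,
                  reward_volumes = list(sucrose = 55, water = 110),
                  subject_id = "f"),
             sched, list())
}

test_that("behavioral logistic fit recovers generating parameters", {
  errs <- vapply(1:30, function(r) {
    s <- choice_session_from_logistic(0.1, 60, seed = 2000 + 3 * r)
    fit_behavioral_logistic(s)$t0 - 60
  }, numeric(1))
  expect_lt(abs(median(errs)), 10)
})

test_that("perfectly separated choices put t0 inside the separation gap and
          identical choices are flagged non-identifiable", {
  s <- choice_session_from_logistic(0.1, 75, n_trials = 120, seed = 5)
  ch <- s$trials$trial_type == "choice"
  m <- 60
  s$trials$chosen[ch] <- ifelse(s$trials$trial_number[ch] < m, "water",
                                "sucrose")
  s$trials$outcome[ch] <- s$trials$chosen[ch]
  fit <- fit_behavioral_logistic(s)
  ch_tn <- s$trials$trial_number[ch]
  gap <- c(max(ch_tn[ch_tn < m]), min(ch_tn[ch_tn >= m]))
  expect_gte(fit$t0, gap[1])
  expect_lte(fit$t0, gap[2])

  s$trials$chosen[ch] <- "sucrose"
  s$trials$outcome[ch] <- "sucrose"
  flat <- fit_behavioral_logistic(s)
  expect_false(flat$identifiable)

  few <- choice_session_from_logistic(0.1, 30, n_trials = 20, seed = 3)
  few$trials$trial_type[few$trials$trial_type == "choice"] <-
    "forced_uncertain"
  few$trials$chosen <- NA_character_
  expect_error(fit_behavioral_logistic(few), "choice trials")
})

test_that("flat-preference sessions give small fitted steepness", {
  ks <- vapply(1:10, function(r) {
    s <- choice_session_from_logistic(0, 60, seed = 300 + r)
    f <- fit_behavioral_logistic(s)
    if (f$identifiable) f$k else 0
  }, numeric(1))
  expect_lt(abs(median(ks)), 0.05)
})

test_that("neural preference curves depend only on (k, t0) and carry the
          fitted indifference point", {
  sched <- base_schedule()
  d <- draw_counts("mixed", list(a = 1.5, b = 0.5, k = 0.15, t0 = 75,
                                 w = 0.7), sched, seed = 88)
  fit <- fit_mle("mixed", d$counts, d$trial_numbers, d$outcomes, d$t_end,
                 n_starts = 20, seed = 4)
  np <- neural_preference(fit)
  expect_equal(np$indifference, fit$params$t0)
  expect_lt(abs(np$indifference - 75), 12)
  expect_true(all(np$curve >= 0 & np$curve <= 1))
  # same (k, t0), different (a, b, w): identical curves
  f2 <- fit
  f2$params$a <- 3; f2$params$b <- -1; f2$params$w <- 0.2
  expect_identical(neural_preference(f2)$curve, np$curve)
  # a satiety-model fit is rejected
  fs <- fit_mle("satiety", d$counts, d$trial_numbers, d$outcomes, d$t_end,
                n_starts = 5, seed = 1)
  expect_error(neural_preference(fs), "mixed")
  # w on its bound flags the curve
  f3 <- fit
  f3$params$w <- 0
  f3$at_bound <- c(a = FALSE, b = FALSE, k = FALSE, t0 = FALSE, w = TRUE)
  np3 <- neural_preference(f3)
  expect_true(np3$low_confidence)
  expect_true(np3$satiety_dominated)
})

test_that("agreement statistics behave as rank statistics should", {
  bfit <- structure(list(k = 0.1, t0 = 70,
                         curve = 1 / (1 + exp(-0.1 * (1:140 - 70)))),
                    class = "behavior_logistic")
  same <- structure(list(curve = bfit$curve, indifference = 70),
                    class = "neural_preference")
  rev <- structure(list(curve = 1 - bfit$curve, indifference = 30),
                   class = "neural_preference")
  flat <- structure(list(curve = rep(0.5, 140), indifference = 70),
                    class = "neural_preference")
  ag <- neuron_behavior_agreement(list(a = same, b = rev, c = flat), bfit)
  expect_equal(ag$rho, c(1, -1, NA))
  expect_equal(ag$delta_indifference, c(0, 40, 0))
  # rho is invariant to strictly monotone transforms of the neural curve
  warped <- structure(list(curve = bfit$curve^3, indifference = 70),
                      class = "neural_preference")
  ag2 <- neuron_behavior_agreement(list(w = warped), bfit)
  expect_equal(ag2$rho, 1)
})

test_that("firing/preference and cue/latency correlations handle the
          monotone, inverted and degenerate cases", {
  s <- tiny_session()
  pref <- smoothed_preference(s)
  cm <- extract_counts(s, "n1", "reward",
                       trial_filter = function(tr) rep(TRUE, nrow(tr)))
  # constant counts -> NA
  expect_true(is.na(firing_preference_correlation(cm, pref, "sucrose",
                                                  min_trials = 2)))
  # counts increasing with p(t) -> rho 1; water trials invert the curve
  cm$counts <- rank(pref$p[match(cm$trial_numbers, pref$trial_number)])
  expect_equal(firing_preference_correlation(cm, pref, "sucrose",
                                             min_trials = 2), 1)
  cmw <- cm
  keepw <- cmw$outcomes == "water"
  expect_equal(
    firing_preference_correlation(cmw, pref, "water", min_trials = 2),
    suppressWarnings(cor(cmw$counts[keepw],
                         1 - pref$p[match(cmw$trial_numbers[keepw],
                                          pref$trial_number)],
                         method = "spearman")))
  expect_error(firing_preference_correlation(cm, pref, "water",
                                             min_trials = 99), "at least")

  ll <- log_latency(s)
  cmc <- extract_counts(s, "n1", "cue",
                        trial_filter = function(tr) rep(TRUE, nrow(tr)))
  cmc$counts <- seq_along(cmc$counts)
  ll$log_latency <- -seq_len(nrow(ll))  # perfect negative coupling
  expect_equal(cue_latency_correlation(cmc, ll), -1)
  cmc$counts <- rep(2, length(cmc$counts))
  expect_true(is.na(cue_latency_correlation(cmc, ll)))
})

test_that("latency-coupled simulations yield negative cue-rate/latency
          correlations on average", {
  sim <- cached_sim("lat",
                    sim_config(n_trials = 100, n_neurons = 0,
                               latency_coupling = 0.8, seed = 77))
  s <- sim$session
  ll <- log_latency(s)
  # under coupling, later sucrose trials (high drive) have short latencies:
  # correlate drive proxy with log latency
  drive <- ifelse(s$trials$outcome == "sucrose",
                  s$trials$trial_number, -s$trials$trial_number)
  m <- match(ll$trial_number, s$trials$trial_number)
  ok <- !is.na(drive[m])
  rho <- cor(drive[m][ok], ll$log_latency[ok], method = "spearman")
  expect_lt(rho, 0)
})

test_that("rank-sum contrasts are symmetric and detect disjoint groups", {
  a <- c(1.2, 1.5, 1.7, 2.0)
  res_same <- group_contrast(a, a)
  expect_gt(res_same$p_value, 0.9)
  res <- group_contrast(a, a + 10)
  res_swap <- group_contrast(a + 10, a)
  expect_equal(res$p_value, res_swap$p_value)
  # disjoint supports at n = m = 4: the exact two-sided minimum is
  # 2 * 1/choose(8, 4) = 2/70
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_error(group_contrast(numeric(0), a), "non-empty")
})
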