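make_choice_session <- function(choices, n_trials = length(choices) * 2) {
  # choice trials at even positions, forced water at odd ones
  n_ch <- length(choices)
  types <- rep(c("forced_water", "choice"), length.out = n_trials)
  ch_idx <- which(types == "choice")[seq_len(n_ch)]
  types[setdiff(which(types == "choice"), ch_idx)] <- "forced_water"
  chosen <- rep(NA_character_, n_trials)
  chosen[ch_idx] <- choices
  cue <- 50 * seq_len(n_trials)
  trials <- data.frame(
    trial_number = seq_len(n_trials), trial_type = types,
    cue_onset_s = cue, press_time_s = cue + 1,
    reward_time_s = cue + 3,
    outcome = ifelse(types == "choice", chosen, "water"),
    in_port_at_delivery = TRUE, chosen = chosen, stringsAsFactors = FALSE)
  vp_session(list(session_id = "c", task = "specific_cues",
                  n_trials = n_trials,
                  reward_volumes = list(sucrose = 55, water = 110),
                  subject_id = "f"),
             trials, list())
}

test_that("constant choice sequences map to the endpoints of the preference
          scale", {
  all_s <- make_choice_session(rep("sucrose", 10))
  expect_true(all(smoothed_preference(all_s)$p == 1))
  all_w <- make_choice_session(rep("water", 10))
  expect_true(all(smoothed_preference(all_w)$p == 0))
  no_choice <- make_choice_session(rep("water", 4))
  no_choice$trials$trial_type <- "forced_water"
  no_choice$trials$chosen <- NA_character_
  no_choice$trials$outcome <- "water"
  expect_error(smoothed_preference(no_choice), "no choice trials")
})

test_that("smoothed preference matches a direct Gaussian kernel sum and is
          ~0.5 inside a long alternating sequence", {
  choices <- rep(c("water", "sucrose"), 20)
  s <- make_choice_session(choices)
  p <- smoothed_preference(s)
  # direct kernel computation at interior choice trial 20
  y <- as.numeric(choices == "sucrose")
  i <- 20
  w <- exp(-((seq_along(y) - i)^2) / (2 * 25))
  expected <- sum(w * y) / sum(w)
  ch_tn <- s$trials$trial_number[s$trials$trial_type == "choice"]
  expect_equal(p$p[p$trial_number == ch_tn[i]], expected, tolerance = 1e-12)
  expect_lt(abs(expected - 0.5), 0.05)
  # forced trials inherit the nearest choice trial's value (tie -> earlier)
  forced_tn <- 1  # trial 1 is forced; nearest choice trial is trial 2
  expect_equal(p$p[p$trial_number == forced_tn],
               p$p[p$trial_number == ch_tn[1]])
})

test_that("monotone choice sequences give non-decreasing preference", {
  for (seed in 1:3) {
    set.seed(seed)
    n_ch <- sample(10:30, 1)
    cut <- sample(2:(n_ch - 1), 1)
    choices <- c(rep("water", cut), rep("sucrose", n_ch - cut))
    p <- smoothed_preference(make_choice_session(choices))
    expect_true(all(diff(p$p) >= -1e-12))
  }
})

test_that("quarter preference applies the stated linear transform", {
  # 3 sucrose of 4 choices -> 2*0.75 - 1 = 0.5
  s <- make_choice_session(c("sucrose", "sucrose", "sucrose", "water"),
                           n_trials = 8)
  q <- quarter_preference(s)
  # quarters of 8 trials hold 2 trials each: quarters contain 1 choice each
  expect_equal(q$preference[1], 1)   # sucrose choice
  expect_equal(q$preference[4], -1)  # water choice
  # aggregate transform on an all-choice session
  s2 <- make_choice_session(c("sucrose", "sucrose", "sucrose", "water"))
  s2$trials$trial_type <- "choice"
  s2$trials$chosen <- rep(c("sucrose", "sucrose", "sucrose", "water"),
                          each = 2)
  s2$trials$outcome <- s2$trials$chosen
  q2 <- quarter_preference(s2)
  expect_equal(sum(q2$n_choice), 8)
  # 6 sucrose of 8 choices: 2 * 0.75 - 1 = 0.5
  expect_equal(stats::weighted.mean(q2$preference, q2$n_choice), 0.5)
})

test_that("quarter preference of iid Bernoulli(q) choices converges to
          2q - 1", {
  set.seed(11)
  qv <- 0.7
  vals <- replicate(60, {
    ch <- ifelse(runif(40) < qv, "sucrose", "water")
    mean(quarter_preference(make_choice_session(ch))$preference)
  })
  expect_lt(abs(mean(vals) - (2 * qv - 1)), 0.05)
})

test_that("quarters partition trials with the extra trials leading", {
  q <- vpref:::quarter_index(10)  # 10 = 4*2 + 2 extras
  expect_equal(as.vector(table(q)), c(3, 3, 2, 2))
  expect_equal(q, sort(q))
  expect_equal(length(vpref:::quarter_index(151)), 151)
})

test_that("log latency is the natural log of cue-to-press time and
          order-preserving", {
  s <- tiny_session()
  ll <- log_latency(s)
  expect_equal(ll$log_latency, rep(log(1.5), nrow(s$trials)))
  s$trials$press_time_s[2] <- s$trials$cue_onset_s[2] + 1
  s$trials$press_time_s[3] <- s$trials$cue_onset_s[3] + exp(1)
  s$trials$press_time_s[4] <- s$trials$cue_onset_s[4] + 2.5
  ll <- log_latency(s)
  expect_equal(ll$log_latency[2], 0)
  expect_equal(ll$log_latency[3], 1)
  expect_equal(ll$log_latency[4], log(2.5))
  lat <- exp(ll$log_latency)
  expect_equal(order(lat), order(ll$log_latency))
  s$trials$press_time_s[5] <- s$trials$cue_onset_s[5]
  expect_error(log_latency(s), "non-positive latency")
})

test_that("lick PSTH conserves event mass under smoothing and reflects the
          simulated water decline", {
  s <- tiny_session()  # 3 licks/trial at fixed offsets in (0.5, 1.5)
  # window padded so neither the kernel's start-edge renormalization nor its
  # tail clips the lick mass: sum(rate)*binwidth = licks per trial
  tr <- lick_psth(s, "sucrose", window = c(-2, 4))
  expect_equal(sum(tr$lick_rate) * 0.01, 3, tolerance = 1e-9)
  # a no-lick session yields an all-zero trace
  s0 <- tiny_session()
  s0$licks <- s0$licks[0, ]
  expect_true(all(lick_psth(s0, "sucrose", window = c(0, 3))$lick_rate == 0))
  expect_error(lick_psth(s0, "sucrose", quarter = 9), "no qualifying")

  sim <- cached_sim("s150", sim_config(n_trials = 150, n_neurons = 20,
                                       seed = 21))
  w1 <- lick_psth(sim$session, "water", quarter = 1, window = c(0, 8))
  w4 <- lick_psth(sim$session, "water", quarter = 4, window = c(0, 8))
  expect_gt(mean(w1$lick_rate), mean(w4$lick_rate))
})
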