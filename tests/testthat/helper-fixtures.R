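# Shared fixtures, built in code.

# A tiny deterministic session: 8 trials (5 forced, 3 choice), two neurons
# with hand-placed spikes. Trial i's cue is at 100*i s; presses 1.5 s after
# cue; rewards 2 s after press.
tiny_session <- function() {
  n <- 8
  cue <- 100 * seq_len(n)
  press <- cue + 1.5
  reward <- press + 2
  types <- c("forced_sucrose", "forced_water", "choice", "forced_sucrose",
             "choice", "forced_water", "forced_sucrose", "choice")
  chosen <- ifelse(types == "choice", c(NA, NA, "water", NA, "sucrose", NA,
                                        NA, "sucrose"), NA)
  outcome <- ifelse(types == "forced_sucrose", "sucrose",
                    ifelse(types == "forced_water", "water", chosen))
  trials <- data.frame(trial_number = seq_len(n), trial_type = types,
                       cue_onset_s = cue, press_time_s = press,
                       reward_time_s = reward, outcome = outcome,
                       in_port_at_delivery = TRUE, chosen = chosen,
                       stringsAsFactors = FALSE)
  # n1: 3 spikes in each reward window (at reward + 0.8, 1.0, 1.9), one
  # spike at each cue + 0.13, and i baseline spikes before trial i's cue so
  # the pre-cue baseline rate varies across trials (needed for z-scoring)
  base1 <- unlist(lapply(seq_len(n), function(i)
    cue[i] - 8 + 0.4 * seq_len(i)))
  sp1 <- sort(c(reward + 0.8, reward + 1.0, reward + 1.9, cue + 0.13,
                base1))
  # n2: steady 2 Hz-ish background (every 0.5 s for 10 s before each cue)
  sp2 <- sort(unlist(lapply(cue, function(cc) seq(cc - 10, cc - 0.25,
                                                  by = 0.5))))
  licks <- data.frame(
    trial_number = rep(seq_len(n), each = 3),
    lick_time_s = as.vector(vapply(reward, function(r)
      r + c(0.6, 1.0, 1.4), numeric(3))))
  vp_session(
    meta = list(session_id = "tiny", task = "specific_cues", n_trials = n,
                reward_volumes = list(sucrose = 55, water = 110),
                subject_id = "fixture"),
    trials = trials,
    spikes = list(n1 = sp1, n2 = sp2),
    licks = licks)
}

# Cache expensive simulated sessions across test files.
.fixture_env <- new.env(parent = emptyenv())

cached_sim <- function(key, config) {
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_session(config)
  .fixture_env[[key]]
}

# A resolved 150-trial uncertain-outcome schedule shared by count-level
# model tests (no neurons attached).
base_schedule <- function() {
  if (is.null(.fixture_env$sched)) {
    sched <- simulate_schedule(150, "uncertain_outcome", seed = 42)
    .fixture_env$sched <- simulate_choices(sched, 0.15, 75, seed = 43)
  }
  .fixture_env$sched
}

# Included forced-trial view of a schedule (the model-fitting trial set).
included_trials <- function(sched) {
  keep <- sched$trial_type %in% c("forced_sucrose", "forced_water",
                                  "forced_uncertain") &
    sched$in_port_at_delivery
  list(trial_numbers = sched$trial_number[keep],
       outcomes = sched$outcome[keep])
}

# Draw Poisson counts directly from a model's rate sequence (count-level
# generator used where full spike trains are unnecessary).
draw_counts <- function(model, params, sched, seed) {
  inc <- included_trials(sched)
  lam <- model_rate(model, params, inc$trial_numbers, inc$outcomes,
                    nrow(sched))
  set.seed(seed)
  list(counts = rpois(length(lam), lam), trial_numbers = inc$trial_numbers,
       outcomes = inc$outcomes, t_end = nrow(sched))
}
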