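#' Simulate a trial schedule
#'
#' Draws the trial-type sequence and event timestamps for one session.
#' Trial types are i.i.d.: choice trials occur with probability 0.4; in the
#' specific-cues task the remainder splits evenly between forced sucrose and
#' forced water (0.3 each); in the uncertain-outcome task the remaining 0.6
#' are forced trials whose outcome is sucrose or water with equal
#' probability, revealed only at delivery. Reward follows the response
#' (lever press, or port entry on uncertain forced trials) by 2 s, and
#' consecutive trials are separated by an inter-trial interval drawn
#' uniformly from 20 to 45 s.
#'
#' Forced trials in the specific-cues task and all choice trials carry a
#' lever-press time; uncertain forced trials record no press (the animal
#' responds by entering the port). Choice-trial outcomes are filled in later
#' by [simulate_choices()].
#'
#' @param n_trials number of completed trials (>= 4).
#' @param task `"specific_cues"` or `"uncertain_outcome"`.
#' @param seed integer seed.
#' @param p_in_port probability the animal is in the port at delivery.
#' @param latency_meanlog,latency_sdlog log-normal press-latency parameters
#'   (seconds scale).
#' @return trial data.frame in the session-format column layout.
#' @export
simulate_schedule <- function(n_trials, task = c("specific_cues",
                                                 "uncertain_outcome"),
                              seed = 1, p_in_port = 0.9,
                              latency_meanlog = log(1.5),
                              latency_sdlog = 0.4) {
  task <- match.arg(task)
  if (n_trials < 4) stop("n_trials must be at least 4")
  set.seed(seed)
  types <- if (task == "specific_cues") {
    sample(c("choice", "forced_sucrose", "forced_water"), n_trials,
           replace = TRUE, prob = c(0.4, 0.3, 0.3))
  } else {
    sample(c("choice", "forced_uncertain"), n_trials, replace = TRUE,
           prob = c(0.4, 0.6))
  }
  outcome <- rep(NA_character_, n_trials)
  outcome[types == "forced_sucrose"] <- "sucrose"
  outcome[types == "forced_water"] <- "water"
  unc <- types == "forced_uncertain"
  outcome[unc] <- sample(c("sucrose", "water"), sum(unc), replace = TRUE)

  latency <- stats::rlnorm(n_trials, latency_meanlog, latency_sdlog)
  iti <- stats::runif(n_trials, 20, 45)
  cue <- press <- reward <- numeric(n_trials)
  clock <- 10
  for (i in seq_len(n_trials)) {
    cue[i] <- clock
    has_press <- types[i] != "forced_uncertain"
    press[i] <- if (has_press) cue[i] + latency[i] else NA_real_
    # on uncertain forced trials the port entry (at cue + latency) starts the
    # same 2-s delay a press would
    reward[i] <- cue[i] + latency[i] + 2
    clock <- reward[i] + iti[i]
  }
  data.frame(trial_number = seq_len(n_trials),
             trial_type = types,
             cue_onset_s = cue,
             press_time_s = press,
             reward_time_s = reward,
             outcome = outcome,
             in_port_at_delivery = stats::runif(n_trials) < p_in_port,
             chosen = NA_character_,
             stringsAsFactors = FALSE)
}

#' Simulate choices from a logistic preference trajectory
#'
#' On each choice trial with session trial number t, the probability of
#' choosing sucrose is `1 / (1 + exp(-k_true * (t - t0_true)))` — the same
#' logistic family the analysis fits to behavior, so behavioral parameter
#' recovery is well-posed. The chosen reward becomes the trial's outcome.
#'
#' @param schedule trial data.frame from [simulate_schedule()].
#' @param k_true logistic steepness (per trial).
#' @param t0_true logistic midpoint (trials); the ground-truth indifference
#'   point.
#' @param seed integer seed.
#' @return the schedule with `chosen` and `outcome` filled on choice trials.
#' @export
simulate_choices <- function(schedule, k_true, t0_true, seed = 1) {
  set.seed(seed)
  idx <- which(schedule$trial_type == "choice")
  t <- schedule$trial_number[idx]
  p_suc <- 1 / (1 + exp(-k_true * (t - t0_true)))
  pick <- ifelse(stats::runif(length(idx)) < p_suc, "sucrose", "water")
  schedule$chosen[idx] <- pick
  schedule$outcome[idx] <- pick
  schedule
}

# Trials whose analysis-window count is driven by the generative model:
# forced trials, with port occupancy required for the reward window. This is
# the same inclusion rule the fitting stage applies.
modeled_trials <- function(schedule, window) {
  forced <- schedule$trial_type %in%
    c("forced_sucrose", "forced_water", "forced_uncertain")
  if (window == "reward") forced & schedule$in_port_at_delivery else forced
}

#' Simulate one neuron's spike train from a spike-count model
#'
#' On each modeled trial the spike count inside the analysis window is drawn
#' Poisson with rate `lambda(t)` from [model_rate()] — the exact rate
#' function the fitting stage optimizes, guaranteeing generator/fitter
#' consistency — and the spikes are placed uniformly within the window.
#' Everywhere else (between trials, on excluded trials) the train is
#' homogeneous Poisson at `baseline_hz`.
#'
#' @param schedule trial data.frame with outcomes resolved.
#' @param model generative family: `"unmodulated"`, `"satiety"`,
#'   `"preference"` or `"mixed"`.
#' @param params named list of generative parameters (see [model_rate()]).
#' @param window which analysis window the model drives (`"reward"` or
#'   `"cue"`).
#' @param seed integer seed.
#' @param baseline_hz background firing rate outside analysis windows.
#' @return sorted numeric vector of spike times (s).
#' @export
simulate_neuron <- function(schedule, model, params,
                            window = c("reward", "cue"), seed = 1,
                            baseline_hz = 4.8) {
  window <- match.arg(window)
  model <- match.arg(model, c("unmodulated", "satiety", "preference",
                              "mixed"))
  set.seed(seed)
  t_end <- nrow(schedule)
  bounds <- analysis_window(window)
  align <- if (window == "cue") schedule$cue_onset_s else
    schedule$reward_time_s
  win_start <- align + bounds[1]
  win_end <- align + bounds[2]
  width <- bounds[2] - bounds[1]
  t_max <- max(schedule$reward_time_s, na.rm = TRUE) + 15

  # background: homogeneous Poisson over the session, thinned out of every
  # trial's analysis window (window counts are fully model-driven there)
  n_bg <- stats::rpois(1, baseline_hz * t_max)
  bg <- sort(stats::runif(n_bg, 0, t_max))
  has_win <- !is.na(align)
  in_win <- rep(FALSE, length(bg))
  for (i in which(has_win)) {
    in_win <- in_win | (bg >= win_start[i] & bg < win_end[i])
  }
  spikes <- bg[!in_win]

  incl <- modeled_trials(schedule, window) & has_win
  lam <- rep(baseline_hz * width, t_end)
  lam[incl] <- model_rate(model, params,
                          schedule$trial_number[incl],
                          schedule$outcome[incl], t_end)
  for (i in which(has_win)) {
    n_i <- stats::rpois(1, lam[i])
    if (n_i > 0)
      spikes <- c(spikes, stats::runif(n_i, win_start[i], win_end[i]))
  }
  spikes <- sort(spikes)
  # strict monotonicity required by the session model
  dup <- c(FALSE, diff(spikes) <= 0)
  while (any(dup)) {
    spikes[dup] <- spikes[dup] + 1e-9
    spikes <- sort(spikes)
    dup <- c(FALSE, diff(spikes) <= 0)
  }
  spikes
}

# Licking: a burst after reward delivery. Sucrose rate is constant across
# the session; the water rate declines linearly with trial number
# (satiety_slope licks/s per trial), emulating waning motivation to drink.
simulate_licks <- function(schedule, seed = 1, base_rate = 6,
                           satiety_slope = -0.03, burst_dur = 6) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(schedule))) {
    out <- schedule$outcome[i]
    rew <- schedule$reward_time_s[i]
    if (is.na(out) || is.na(rew) || !schedule$in_port_at_delivery[i]) next
    rate <- if (out == "water")
      max(base_rate + satiety_slope * (schedule$trial_number[i] - 1), 0.2)
    else base_rate
    n <- stats::rpois(1, rate * burst_dur)
    if (n == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      trial_number = schedule$trial_number[i],
      lick_time_s = sort(stats::runif(n, rew + 0.5, rew + 0.5 + burst_dur)))
  }
  if (!length(rows))
    return(data.frame(trial_number = integer(), lick_time_s = numeric()))
  do.call(rbind, rows)
}

#' Default simulation configuration
#'
#' Study conditions for a synthetic uncertain-outcome session: ~150 trials
#' (the recorded uncertain-outcome sessions spanned 126-175 trials, median
#' 157), 60/40 forced/choice split, a water-to-sucrose preference shift with
#' midpoint near mid-session, declining water licking, and a population in
#' which most modeled neurons follow the mixed (satiety-weighted preference)
#' family.
#'
#' @param n_trials,task,n_neurons session size.
#' @param k_true,t0_true behavioral logistic parameters; `t0_true = NULL`
#'   places the midpoint at mid-session.
#' @param model_mix named probabilities over generative families.
#' @param a,b,w generative neuron parameters (gain, offset, preference
#'   weight); each neuron's (k, t0) equal the behavioral values so that the
#'   population shares the session's preference trajectory.
#' @param satiety_slope water lick-rate decline (licks/s per trial).
#' @param latency_coupling strength of (negative) coupling between a
#'   neuron-independent motivation signal and press latency; 0 disables.
#' @param seed master seed; all component seeds derive from it.
#' @return a configuration list for [simulate_session()].
#' @export
sim_config <- function(n_trials = 150, task = "uncertain_outcome",
                       n_neurons = 30, k_true = 0.15, t0_true = NULL,
                       model_mix = c(unmodulated = 0.3, mixed = 0.7),
                       a = 1.5, b = 0.5, w = 0.7,
                       satiety_slope = -0.03, latency_coupling = 0,
                       seed = 1) {
  if (is.null(t0_true)) t0_true <- n_trials / 2
  list(n_trials = n_trials, task = task, n_neurons = n_neurons,
       k_true = k_true, t0_true = t0_true, model_mix = model_mix,
       a = a, b = b, w = w, satiety_slope = satiety_slope,
       latency_coupling = latency_coupling, seed = seed)
}

#' Simulate a complete session with known ground truth
#'
#' Composes [simulate_schedule()], [simulate_choices()], a lick generator
#' with linearly declining water licking, and [simulate_neuron()] for a
#' population of neurons whose generative families are drawn from
#' `config$model_mix`. Modeled (non-unmodulated) neurons share the
#' behavioral logistic (k, t0), so their activity tracks the same preference
#' trajectory the choices express.
#'
#' @param config list from [sim_config()].
#' @return list with elements `session` (a validated [vp_session()]) and
#'   `ground_truth` (behavioral parameters, per-neuron families and
#'   parameters, lick slope, master seed).
#' @export
simulate_session <- function(config = sim_config()) {
  cf <- config
  sched <- simulate_schedule(cf$n_trials, cf$task,
                             seed = derive_seed(cf$seed, 1))
  sched <- simulate_choices(sched, cf$k_true, cf$t0_true,
                            seed = derive_seed(cf$seed, 2))
  if (cf$latency_coupling != 0) {
    # motivation-coupled latencies: presses quicken with the satiety-weighted
    # preference of the trial's outcome (enables latency-correlation tests)
    set.seed(derive_seed(cf$seed, 3))
    has_press <- !is.na(sched$press_time_s)
    drive <- ifelse(is.na(sched$outcome), 0.5,
                    ifelse(sched$outcome == "sucrose",
                           1 / (1 + exp(-cf$k_true * (sched$trial_number -
                                                        cf$t0_true))),
                           1 - 1 / (1 + exp(-cf$k_true * (sched$trial_number -
                                                            cf$t0_true)))))
    lat <- stats::rlnorm(nrow(sched),
                         log(1.5) - cf$latency_coupling * (drive - 0.5),
                         0.4)
    sched$press_time_s[has_press] <- sched$cue_onset_s[has_press] +
      lat[has_press]
    sched$reward_time_s <- ifelse(has_press, sched$press_time_s + 2,
                                  sched$reward_time_s)
  }
  licks <- simulate_licks(sched, seed = derive_seed(cf$seed, 4),
                          satiety_slope = cf$satiety_slope)
  families <- character(0)
  spikes <- list()
  gt_params <- list()
  if (cf$n_neurons > 0) {
    set.seed(derive_seed(cf$seed, 5))
    mix <- cf$model_mix / sum(cf$model_mix)
    families <- sample(names(mix), cf$n_neurons, replace = TRUE, prob = mix)
    for (j in seq_len(cf$n_neurons)) {
      fam <- families[j]
      pars <- switch(fam,
        # a truly unmodulated neuron keeps its background rate inside the
        # analysis window (4.8 Hz x 1.2 s)
        unmodulated = list(sbar = 4.8 * 1.2),
        satiety = list(a = cf$a, b = cf$b),
        preference = list(a = cf$a, b = cf$b, k = cf$k_true,
                          t0 = cf$t0_true),
        mixed = list(a = cf$a, b = cf$b, k = cf$k_true, t0 = cf$t0_true,
                     w = cf$w))
      nid <- sprintf("n%03d", j)
      spikes[[nid]] <- simulate_neuron(sched, fam, pars, window = "reward",
                                       seed = derive_seed(cf$seed, 1000 + j))
      gt_params[[nid]] <- c(list(model = fam), pars)
    }
  }
  meta <- list(session_id = sprintf("sim-%06d", cf$seed %% 1000000),
               task = cf$task, n_trials = cf$n_trials,
               reward_volumes = list(sucrose = 55, water = 110),
               subject_id = "synthetic")
  session <- vp_session(meta, sched, spikes, licks)
  ground_truth <- list(k_true = cf$k_true, t0_true = cf$t0_true,
                       satiety_slope = cf$satiety_slope,
                       neurons = gt_params, seed = cf$seed)
  list(session = session, ground_truth = ground_truth)
}
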