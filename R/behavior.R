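#' Smoothed behavioral preference curve
#'
#' Codes choices 0 (water) / 1 (sucrose) and smooths them over the ordered
#' sequence of choice trials with a Gaussian kernel (sigma = 5 choice-trial
#' indices), truncating and renormalizing the kernel at the edges so
#' constant choice sequences map to themselves. Every forced trial is then
#' assigned the smoothed preference of the nearest choice trial (by trial
#' number; equidistant neighbors resolve to the earlier trial).
#'
#' @param session a `vp_session`.
#' @param sigma Gaussian width in choice-trial units (default 5).
#' @return data.frame of class `preference_curve` with columns
#'   `trial_number` and `p` (sucrose preference in [0, 1]) for every trial.
#' @export
smoothed_preference <- function(session, sigma = 5) {
  tr <- session$trials
  ch <- which(tr$trial_type == "choice" & !is.na(tr$chosen))
  if (!length(ch))
    stop("session has no choice trials with a recorded choice")
  y <- as.numeric(tr$chosen[ch] == "sucrose")
  n <- length(y)
  idx <- seq_len(n)
  sm <- vapply(idx, function(i) {
    wgt <- exp(-((idx - i)^2) / (2 * sigma^2))
    sum(wgt * y) / sum(wgt)
  }, numeric(1))
  choice_tn <- tr$trial_number[ch]
  p <- vapply(tr$trial_number, function(t) {
    d <- abs(choice_tn - t)
    sm[which.min(d)]  # which.min takes the first (earlier) on ties
  }, numeric(1))
  structure(data.frame(trial_number = tr$trial_number, p = p),
            class = c("preference_curve", "data.frame"))
}

# Quarter assignment: partition the completed trials into four contiguous
# blocks; when t_end is not divisible by 4 the first (t_end mod 4) quarters
# take the extra trial.
quarter_index <- function(t_end) {
  base <- t_end %/% 4
  extra <- t_end %% 4
  sizes <- rep(base, 4) + c(rep(1, extra), rep(0, 4 - extra))
  rep(1:4, times = sizes)
}

#' Quarter-wise behavioral preference
#'
#' For each quarter of completed trials, computes the fraction of choices
#' that were sucrose and transforms it linearly to [-1, 1]
#' (`2 * fraction - 1`), so -1 is exclusive water choice and +1 exclusive
#' sucrose choice. A quarter containing no choice trial yields `NA`.
#'
#' @param session a `vp_session`.
#' @return data.frame with `quarter`, `preference`, `n_choice`,
#'   `first_trial`, `last_trial`.
#' @export
quarter_preference <- function(session) {
  tr <- session$trials
  q <- quarter_index(nrow(tr))
  out <- lapply(1:4, function(k) {
    rows <- tr[q == k, ]
    ch <- rows$trial_type == "choice" & !is.na(rows$chosen)
    pref <- if (any(ch)) 2 * mean(rows$chosen[ch] == "sucrose") - 1
    else NA_real_
    data.frame(quarter = k, preference = pref, n_choice = sum(ch),
               first_trial = min(rows$trial_number),
               last_trial = max(rows$trial_number))
  })
  do.call(rbind, out)
}

#' Natural-log press latencies
#'
#' Latency is the interval from cue onset to the first correct lever press;
#' trials without a press are excluded. Values are returned on the natural
#' log scale (seconds).
#'
#' @param session a `vp_session`.
#' @return data.frame with `trial_number` and `log_latency`.
#' @export
log_latency <- function(session) {
  tr <- session$trials
  has <- !is.na(tr$press_time_s)
  lat <- tr$press_time_s[has] - tr$cue_onset_s[has]
  if (any(lat <= 0))
    stop_validation("non-positive latency on trial ",
                    tr$trial_number[has][which(lat <= 0)[1]])
  data.frame(trial_number = tr$trial_number[has], log_latency = log(lat))
}

#' Lick-rate PSTH around reward delivery
#'
#' Bins lick events of qualifying trials (delivered outcome matching
#' `outcome`, optionally restricted to one session quarter) in 0.01-s bins
#' relative to reward delivery, averages across trials, and applies a single
#' causal half-normal smoothing pass (sigma = 25 bins). Units are licks/s.
#'
#' @param session a `vp_session`.
#' @param outcome `"sucrose"` or `"water"`.
#' @param quarter optional quarter 1-4; `NULL` uses the whole session.
#' @param window time range (s) relative to reward delivery.
#' @param bin_width bin width in seconds.
#' @param sigma_bins smoothing width in bins.
#' @return data.frame with `time_s` (bin centers) and `lick_rate` (licks/s).
#' @export
lick_psth <- function(session, outcome, quarter = NULL,
                      window = c(-2, 13), bin_width = 0.01,
                      sigma_bins = 25) {
  tr <- session$trials
  keep <- !is.na(tr$outcome) & tr$outcome == outcome &
    !is.na(tr$reward_time_s)
  if (!is.null(quarter)) {
    q <- quarter_index(nrow(tr))
    keep <- keep & q == quarter
  }
  idx <- which(keep)
  if (!length(idx))
    stop("no qualifying ", outcome, " trials",
         if (!is.null(quarter)) paste0(" in quarter ", quarter) else "")
  events <- lapply(idx, function(i)
    session$licks$lick_time_s[session$licks$trial_number ==
                                tr$trial_number[i]])
  align <- tr$reward_time_s[idx]
  counts <- bin_events(events, align, window, bin_width)
  mean_rate <- colMeans(counts) / bin_width
  sm <- causal_halfnorm_smooth(mean_rate, sigma_bins)
  edges <- seq(window[1], window[2], by = bin_width)
  data.frame(time_s = edges[-length(edges)] + bin_width / 2, lick_rate = sm)
}

#' Per-trial total lick counts
#'
#' Convenience accessor giving the total number of licks recorded on each
#' trial, used as the covariate of the lick-count spike model.
#'
#' @param session a `vp_session`.
#' @param trial_numbers trials to tabulate (default: all).
#' @return integer vector aligned with `trial_numbers`.
#' @export
trial_lick_counts <- function(session, trial_numbers = NULL) {
  if (is.null(trial_numbers)) trial_numbers <- session$trials$trial_number
  tab <- table(factor(session$licks$trial_number, levels = trial_numbers))
  as.integer(tab)
}
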