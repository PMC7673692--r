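#' Bin event times around aligning events
#'
#' Builds the trials x bins count matrix underlying every PSTH: for each
#' trial, events are shifted relative to that trial's aligning event and
#' counted in half-open bins `[edge, edge + bin_width)` spanning `window`.
#' An event exactly on a bin edge falls in the bin to its right, and no
#' event is counted twice, so the row sum equals the number of events in the
#' window.
#'
#' @param events list of numeric vectors (event times, session clock), one
#'   per trial.
#' @param align_times numeric vector of aligning-event times, one per trial.
#' @param window length-2 numeric, time range (s) relative to the aligning
#'   event; must be increasing.
#' @param bin_width bin width in seconds (default 0.01).
#' @return integer matrix, trials x bins.
#' @export
bin_events <- function(events, align_times, window, bin_width = 0.01) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be an increasing length-2 range")
  if (bin_width <= 0) stop("bin_width must be positive")
  edges <- seq(window[1], window[2], by = bin_width)
  n_bins <- length(edges) - 1
  out <- matrix(0L, nrow = length(events), ncol = n_bins)
  for (i in seq_along(events)) {
    rel <- events[[i]] - align_times[i]
    rel <- rel[rel >= window[1] & rel < edges[n_bins + 1]]
    if (length(rel)) {
      bin <- floor((rel - window[1]) / bin_width) + 1
      bin <- bin[bin >= 1 & bin <= n_bins]
      tab <- tabulate(bin, nbins = n_bins)
      out[i, ] <- tab
    }
  }
  out
}

#' Causal half-normal smoothing
#'
#' Smooths a vector with a half-normal kernel that weights only the current
#' and previous bins, never upcoming ones — the filter used for all firing
#' and licking traces so that smoothed activity never precedes its cause.
#' The kernel is truncated at the start of the vector and renormalized to
#' unit mass over the available lags, so a constant input maps to itself.
#'
#' @param x numeric vector.
#' @param sigma_bins kernel scale in bins (> 0).
#' @param max_lag kernel support in bins (default `ceiling(5 * sigma_bins)`).
#' @return smoothed vector, same length as `x`.
#' @export
causal_halfnorm_smooth <- function(x, sigma_bins, max_lag = NULL) {
  if (sigma_bins <= 0) stop("sigma_bins must be positive")
  if (is.null(max_lag)) max_lag <- ceiling(5 * sigma_bins)
  lags <- 0:max_lag
  k <- exp(-lags^2 / (2 * sigma_bins^2))
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    use <- lags[lags < i]
    kv <- k[seq_along(use)]
    out[i] <- sum(kv * x[i - use]) / sum(kv)
  }
  out
}

#' Z-score a trace against pre-trial baseline windows
#'
#' The baseline set holds one mean firing rate per trial, measured over the
#' 10 s preceding that trial's cue onset. The trace is standardized by the
#' mean and (sample, n-1 denominator) standard deviation of that set.
#'
#' @param trace numeric vector (Hz).
#' @param session a `vp_session`.
#' @param neuron_id neuron whose baseline is used.
#' @param trial_numbers trials contributing baseline windows (default: all).
#' @param baseline_dur baseline window length in seconds (default 10).
#' @return list: `z` (standardized trace), `baseline_mean`, `baseline_sd`.
#' @export
zscore_trace <- function(trace, session, neuron_id, trial_numbers = NULL,
                         baseline_dur = 10) {
  tr <- session$trials
  if (is.null(trial_numbers)) trial_numbers <- tr$trial_number
  cue <- tr$cue_onset_s[match(trial_numbers, tr$trial_number)]
  st <- session$spikes[[neuron_id]]
  if (is.null(st)) stop("unknown neuron_id: ", neuron_id)
  rates <- vapply(cue, function(cc) {
    lo <- max(cc - baseline_dur, 0)
    if (cc <= lo) return(NA_real_)
    sum(st >= lo & st < cc) / (cc - lo)
  }, numeric(1))
  rates <- rates[!is.na(rates)]
  if (length(rates) < 2)
    stop("need at least 2 pre-trial baseline windows")
  mu <- mean(rates)
  sdv <- stats::sd(rates)
  if (sdv == 0)
    stop("zero baseline SD for neuron ", neuron_id,
         "; exclude it from z-scored displays")
  list(z = (trace - mu) / sdv, baseline_mean = mu, baseline_sd = sdv)
}

#' Event-aligned, smoothed, z-scored PSTH
#'
#' The display/analysis convention for firing traces: spikes are binned at
#' 0.01 s around the aligning event, each trial's rate vector is smoothed
#' with a causal half-normal filter (sigma = 3 bins), trials are averaged,
#' the average is smoothed again (sigma = 8 bins), and the result is
#' z-scored against the per-trial 10-s pre-cue baseline windows via
#' [zscore_trace()].
#'
#' @param session a `vp_session`.
#' @param neuron_id neuron to analyze.
#' @param align `"cue"` or `"reward"` — the aligning event.
#' @param trial_filter optional predicate on the trial data.frame; default
#'   keeps forced trials (plus port occupancy when aligning to reward).
#' @param window time range (s) around the event.
#' @param bin_width bin width (s).
#' @param sigma_trial,sigma_avg smoothing widths (bins) for the per-trial
#'   and trial-averaged passes.
#' @return list of class `vp_psth`: `time_s`, `mean_rate` (Hz), `z`,
#'   `baseline_mean`, `baseline_sd`, `n_trials`.
#' @export
build_psth <- function(session, neuron_id, align = c("cue", "reward"),
                       trial_filter = NULL, window = c(-2, 5),
                       bin_width = 0.01, sigma_trial = 3, sigma_avg = 8) {
  align <- match.arg(align)
  tr <- session$trials
  keep <- if (is.null(trial_filter)) {
    k <- tr$trial_type %in% c("forced_sucrose", "forced_water",
                              "forced_uncertain")
    if (align == "reward") k & !is.na(tr$in_port_at_delivery) &
      tr$in_port_at_delivery else k
  } else trial_filter(tr)
  ev <- if (align == "cue") tr$cue_onset_s else tr$reward_time_s
  keep <- keep & !is.na(ev)
  idx <- which(keep)
  if (!length(idx)) stop("no qualifying trials for PSTH")
  st <- session$spikes[[neuron_id]]
  if (is.null(st)) stop("unknown neuron_id: ", neuron_id)
  counts <- bin_events(rep(list(st), length(idx)), ev[idx], window,
                       bin_width)
  rates <- counts / bin_width
  sm <- t(apply(rates, 1, causal_halfnorm_smooth, sigma_bins = sigma_trial))
  avg <- colMeans(sm)
  avg <- causal_halfnorm_smooth(avg, sigma_avg)
  zs <- zscore_trace(avg, session, neuron_id,
                     trial_numbers = tr$trial_number[idx])
  edges <- seq(window[1], window[2], by = bin_width)
  structure(list(time_s = edges[-length(edges)] + bin_width / 2,
                 mean_rate = avg, z = zs$z,
                 baseline_mean = zs$baseline_mean,
                 baseline_sd = zs$baseline_sd,
                 n_trials = length(idx)),
            class = "vp_psth")
}

#' @export
print.vp_psth <- function(x, ...) {
  cat("<vp_psth> ", length(x$time_s), " bins over [",
      min(x$time_s), ", ", max(x$time_s), "] s, ", x$n_trials,
      " trials; baseline ", signif(x$baseline_mean, 3), " +/- ",
      signif(x$baseline_sd, 3), " Hz\n", sep = "")
  invisible(x)
}

#' @export
plot.vp_psth <- function(x, what = c("z", "rate"), ...) {
  what <- match.arg(what)
  y <- if (what == "z") x$z else x$mean_rate
  ylab <- if (what == "z") "firing (z)" else "firing rate (Hz)"
  plot(x$time_s, y, type = "l", xlab = "time from event (s)", ylab = ylab,
       ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
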