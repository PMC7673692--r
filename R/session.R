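#' Construct a behavioral/electrophysiology session object
#'
#' A session bundles the ordered trial table of one recording session with the
#' spike trains of simultaneously recorded neurons and the lick timestamps.
#' All timestamps are in seconds on a common session clock starting at 0.
#' Only completed trials (trials on which the animal responded) are
#' represented; trial numbers are contiguous from 1.
#'
#' @param meta list with elements `session_id`, `task`
#'   (`"specific_cues"` or `"uncertain_outcome"`), `n_trials`,
#'   `reward_volumes` (named list, e.g. `list(sucrose = 55, water = 110)` in
#'   microliters) and `subject_id`.
#' @param trials data.frame with columns `trial_number`, `trial_type`,
#'   `cue_onset_s`, `press_time_s`, `reward_time_s`, `outcome`,
#'   `in_port_at_delivery`, `chosen`. Missing events are `NA`.
#' @param spikes named list of strictly increasing numeric vectors of spike
#'   times (seconds), one element per neuron.
#' @param licks data.frame with columns `trial_number`, `lick_time_s`.
#'
#' @return An object of class `vp_session`.
#' @export
vp_session <- function(meta, trials, spikes = list(), licks = NULL) {
  if (is.null(licks)) {
    licks <- data.frame(trial_number = integer(), lick_time_s = numeric())
  }
  if (!is.null(meta$n_trials)) meta$n_trials <- as.integer(meta$n_trials)
  s <- structure(list(meta = meta, trials = trials, spikes = spikes,
                      licks = licks),
                 class = "vp_session")
  validate_session(s)
  s
}

#' Validate a session object
#'
#' Checks every structural invariant of the session data model: contiguous
#' 1-based trial numbering, event ordering (cue < press < reward where
#' present), positive latencies, outcome present whenever a reward was
#' delivered, `chosen` recorded exactly on choice trials with a press, sorted
#' non-negative spike times, and consistency between `meta$n_trials` and the
#' trial table.
#'
#' @param session a `vp_session`.
#' @return the session, invisibly, if valid; otherwise an error naming the
#'   offending trial or neuron.
#' @export
validate_session <- function(session) {
  m <- session$meta
  tr <- session$trials
  need_meta <- c("session_id", "task", "n_trials", "reward_volumes")
  miss <- setdiff(need_meta, names(m))
  if (length(miss))
    stop_validation("meta is missing fields: ", paste(miss, collapse = ", "))
  if (!m$task %in% c("specific_cues", "uncertain_outcome"))
    stop_validation("unknown task: ", m$task)
  if (m$n_trials < 1)
    stop_validation("n_trials must be >= 1")
  rv <- sort(names(m$reward_volumes))
  if (!identical(rv, c("sucrose", "water")) &&
      !identical(rv, c("maltodextrin", "sucrose")))
    stop_validation("reward_volumes must name exactly {sucrose, water} or ",
                    "{sucrose, maltodextrin}")
  if (nrow(tr) != m$n_trials)
    stop_validation("meta$n_trials (", m$n_trials, ") != trial table rows (",
                    nrow(tr), ")")
  if (!identical(as.integer(tr$trial_number), seq_len(nrow(tr))))
    stop_validation("trial_number must be contiguous 1..n_trials")
  ok_types <- c("forced_sucrose", "forced_water", "forced_uncertain", "choice")
  bad <- which(!tr$trial_type %in% ok_types)
  if (length(bad))
    stop_validation("trial ", bad[1], ": unknown trial_type '",
                    tr$trial_type[bad[1]], "'")
  for (i in seq_len(nrow(tr))) {
    cue <- tr$cue_onset_s[i]; prs <- tr$press_time_s[i]
    rew <- tr$reward_time_s[i]
    if (is.na(cue))
      stop_validation("trial ", i, ": cue_onset_s is required")
    if (!is.na(prs) && prs <= cue)
      stop_validation("trial ", i, ": press_time_s must exceed cue_onset_s")
    if (!is.na(rew)) {
      if (!is.na(prs) && rew <= prs)
        stop_validation("trial ", i, ": reward_time_s must exceed press_time_s")
      if (rew <= cue)
        stop_validation("trial ", i, ": reward_time_s must exceed cue_onset_s")
      if (!tr$outcome[i] %in% c("sucrose", "water", "maltodextrin"))
        stop_validation("trial ", i, ": delivered reward requires outcome")
    }
    is_choice <- tr$trial_type[i] == "choice"
    has_chosen <- !is.na(tr$chosen[i]) && nzchar(tr$chosen[i])
    if (has_chosen && !is_choice)
      stop_validation("trial ", i, ": chosen set on a forced trial")
    if (is_choice && !is.na(prs) && !has_chosen)
      stop_validation("trial ", i, ": choice trial with press lacks chosen")
  }
  for (nid in names(session$spikes)) {
    st <- session$spikes[[nid]]
    if (length(st)) {
      if (any(st < 0))
        stop_validation("neuron ", nid, ": negative spike time")
      if (any(diff(st) <= 0))
        stop_validation("neuron ", nid, ": spike times not strictly increasing")
    }
  }
  invisible(session)
}

#' @export
print.vp_session <- function(x, ...) {
  tt <- table(x$trials$trial_type)
  cat("<vp_session> ", x$meta$session_id, " (", x$meta$task, ")\n", sep = "")
  cat("  trials: ", x$meta$n_trials, " [",
      paste(names(tt), tt, sep = "=", collapse = ", "), "]\n", sep = "")
  cat("  neurons: ", length(x$spikes),
      "; licks: ", nrow(x$licks), "\n", sep = "")
  invisible(x)
}

trial_columns <- c("trial_number", "trial_type", "cue_onset_s", "press_time_s",
                   "reward_time_s", "outcome", "in_port_at_delivery", "chosen")

#' Write a session bundle to disk
#'
#' The on-disk format is a directory holding `meta.json`, `trials.csv`,
#' `spikes.csv` (long format: `neuron_id`, `spike_time_s`) and `licks.csv`.
#' All files are UTF-8 CSV with header rows; empty cells encode absent values.
#' Numeric fields are written with enough digits that `read_session()`
#' recovers them exactly.
#'
#' @param session a valid `vp_session`.
#' @param path directory to create (or overwrite files within).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    stop("cannot create session directory: ", path)
  meta <- session$meta
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- session$trials
  out <- data.frame(
    trial_number = as.integer(tr$trial_number),
    trial_type = tr$trial_type,
    cue_onset_s = fmt_num(tr$cue_onset_s),
    press_time_s = fmt_num(tr$press_time_s),
    reward_time_s = fmt_num(tr$reward_time_s),
    outcome = ifelse(is.na(tr$outcome), "", tr$outcome),
    in_port_at_delivery = ifelse(is.na(tr$in_port_at_delivery), "",
                                 ifelse(tr$in_port_at_delivery, "true", "false")),
    chosen = ifelse(is.na(tr$chosen), "", tr$chosen),
    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(path, "trials.csv"), row.names = FALSE,
                   quote = FALSE)
  ns <- vapply(session$spikes, length, integer(1))
  sp <- data.frame(
    neuron_id = rep(names(session$spikes), ns),
    spike_time_s = fmt_num(unlist(session$spikes, use.names = FALSE) %||%
                             numeric(0)),
    stringsAsFactors = FALSE)
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  lk <- data.frame(trial_number = as.integer(session$licks$trial_number),
                   lick_time_s = fmt_num(session$licks$lick_time_s),
                   stringsAsFactors = FALSE)
  utils::write.csv(lk, file.path(path, "licks.csv"), row.names = FALSE,
                   quote = FALSE)
  # neuron order is not expressible in a long CSV; keep it in meta-side file
  writeLines(names(session$spikes) %||% character(0),
             file.path(path, "neurons.txt"))
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]: reads the directory format and returns a
#' validated [vp_session()]. Reading a bundle produced by `write_session()`
#' reproduces the original session exactly, field by field.
#'
#' @param path session directory.
#' @return a validated `vp_session`.
#' @export
read_session <- function(path) {
  need <- c("meta.json", "trials.csv", "spikes.csv", "licks.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop("session bundle at '", path, "' is missing ", f)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = FALSE)
  meta$n_trials <- as.integer(meta$n_trials)
  tr <- utils::read.csv(file.path(path, "trials.csv"),
                        colClasses = "character")
  miss <- setdiff(trial_columns, names(tr))
  if (length(miss))
    stop("trials.csv missing columns: ", paste(miss, collapse = ", "))
  blank_na <- function(x) ifelse(nzchar(x), x, NA_character_)
  trials <- data.frame(
    trial_number = as.integer(tr$trial_number),
    trial_type = tr$trial_type,
    cue_onset_s = as.numeric(blank_na(tr$cue_onset_s)),
    press_time_s = as.numeric(blank_na(tr$press_time_s)),
    reward_time_s = as.numeric(blank_na(tr$reward_time_s)),
    outcome = blank_na(tr$outcome),
    in_port_at_delivery = blank_na(tr$in_port_at_delivery) == "true",
    chosen = blank_na(tr$chosen),
    stringsAsFactors = FALSE)
  sp <- utils::read.csv(file.path(path, "spikes.csv"),
                        colClasses = "character")
  nfile <- file.path(path, "neurons.txt")
  nids <- if (file.exists(nfile)) readLines(nfile) else unique(sp$neuron_id)
  spikes <- stats::setNames(
    lapply(nids, function(id)
      as.numeric(sp$spike_time_s[sp$neuron_id == id])),
    nids)
  lk <- utils::read.csv(file.path(path, "licks.csv"),
                        colClasses = "character")
  licks <- data.frame(trial_number = as.integer(lk$trial_number),
                      lick_time_s = as.numeric(lk$lick_time_s))
  vp_session(meta = meta, trials = trials, spikes = spikes, licks = licks)
}

#' Analysis windows for event-aligned spike counts
#'
#' Cue-evoked activity is counted 0 to 0.75 s after cue onset; reward-evoked
#' activity 0.75 to 1.95 s after reward delivery. Both windows are half-open
#' `[start, end)` so that shared boundaries are never double counted.
#'
#' @param window `"cue"` or `"reward"`.
#' @return numeric length-2 vector of offsets (s) relative to aligning event.
#' @export
analysis_window <- function(window = c("cue", "reward")) {
  window <- match.arg(window)
  if (window == "cue") c(0, 0.75) else c(0.75, 1.95)
}

#' Extract per-trial spike counts in an analysis window
#'
#' Counts spikes of one neuron within the cue or reward analysis window of
#' every qualifying trial. The aligning event is cue onset for the cue window
#' and reward delivery for the reward window; trials lacking the aligning
#' event are dropped. For the reward window, trials on which the animal was
#' not in the reward port at delivery are always excluded, matching the
#' inclusion rule used for all reward-activity analyses.
#'
#' @param session a `vp_session`.
#' @param neuron_id neuron identifier present in `session$spikes`.
#' @param window `"cue"` or `"reward"`.
#' @param trial_filter optional function taking the trial data.frame and
#'   returning a logical vector of trials to keep. Default keeps forced
#'   trials only.
#' @return list of class `count_matrix`: `neuron_id`, `window`, `counts`
#'   (integer per included trial), `trial_numbers`, `window_bounds`.
#' @export
extract_counts <- function(session, neuron_id,
                           window = c("cue", "reward"),
                           trial_filter = NULL) {
  window <- match.arg(window)
  if (!neuron_id %in% names(session$spikes))
    stop("unknown neuron_id: ", neuron_id)
  tr <- session$trials
  keep <- if (is.null(trial_filter)) {
    tr$trial_type %in% c("forced_sucrose", "forced_water", "forced_uncertain")
  } else {
    trial_filter(tr)
  }
  bounds <- analysis_window(window)
  align <- if (window == "cue") tr$cue_onset_s else tr$reward_time_s
  keep <- keep & !is.na(align)
  if (window == "reward")
    keep <- keep & !is.na(tr$in_port_at_delivery) & tr$in_port_at_delivery
  idx <- which(keep)
  st <- session$spikes[[neuron_id]]
  counts <- vapply(idx, function(i) {
    a <- align[i]
    sum(st >= a + bounds[1] & st < a + bounds[2])
  }, integer(1))
  structure(list(neuron_id = neuron_id, window = window,
                 counts = counts, trial_numbers = tr$trial_number[idx],
                 outcomes = tr$outcome[idx],
                 window_bounds = bounds),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> neuron ", x$neuron_id, ", ", x$window,
      " window [", x$window_bounds[1], ", ", x$window_bounds[2], ") s, ",
      length(x$counts), " trials, mean count ",
      signif(mean(x$counts), 4), "\n", sep = "")
  invisible(x)
}
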