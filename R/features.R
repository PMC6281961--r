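# Peak-force extraction from indentation force traces.
#
# A force trace is sampled every `dt` ms.  Indentation peaks are located on
# a moving-average-smoothed copy of the trace where the discrete force
# derivative turns from positive to negative; peaks closer together than
# the refractory interval (default 180 ms) are reduced to the largest one,
# which removes finger-shaking ripples and movement pauses.  Contact bouts
# are maximal runs with smoothed force strictly above the contact
# threshold (default 0.1 N).

#' Configuration for force-trace feature extraction
#'
#' @param smoothing_kernel Moving-average kernel width in ms (default 45).
#' @param min_peak_separation Minimum time between two retained peaks in
#'   ms (default 180); the larger of two closer peaks wins.
#' @param contact_threshold Force (N) strictly above which the finger
#'   counts as touching the stimulus (default 0.1).
#' @param dt Sampling interval in ms (default 3).
#' @return A list of class `"feature_config"`.
#' @export
feature_config <- function(smoothing_kernel = 45, min_peak_separation = 180,
                           contact_threshold = 0.1, dt = 3) {
  stopifnot(smoothing_kernel > 0, min_peak_separation > 0,
            contact_threshold >= 0, dt > 0)
  structure(list(smoothing_kernel = smoothing_kernel,
                 min_peak_separation = min_peak_separation,
                 contact_threshold = contact_threshold, dt = dt),
            class = "feature_config")
}

smoothing_window <- function(cfg) {
  w <- round(cfg$smoothing_kernel / cfg$dt)
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L  # centered window must be odd
  w
}

#' Moving-average smoothing of a force signal
#'
#' Centered moving average with a window of `round(kernel / dt)` samples
#' (forced odd; 45 ms at 3 ms sampling = 15 samples).  At the edges the
#' window is truncated to the available samples, which avoids phantom
#' edge peaks.  Output length equals input length.
#'
#' @param force Numeric vector of force samples (uniformly sampled at
#'   `cfg$dt`).
#' @param cfg A [feature_config()].
#' @return Smoothed numeric vector.
#' @export
smooth_force <- function(force, cfg = feature_config()) {
  if (length(force) == 0) stop("empty force signal")
  w <- smoothing_window(cfg)
  if (w == 1L || length(force) == 1L) return(force)
  h <- (w - 1L) %/% 2L
  n <- length(force)
  cs <- cumsum(c(0, force))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect indentation peaks in a (smoothed) force signal
#'
#' Candidate peaks are the samples where the forward difference of the
#' signal changes sign from positive to negative; on a plateau following a
#' rise the peak is placed on the plateau's first sample.  Candidates
#' closer together than `cfg$min_peak_separation` are thinned greedily,
#' highest first, so that only the dominant press of a sub-interval
#' survives.
#'
#' @param force Numeric force samples; pass a smoothed signal (see
#'   [smooth_force()]).
#' @param time Optional sample times in ms (defaults to
#'   `(seq_along(force) - 1) * cfg$dt`).
#' @param cfg A [feature_config()].
#' @return Tibble with columns `index`, `time`, `force`, ordered by time;
#'   zero rows when the signal has no interior maximum.
#' @export
detect_peaks <- function(force, time = NULL, cfg = feature_config()) {
  n <- length(force)
  if (is.null(time)) time <- (seq_len(n) - 1) * cfg$dt
  stopifnot(length(time) == n)
  empty <- tibble::tibble(index = integer(0), time = numeric(0), force = numeric(0))
  if (n < 3) return(empty)
  d <- diff(force)
  # derivatives below numerical resolution count as flat, so that
  # floating-point ripple on constant baselines cannot seed candidates
  d[abs(d) < 1e-9] <- 0
  s <- sign(d)
  # fill zero-runs with the next non-zero sign so that a rise-plateau-fall
  # sequence peaks on the first plateau sample (deterministic tie-break)
  nz_pos <- ifelse(s != 0, seq_along(s), NA_integer_)
  nxt <- rev(cummin(rev(ifelse(is.na(nz_pos), Inf, nz_pos))))
  s_f <- ifelse(is.finite(nxt), s[pmin(nxt, length(s))], 0)
  cand <- which(s_f[-length(s_f)] > 0 & s_f[-1] < 0) + 1L
  if (!length(cand)) return(empty)
  # refractory thinning: keep highest peaks first, suppress neighbors
  ord <- cand[order(-force[cand], time[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        all(abs(time[i] - time[kept]) >= cfg$min_peak_separation)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  tibble::tibble(index = kept, time = time[kept], force = force[kept])
}

#' Segment a trial's force trace into indentations
#'
#' The smoothed trace is cut into contact bouts (maximal runs with force
#' strictly above the contact threshold).  Every retained peak falling
#' inside a bout becomes one indentation carrying the bout's stimulus
#' identity; ordinals number the indentations in time order across the
#' whole trial.  The reported `peak_force` is read from the unsmoothed
#' trace at the detected peak time, so that in noise-free recordings the
#' generating peak force is recovered exactly.
#'
#' @param samples A data frame with columns `t_ms`, `force_N` and
#'   optionally `stimulus_id` (per-sample contacted stimulus,
#'   `"none"` off-stimulus).
#' @param cfg A [feature_config()].
#' @return Tibble with columns `ordinal`, `stimulus_id`, `peak_time`,
#'   `peak_force`, `onset`, `offset`; zero rows if the trace never exceeds
#'   the contact threshold.
#' @export
segment_indentations <- function(samples, cfg = feature_config()) {
  stopifnot(all(c("t_ms", "force_N") %in% names(samples)))
  force <- samples$force_N
  time <- samples$t_ms
  sm <- smooth_force(force, cfg)
  in_contact <- sm > cfg$contact_threshold   # strict: > 0.1 N counts as touch
  runs <- rle(in_contact)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bout_idx <- which(runs$values)
  out <- tibble::tibble(ordinal = integer(0), stimulus_id = character(0),
                        peak_time = numeric(0), peak_force = numeric(0),
                        onset = numeric(0), offset = numeric(0))
  if (!length(bout_idx)) return(out)
  peaks <- detect_peaks(sm, time, cfg)
  peaks <- peaks[sm[peaks$index] > cfg$contact_threshold, , drop = FALSE]
  if (!nrow(peaks)) return(out)
  bout_of <- rep(NA_integer_, length(force))
  for (b in seq_along(bout_idx)) {
    bout_of[starts[bout_idx[b]]:ends[bout_idx[b]]] <- b
  }
  pb <- bout_of[peaks$index]
  if (anyNA(pb)) stop("internal consistency error: detected peak outside any contact bout")
  sid <- if ("stimulus_id" %in% names(samples)) samples$stimulus_id else NULL
  tibble::tibble(
    ordinal = seq_len(nrow(peaks)),
    stimulus_id = vapply(seq_len(nrow(peaks)), function(k) {
      if (is.null(sid)) return(NA_character_)
      b <- pb[k]
      ids <- sid[starts[bout_idx[b]]:ends[bout_idx[b]]]
      ids <- ids[!is.na(ids) & ids != "none"]
      if (!length(ids)) NA_character_ else names(sort(table(ids), decreasing = TRUE))[1]
    }, character(1)),
    peak_time = peaks$time,
    peak_force = force[peaks$index],
    onset = time[starts[bout_idx[pb]]],
    offset = time[ends[bout_idx[pb]]]
  )
}

#' Summarize one trial's indentations into analysis features
#'
#' @param indentations Tibble from [segment_indentations()] (>= 1 row).
#' @param response Optional chosen side (`"left"`/`"right"`) used to fill
#'   `last_touch_matches_choice`.
#' @return One-row tibble with `n_indentations`, `first_peak`,
#'   `middle_peak` (peak of the indentation at ordinal `ceiling(n / 2)`),
#'   `last_peak`, `effort` (sum of all peak forces), `mean_peak`,
#'   `last_touched` and `last_touch_matches_choice`.
#' @export
extract_trial_features <- function(indentations, response = NULL) {
  n <- nrow(indentations)
  if (n < 1) stop("trial has no indentations; flag it unanalyzable instead")
  pk <- indentations$peak_force
  last_id <- indentations$stimulus_id[n]
  tibble::tibble(
    n_indentations = n,
    first_peak = pk[1],
    middle_peak = pk[ceiling(n / 2)],
    last_peak = pk[n],
    effort = sum(pk),
    mean_peak = mean(pk),
    last_touched = last_id,
    last_touch_matches_choice =
      if (is.null(response) || is.na(last_id)) NA else identical(last_id, response)
  )
}

#' Extract per-trial features from a long-format trace table
#'
#' Applies [segment_indentations()] and [extract_trial_features()] to
#' every trial of a trace table (as written by [simulate_dataset()] with
#' `traces = TRUE`).  Trials in which no indentation is detected are
#' excluded and counted in the `qc` attribute of the result.
#'
#' @param traces Long tibble with columns `trial_uid`, `t_ms`, `force_N`,
#'   `stimulus_id` (and any metadata columns, which are ignored here).
#' @param trials Optional trial metadata table with a `trial_uid` column;
#'   matched columns (e.g. `response`, condition labels) are joined onto
#'   the features.
#' @param cfg A [feature_config()].
#' @return Tibble with one row per analyzable trial; the attribute
#'   `qc` holds `list(n_trials, n_excluded, excluded_uids)`.
#' @export
extract_features <- function(traces, trials = NULL, cfg = feature_config()) {
  stopifnot(all(c("trial_uid", "t_ms", "force_N") %in% names(traces)))
  keys <- unique(traces$trial_uid)
  pieces <- split(seq_len(nrow(traces)), traces$trial_uid)
  resp <- NULL
  if (!is.null(trials) && "response" %in% names(trials)) {
    resp <- stats::setNames(trials$response, trials$trial_uid)
  }
  feats <- vector("list", length(keys))
  excluded <- character(0)
  for (k in seq_along(keys)) {
    uid <- as.character(keys[k])
    seg <- segment_indentations(traces[pieces[[uid]], , drop = FALSE], cfg)
    if (nrow(seg) == 0) {
      excluded <- c(excluded, uid)
      next
    }
    f <- extract_trial_features(seg, response = if (is.null(resp)) NULL else resp[[uid]])
    f$trial_uid <- keys[k]
    feats[[k]] <- f
  }
  out <- dplyr::bind_rows(feats)
  if (!is.null(trials)) {
    drop <- intersect(setdiff(names(out), "trial_uid"), names(trials))
    out <- dplyr::left_join(out, trials[, setdiff(names(trials), drop)],
                            by = "trial_uid")
    # the trace channel records stimulus ids while the response is a side;
    # translate the chosen side into its stimulus id to compare
    if (all(c("response", "standard_side", "comparison_id", "category")
            %in% names(out))) {
      chosen_id <- ifelse(out$response == out$standard_side,
                          paste0(as.character(out$category), "_s"),
                          out$comparison_id)
      out$last_touch_matches_choice <- out$last_touched == chosen_id
    }
  }
  attr(out, "qc") <- list(n_trials = length(keys),
                          n_excluded = length(excluded),
                          excluded_uids = excluded)
  out
}
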