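# Generative model for softness-exploration recordings.
#
# Peak indentation forces follow
#   F_peak(i, k, j) = mu + a_i + beta_pred * w_k * [blocked]
#                     + (beta_sens * w_k * gain + gamma_drift) * s_j + eps,
# where a_i is a participant offset, w_k the centered category weight
# (soft to hard), s_j = (j - 1) / (n - 1) the indentation's relative
# position within the trial (0 = first, 1 = last), gain the motivation
# multiplier on the sensory slope, and eps Gaussian noise whose SD tapers
# from sd_trial at the first indentation to sd_last_ratio * sd_trial at
# the last (the convergence of movement parameters).  The 2AFC response
# comes from a cumulative-evidence signal-detection observer whose
# sensitivity grows with the square root of the number of indentations
# and, for hard stimuli, with indentation force.

#' Configuration of the planted force-adjustment effects
#'
#' @param mu_force Baseline peak indentation force (N).
#' @param beta_pred Predictive adjustment slope (N per contrast-weight
#'   unit): how strongly peak forces follow the softness category when the
#'   category is predictable (blocked presentation).
#' @param beta_sens Sensory adjustment slope (N per contrast-weight unit):
#'   the category-dependent growth from first to last indentation.
#' @param gamma_drift Category-independent increase of peak force from
#'   first to last indentation (N).
#' @param motivation_gain Multiplier (> 0) applied to `beta_sens` and to
#'   the indentation count in motivation-part trials; 1 = no motivation
#'   effect.
#' @param sd_participant SD of the participant force offsets (N).
#' @param sd_trial SD of the per-indentation peak-force noise (N) at the
#'   first indentation.
#' @param sd_last_ratio Noise SD at the last indentation relative to the
#'   first (< 1 plants the convergence detected by
#'   [cov_convergence_test()]).
#' @param sd_noise Sample-level force sensor noise SD (N) in rendered
#'   traces.
#' @param shaking_amplitude Amplitude (N) of sub-refractory finger-shaking
#'   ripples added to rendered pulses; 0 disables them.
#' @param shaking_period Ripple period in ms; must stay below the 180 ms
#'   refractory interval so ripples are artifacts, not indentations.
#' @param n_indent_median Population median number of indentations per
#'   trial.
#' @param n_indent_sdlog_participant,n_indent_sdlog_trial Log-normal
#'   dispersion of the indentation count across participants and across
#'   trials; counts are rounded and truncated at 2.
#' @param p_switch Probability of switching stimulus between consecutive
#'   indentations.
#' @param p_last_touch_choice Probability that the last-touched stimulus
#'   is the one about to be chosen.
#' @param pulse_duration Duration (ms) of one rendered indentation pulse.
#' @param gap_range Range (ms) of inter-pulse gaps in rendered traces;
#'   the lower bound must exceed the 180 ms refractory interval.
#' @return A list of class `"effect_config"`.
#' @export
effect_config <- function(mu_force = 4, beta_pred = 0.05, beta_sens = 0.1,
                          gamma_drift = 0.3, motivation_gain = 1.5,
                          sd_participant = 0.8, sd_trial = 0.5,
                          sd_last_ratio = 0.7, sd_noise = 0.05,
                          shaking_amplitude = 0.3, shaking_period = 60,
                          n_indent_median = 6,
                          n_indent_sdlog_participant = 0.25,
                          n_indent_sdlog_trial = 0.3,
                          p_switch = 0.5, p_last_touch_choice = 0.75,
                          pulse_duration = 300, gap_range = c(250, 450)) {
  stopifnot(mu_force > 0, motivation_gain > 0,
            sd_participant >= 0, sd_trial >= 0, sd_noise >= 0,
            sd_last_ratio > 0,
            shaking_amplitude >= 0, shaking_period < 180, shaking_period > 0,
            n_indent_median >= 2,
            p_switch >= 0, p_switch <= 1,
            p_last_touch_choice >= 0, p_last_touch_choice <= 1,
            pulse_duration > 0, length(gap_range) == 2,
            gap_range[1] > 180, gap_range[2] >= gap_range[1])
  structure(as.list(environment()), class = "effect_config")
}

#' Configuration of the 2AFC softness observer
#'
#' The observer accumulates softness evidence over indentations:
#' `d' = (delta_c / (w * c_std)) * sqrt(gain * n) * boost`, with `w` the
#' category's Weber fraction, `n` the number of indentations, and `boost`
#' a force bonus `1 + force_benefit_hard * (F - mu) / mu` applied to hard
#' stimuli only (higher indentation forces improve discrimination
#' especially for hard objects).  The probability of a correct 2AFC
#' response is `pnorm(d' / sqrt(2))`.
#'
#' @param weber_fraction Optional named per-category vector of Weber
#'   fractions; when `NULL` they are interpolated from `weber` at each
#'   standard's compliance.
#' @param evidence_gain_per_indentation Evidence units gained per
#'   indentation (> 0 for a useful observer; 0 yields chance performance).
#' @param force_benefit_hard Discriminability bonus per unit of relative
#'   force increase, hard category only.
#' @param weber A [weber_spec()] used when `weber_fraction` is `NULL`.
#' @return A list of class `"observer_config"`.
#' @export
observer_config <- function(weber_fraction = NULL,
                            evidence_gain_per_indentation = 1,
                            force_benefit_hard = 0.5,
                            weber = weber_spec()) {
  stopifnot(evidence_gain_per_indentation >= 0, force_benefit_hard >= 0)
  structure(list(weber_fraction = weber_fraction,
                 evidence_gain_per_indentation = evidence_gain_per_indentation,
                 force_benefit_hard = force_benefit_hard,
                 weber = weber),
            class = "observer_config")
}

#' Analytic probability of a correct 2AFC softness response
#'
#' @param c_standard,c_comparison Compliances (mm/N) of the trial's
#'   standard and comparison stimulus.
#' @param category Category label(s) (force bonus applies to `"hard"`).
#' @param n_indentations Indentations performed in the trial.
#' @param mean_force Mean peak force of the trial (N).
#' @param mu_force Baseline force (N) against which the force bonus is
#'   measured.
#' @param observer An [observer_config()].
#' @return Probability/ies of a correct response, in [0.5, 1).
#' @export
observer_p_correct <- function(c_standard, c_comparison, category,
                               n_indentations, mean_force, mu_force,
                               observer = observer_config()) {
  wf <- if (is.null(observer$weber_fraction)) {
    weber_fraction_at(c_standard, observer$weber)
  } else {
    unname(observer$weber_fraction[as.character(category)])
  }
  jnds <- abs(c_comparison - c_standard) / (wf * c_standard)
  boost <- ifelse(as.character(category) == "hard",
                  pmax(0.1, 1 + observer$force_benefit_hard *
                              (mean_force - mu_force) / mu_force),
                  1)
  dprime <- jnds * sqrt(observer$evidence_gain_per_indentation * n_indentations) * boost
  stats::pnorm(dprime / sqrt(2))
}

#' One half-sine indentation pulse on the sampling grid
#'
#' @param peak_force Apex force (N, > 0).
#' @param duration Pulse duration in ms (rounded to an even multiple of
#'   `dt` so the apex falls on the grid).
#' @param dt Sampling interval (ms).
#' @return Tibble with `t_ms` and `force_N`; the maximum sample equals
#'   `peak_force` exactly, at `t = duration / 2`.
#' @export
simulate_indentation_pulse <- function(peak_force, duration, dt = 3) {
  stopifnot(peak_force > 0)
  if (duration < 2 * dt) stop("duration must be at least 2 * dt")
  half <- round(duration / (2 * dt))
  duration <- 2 * half * dt
  t <- seq(0, duration, by = dt)
  tibble::tibble(t_ms = t, force_N = peak_force * sin(pi * t / duration))
}

other_side <- function(side) ifelse(side == "left", "right", "left")

draw_participants <- function(pids, effects, seed) {
  set.seed(derive_seed(seed, 101))
  np <- length(pids)
  tibble::tibble(
    participant = pids,
    force_offset = stats::rnorm(np, 0, effects$sd_participant),
    n_indent_median = effects$n_indent_median *
      exp(stats::rnorm(np, 0, effects$n_indent_sdlog_participant))
  )
}

compliance_lookup <- function(stimuli) {
  stats::setNames(stimuli$compliance, stimuli$id)
}

#' Simulate a dataset of softness-exploration trials
#'
#' Draws, for every trial of a schedule, the indentation count, the
#' planted peak forces, the stimulus visit sequence, and the observer's
#' 2AFC response; optionally renders full force/displacement traces at
#' 3 ms resolution.  All randomness derives from `seed`: participant
#' parameters, per-trial feature draws, and trace rendering use three
#' separate derived streams, so the trial table is identical whether or
#' not traces are rendered.
#'
#' @param schedule A schedule tibble from the design builders.
#' @param effects An [effect_config()].
#' @param observer An [observer_config()].
#' @param stimuli Stimulus table; defaults to [exp1_stimuli()] or
#'   [exp2_stimuli()] according to the schedule's design label.
#' @param seed Integer seed.
#' @param traces If `TRUE`, also render per-sample force traces.
#' @param dt Sampling interval of rendered traces (ms).
#' @return A list of class `"haptic_dataset"` with
#'   `trials` (schedule columns plus `trial_uid`, `n_indentations`,
#'   `first_peak`, `middle_peak`, `last_peak`, `effort`, `mean_peak`,
#'   `p_correct`, `correct`, `response`, `last_touched`,
#'   `last_touch_matches_choice`), `indentations` (planted per-indentation
#'   peaks and stimulus ids), `participants`, `traces` (long sample table
#'   or `NULL`) and `config` (the generating configurations).
#' @export
simulate_dataset <- function(schedule, effects = effect_config(),
                             observer = observer_config(), stimuli = NULL,
                             seed = 1L, traces = FALSE, dt = 3) {
  label <- attr(schedule, "design_label")
  if (is.null(stimuli)) {
    stimuli <- if (identical(label, "exp2")) exp2_stimuli() else exp1_stimuli()
  }
  n_tr <- nrow(schedule)
  stopifnot(n_tr >= 1)
  pids <- sort(unique(schedule$participant))
  participants <- draw_participants(pids, effects, seed)
  idx_p <- match(schedule$participant, pids)

  cat_chr <- as.character(schedule$category)
  # planted category weights span the design's full category set (the
  # factor levels), not just the categories present in this subset
  cat_levels <- if (is.factor(schedule$category)) {
    levels(schedule$category)
  } else {
    levels(category_factor(cat_chr))
  }
  w_by_cat <- stats::setNames(contrast_weights(length(cat_levels)), cat_levels)
  w <- unname(w_by_cat[cat_chr])
  blocked <- schedule$presentation_order == "blocked"
  gain <- ifelse(schedule$motivation_part == "motivation",
                 effects$motivation_gain, 1)

  comp <- compliance_lookup(stimuli)
  std_ids <- paste0(cat_chr, "_s")
  if (!all(std_ids %in% names(comp)) ||
      !all(schedule$comparison_id %in% names(comp))) {
    stop("schedule refers to stimuli missing from the stimulus set")
  }
  c_std <- unname(comp[std_ids])
  c_cmp <- unname(comp[schedule$comparison_id])

  set.seed(derive_seed(seed, 202))
  n_ind <- pmax(2L, as.integer(round(exp(
    log(participants$n_indent_median[idx_p] * gain) +
      stats::rnorm(n_tr, 0, effects$n_indent_sdlog_trial)))))
  tot <- sum(n_ind)
  tid <- rep.int(seq_len(n_tr), n_ind)
  j <- sequence(n_ind)
  srel <- (j - 1) / (n_ind[tid] - 1)
  sd_j <- effects$sd_trial * (1 + (effects$sd_last_ratio - 1) * srel)
  peaks <- effects$mu_force + participants$force_offset[idx_p][tid] +
    effects$beta_pred * w[tid] * blocked[tid] +
    (effects$beta_sens * w[tid] * gain[tid] + effects$gamma_drift) * srel +
    stats::rnorm(tot, 0, sd_j)
  peaks <- pmax(peaks, 0.2)  # physical floor: a press always exerts force

  ends <- cumsum(n_ind)
  starts <- ends - n_ind + 1L
  cs <- cumsum(peaks)
  effort <- cs[ends] - cs[starts] + peaks[starts]
  mean_peak <- effort / n_ind

  # stimulus visit sequence: start on the cued side, switch with p_switch
  sw <- stats::runif(tot) < effects$p_switch
  sw[starts] <- FALSE
  cssw <- cumsum(sw)
  parity <- (cssw - cssw[starts][tid]) %% 2
  start_side <- schedule$first_touch_side
  side <- ifelse(parity == 0, start_side[tid], other_side(start_side[tid]))

  # observer response
  p_c <- observer_p_correct(c_std, c_cmp, cat_chr, n_ind, mean_peak,
                            effects$mu_force, observer)
  correct <- stats::runif(n_tr) < p_c
  comparison_side <- other_side(schedule$standard_side)
  softer_side <- ifelse(c_cmp > c_std, comparison_side, schedule$standard_side)
  response <- ifelse(correct, softer_side, other_side(softer_side))
  # the last touch reaffirms the upcoming choice with high probability
  lt_match <- stats::runif(n_tr) < effects$p_last_touch_choice
  last_touched <- ifelse(lt_match, response, other_side(response))
  side[ends] <- last_touched

  trial_uid <- paste0("p", schedule$participant, ".s", schedule$session,
                      ".b", schedule$block, ".t", schedule$trial)

  trials <- tibble::as_tibble(schedule)
  trials$trial_uid <- trial_uid
  trials$n_indentations <- n_ind
  trials$first_peak <- peaks[starts]
  trials$middle_peak <- peaks[starts + as.integer(ceiling(n_ind / 2)) - 1L]
  trials$last_peak <- peaks[ends]
  trials$effort <- effort
  trials$mean_peak <- mean_peak
  trials$p_correct <- p_c
  trials$correct <- correct
  trials$response <- response
  trials$last_touched <- last_touched
  trials$last_touch_matches_choice <- lt_match

  indentations <- tibble::tibble(
    trial_uid = trial_uid[tid], ordinal = j,
    stimulus_side = side, peak_force = peaks)

  trace_tbl <- NULL
  if (traces) {
    stim_of_side <- function(k) {
      ifelse(indentations$stimulus_side[starts[k]:ends[k]] ==
               schedule$standard_side[k],
             std_ids[k], schedule$comparison_id[k])
    }
    set.seed(derive_seed(seed, 303))
    pieces <- vector("list", n_tr)
    apex_times <- vector("list", n_tr)
    for (k in seq_len(n_tr)) {
      tr <- render_trial_trace(
        peak_forces = peaks[starts[k]:ends[k]],
        stimulus_ids = stim_of_side(k),
        compliances = comp, effects = effects, dt = dt)
      apex_times[[k]] <- attr(tr, "apex_times")
      tr$trial_uid <- trial_uid[k]
      pieces[[k]] <- tr
    }
    indentations$peak_time <- unlist(apex_times)
    trace_tbl <- dplyr::bind_rows(pieces)
    meta <- trials[, c("trial_uid", "participant", "session", "block", "trial")]
    trace_tbl <- dplyr::left_join(trace_tbl, meta, by = "trial_uid")
  }

  structure(list(trials = trials, indentations = indentations,
                 participants = participants, traces = trace_tbl,
                 config = list(effects = effects, observer = observer,
                               seed = seed, design_label = label)),
            class = "haptic_dataset")
}

# Render one trial's force/displacement trace from planted peaks.
# Pulses are half-sines with apexes on the sampling grid, separated by
# gaps longer than the 180 ms refractory interval; optional shaking
# ripples (period < 180 ms) and sensor noise are added inside contact.
render_trial_trace <- function(peak_forces, stimulus_ids, compliances,
                               effects, dt = 3) {
  n <- length(peak_forces)
  half <- round(effects$pulse_duration / (2 * dt))
  dur <- 2 * half * dt
  npulse <- 2 * half + 1
  gaps <- round(stats::runif(n, effects$gap_range[1], effects$gap_range[2]) / dt) * dt
  onsets <- cumsum(gaps + c(0, rep(dur, n - 1)))
  total <- onsets[n] + dur + 150
  t <- seq(0, total, by = dt)
  force <- numeric(length(t))
  sid <- rep("none", length(t))
  phase <- stats::runif(n, 0, 2 * pi)
  for (k in seq_len(n)) {
    i0 <- onsets[k] / dt + 1
    idx <- i0:(i0 + npulse - 1)
    env <- sin(pi * seq(0, dur, by = dt) / dur)
    f <- peak_forces[k] * env
    if (effects$shaking_amplitude > 0) {
      f <- f + effects$shaking_amplitude * env *
        sin(2 * pi * (t[idx] - onsets[k]) / effects$shaking_period + phase[k])
    }
    if (effects$sd_noise > 0) {
      f <- f + stats::rnorm(npulse, 0, effects$sd_noise) * (env > 0)
    }
    force[idx] <- pmax(f, 0)
    sid[idx[env > 0]] <- stimulus_ids[k]
  }
  displacement <- ifelse(sid == "none", 0, unname(compliances[sid]) * force)
  displacement[is.na(displacement)] <- 0
  out <- tibble::tibble(t_ms = t, force_N = force,
                        displacement_mm = displacement, stimulus_id = sid)
  attr(out, "apex_times") <- onsets + dur / 2
  out
}

#' Simulate a single trial, including its force trace
#'
#' Convenience wrapper around [simulate_dataset()] for a one-row
#' schedule.
#'
#' @param spec One row of a schedule tibble.
#' @inheritParams simulate_dataset
#' @return List with `samples` (the trace), `features` (the trial row)
#'   and `indentations` (planted peaks).
#' @export
simulate_trial <- function(spec, effects = effect_config(),
                           observer = observer_config(), stimuli = NULL,
                           seed = 1L, dt = 3) {
  stopifnot(nrow(spec) == 1)
  ds <- simulate_dataset(spec, effects, observer, stimuli,
                         seed = seed, traces = TRUE, dt = dt)
  list(samples = ds$traces, features = ds$trials,
       indentations = ds$indentations)
}

#' Simulate questionnaire item responses with a planted motivation shift
#'
#' Every participant answers the full item set (PMI, PANAVA, SDS) once
#' after each experimental part.  A latent motivation level (percent
#' scale) is drawn per participant; in the motivation part it is raised
#' by a planted shift, except for a "manipulation failure" fraction of
#' participants whose shift is non-positive.  Item responses are
#' generated around the latent level with integer rounding and clamping,
#' and social-desirability responses are independent coin flips.
#'
#' @param n_participants Number of participants.
#' @param motivation_shift Planted mean motivation increase (percent
#'   points) for successfully manipulated participants.
#' @param manipulation_failure_rate Fraction of participants (rounded to
#'   a count) whose manipulation fails.
#' @param seed Integer seed.
#' @param key Item key (see [default_item_key()]).
#' @param baseline_mean,baseline_sd Latent motivation level (percent) in
#'   the demotivation part.
#' @param shift_sd SD of the planted shift across successfully
#'   manipulated participants.
#' @param failure_shift Mean planted shift (percent points, negative) for
#'   failed manipulations; draws are capped at -2 so that failures never
#'   shift upward.
#' @param item_sd SD of the per-item response noise (scale points).
#' @return List with `items` (long response table: `participant`, `part`,
#'   `instrument`, `item_id`, `response`) and `truth` (`participant`,
#'   `failed`, `shift`, `baseline`).
#' @export
simulate_questionnaires <- function(n_participants,
                                    motivation_shift = 10,
                                    manipulation_failure_rate = 14 / 30,
                                    seed = 1L,
                                    key = default_item_key(),
                                    baseline_mean = 40, baseline_sd = 8,
                                    shift_sd = 4, item_sd = 0.8,
                                    failure_shift = -4) {
  stopifnot(n_participants >= 1,
            manipulation_failure_rate >= 0, manipulation_failure_rate <= 1)
  set.seed(derive_seed(seed, 404))
  n_fail <- round(n_participants * manipulation_failure_rate)
  failed <- seq_len(n_participants) %in%
    sample.int(n_participants, n_fail)
  baseline <- stats::rnorm(n_participants, baseline_mean, baseline_sd)
  # failed manipulations shift clearly downward (never upward), so the
  # planted classification is recoverable by the inclusion criterion
  stopifnot(failure_shift < 0)
  shift <- ifelse(failed,
                  pmin(-2, stats::rnorm(n_participants, failure_shift, 2)),
                  stats::rnorm(n_participants, motivation_shift, shift_sd))
  kp <- key_for(key, "PMI")
  ka <- key_for(key, "PANAVA")
  ks <- key_for(key, "SDS")
  rows <- vector("list", 2 * n_participants)
  ri <- 0
  for (p in seq_len(n_participants)) {
    for (part in c("demotivation", "motivation")) {
      pct <- baseline[p] + if (part == "motivation") shift[p] else 0
      pct <- min(max(pct, 2), 98)
      # PMI: polarity-coded item mean implied by the target percent
      v5 <- pmin(pmax(round((10 + 40 * pct / 100) / 10 +
                              stats::rnorm(10, 0, item_sd)), 1), 5)
      pmi_resp <- ifelse(kp$polarity == "negative", 6 - v5, v5)
      # PANAVA: positive items rise with the latent level, negative fall
      vfrac <- pct / 100
      pos_mu <- 1 + 6 * vfrac
      neg_mu <- 7 - 6 * vfrac
      pan_resp <- pmin(pmax(round(
        ifelse(ka$polarity == "negative", neg_mu, pos_mu) +
          stats::rnorm(10, 0, item_sd)), 1), 7)
      sds_resp <- stats::rbinom(4, 1, 0.5)
      ri <- ri + 1
      rows[[ri]] <- tibble::tibble(
        participant = p, part = part,
        instrument = c(kp$instrument, ka$instrument, ks$instrument),
        item_id = c(kp$item_id, ka$item_id, ks$item_id),
        response = c(pmi_resp, pan_resp, sds_resp))
    }
  }
  list(items = dplyr::bind_rows(rows),
       truth = tibble::tibble(participant = seq_len(n_participants),
                              failed = failed, shift = shift,
                              baseline = baseline))
}
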