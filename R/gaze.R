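#' Simulate a gaze trace for one trial
#'
#' Builds a 1000 Hz gaze trace following the instructed fixation sequence of
#' a trial: piecewise-constant fixations with Gaussian jitter and linear
#' saccade ramps (40 ms, which for any inter-frame saccade exceeds the
#' 150 deg/s velocity criterion). With \code{compliant = FALSE} a
#' rule-violating event appropriate to the condition is injected: a large
#' excursion during an epoch for \code{NO_SACCADE}, an extra saccade after
#' wheel onset for \code{SAC_AFTER_1}, and omission of a required saccade
#' for \code{SAC_AFTER_2} / \code{TWO_SACCADES}.
#'
#' @param trial One-row session data frame (see
#'   \code{\link{generate_session}}).
#' @param compliant Logical; inject a violation when FALSE.
#' @param noise_sd Gaussian jitter sd (deg) added to every sample.
#' @param seed Integer seed.
#' @param task A \code{\link{locus_task}}.
#' @return Data frame of class \code{c("locus_gaze","data.frame")} with
#'   columns time_ms, x, y, pupil, valid.
#' @export
simulate_gaze <- function(trial, compliant = TRUE, noise_sd = 0, seed = 1,
                          task = locus_task()) {
  stopifnot(noise_sd >= 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  dur_ms <- round((trial$t_wheel_on + 1.5) * 1000)
  tms <- seq_len(dur_ms) - 1
  fix1 <- c(trial$fix1_x, trial$fix1_y)
  fix2 <- c(trial$fix2_x, trial$fix2_y)
  wheel <- c(trial$wheel_x, trial$wheel_y)
  s1 <- round((trial$t_item1_off + task$saccade_latency) * 1000)
  s2 <- round((trial$t_wheel_on + task$saccade_latency) * 1000)
  ramp_ms <- 40
  cond <- trial$condition
  do_s1 <- cond %in% c("SAC_AFTER_1", "TWO_SACCADES")
  do_s2 <- cond %in% c("SAC_AFTER_2", "TWO_SACCADES")
  if (!compliant) {
    if (cond == "SAC_AFTER_2") do_s2 <- FALSE      # stays at fixation
    if (cond == "TWO_SACCADES") do_s2 <- FALSE     # misses the wheel saccade
  }
  pos <- matrix(rep(fix1, each = dur_ms), ncol = 2)
  move <- function(pos, t0, from, to) {
    ramp <- t0:(t0 + ramp_ms - 1)
    frac <- seq(0, 1, length.out = ramp_ms)
    pos[ramp, ] <- cbind(from[1] + frac * (to[1] - from[1]),
                         from[2] + frac * (to[2] - from[2]))
    after <- (t0 + ramp_ms):dur_ms
    pos[after, ] <- matrix(rep(to, each = length(after)), ncol = 2)
    pos
  }
  if (do_s1) pos <- move(pos, s1, fix1, fix2)
  if (do_s2) pos <- move(pos, s2, if (do_s1) fix2 else fix1, wheel)
  if (!compliant && cond == "NO_SACCADE") {
    # 10 deg excursion and return inside the item-2 epoch
    t0 <- round((trial$t_item2_on + 0.5) * 1000)
    away <- fix1 + c(10, 0)
    pos <- move(pos, t0, fix1, away)
    pos <- move(pos, t0 + 200, away, fix1)
  }
  if (!compliant && cond == "SAC_AFTER_1") {
    # forbidden saccade after wheel onset (wheel == frame 2 here, so move away)
    t0 <- round((trial$t_wheel_on + 0.3) * 1000)
    pos <- move(pos, t0, fix2, fix2 + c(10, 0))
  }
  if (noise_sd > 0) {
    # temporally correlated jitter (smoothed white noise rescaled to
    # noise_sd), emulating slow fixational drift rather than white noise,
    # whose sample-to-sample velocity would be unphysiological at 1000 Hz
    jit <- matrix(stats::rnorm(2 * dur_ms), ncol = 2)
    jit <- apply(jit, 2, function(v)
      stats::filter(v, rep(1 / 51, 51), sides = 2, circular = TRUE))
    jit <- jit * (noise_sd / stats::sd(as.vector(jit)))
    pos <- pos + jit
  }
  out <- data.frame(time_ms = tms, x = pos[, 1], y = pos[, 2],
                    pupil = 1000 + stats::rnorm(dur_ms, 0, 2),
                    valid = TRUE)
  class(out) <- c("locus_gaze", "data.frame")
  out
}

#' Mask blink intervals in a gaze trace
#'
#' Marks as invalid all samples where the recorded pupil diameter is zero,
#' plus samples within \code{window_ms} of such an interval whose pupil
#' rate-of-change exceeds a threshold (by default the 99.5th percentile of
#' the absolute rate over the whole trace), to catch the ramp artefacts that
#' flank a blink.
#'
#' @param trace A gaze data frame (time_ms, x, y, pupil, valid).
#' @param rate_quantile Quantile of |d pupil / dt| defining "dramatic"
#'   change.
#' @param window_ms Half-width of the pre/post-blink window searched for
#'   ramp artefacts.
#' @return The trace with its \code{valid} column updated.
#' @export
remove_blinks <- function(trace, rate_quantile = 0.995, window_ms = 50) {
  v <- trace$valid & trace$pupil > 0
  if (all(trace$pupil > 0)) return(trace)
  rate <- abs(c(0, diff(trace$pupil)) / c(1, pmax(diff(trace$time_ms), 1)))
  zero <- which(trace$pupil <= 0)
  near <- rep(FALSE, nrow(trace))
  for (i in zero) {
    w <- max(1, i - window_ms):min(nrow(trace), i + window_ms)
    near[w] <- TRUE
  }
  # "dramatic" relative to the background rate away from any blink
  bg <- rate[trace$pupil > 0 & !near]
  thr <- if (length(bg)) stats::quantile(bg, rate_quantile, names = FALSE) else 0
  trace$valid <- v & !(near & rate > thr)
  trace
}

# runs of TRUE in a logical vector: matrix of (start, end) indices
.runs <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect fixations on a target
#'
#' Maximal runs of valid samples whose gaze lies within \code{radius} of the
#' target and which last at least \code{min_dur_ms}.
#'
#' @param trace A gaze data frame.
#' @param target Numeric length-2 target coordinates (deg).
#' @param radius Dispersion criterion (deg).
#' @param min_dur_ms Minimum duration (ms).
#' @return Data frame with onset_ms, duration_ms, cx, cy (centroid).
#' @export
detect_fixations <- function(trace, target, radius = 2.5, min_dur_ms = 150) {
  if (nrow(trace) == 0 || !any(trace$valid)) stop("no valid gaze samples")
  d <- sqrt((trace$x - target[1])^2 + (trace$y - target[2])^2)
  ok <- trace$valid & d <= radius
  runs <- .runs(ok)
  if (nrow(runs) == 0)
    return(data.frame(onset_ms = numeric(0), duration_ms = numeric(0),
                      cx = numeric(0), cy = numeric(0)))
  dur <- trace$time_ms[runs[, 2]] - trace$time_ms[runs[, 1]] + 1
  keep <- dur >= min_dur_ms
  runs <- runs[keep, , drop = FALSE]
  data.frame(onset_ms = trace$time_ms[runs[, 1]],
             duration_ms = dur[keep],
             cx = vapply(seq_len(nrow(runs)), function(i)
               mean(trace$x[runs[i, 1]:runs[i, 2]]), numeric(1)),
             cy = vapply(seq_len(nrow(runs)), function(i)
               mean(trace$y[runs[i, 1]:runs[i, 2]]), numeric(1)))
}

#' Detect saccades in a gaze trace
#'
#' Velocity is estimated by central differences after 5-sample median
#' smoothing of each coordinate. A saccade is a run of samples with speed
#' above \code{vel_thresh} lasting longer than \code{min_dur_ms} whose net
#' displacement (from the sample before the run to the sample after it)
#' exceeds \code{min_amp} - the radius of the perifoveal field.
#'
#' @param trace A gaze data frame.
#' @param vel_thresh Velocity criterion (deg/s).
#' @param min_amp Amplitude criterion on net displacement (deg).
#' @param min_dur_ms Duration criterion (ms).
#' @return Data frame with onset_ms, duration_ms, amplitude, peak_velocity.
#' @export
detect_saccades <- function(trace, vel_thresh = 150, min_amp = 9.2,
                            min_dur_ms = 10) {
  n <- nrow(trace)
  if (n < 7)
    return(data.frame(onset_ms = numeric(0), duration_ms = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0)))
  xs <- stats::runmed(trace$x, 5)
  ys <- stats::runmed(trace$y, 5)
  # central differences over a +/- 5 ms stencil: robust to sample jitter
  # while a real saccade (>150 deg/s for >10 ms) still saturates it
  k <- 5L
  lead <- c((k + 1):n, rep(n, k))
  lag <- c(rep(1, k), 1:(n - k))
  dt_ms <- pmax(trace$time_ms[lead] - trace$time_ms[lag], 1)
  vx <- (xs[lead] - xs[lag]) / dt_ms * 1000
  vy <- (ys[lead] - ys[lag]) / dt_ms * 1000
  speed <- sqrt(vx^2 + vy^2)
  ok <- trace$valid & speed > vel_thresh
  runs <- .runs(ok)
  out <- data.frame(onset_ms = numeric(0), duration_ms = numeric(0),
                    amplitude = numeric(0), peak_velocity = numeric(0))
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]; b <- runs[i, 2]
    dur <- trace$time_ms[b] - trace$time_ms[a] + 1
    if (dur <= min_dur_ms) next
    pre <- max(1, a - 1); post <- min(n, b + 1)
    amp <- sqrt((xs[post] - xs[pre])^2 + (ys[post] - ys[pre])^2)
    if (amp <= min_amp) next
    out <- rbind(out, data.frame(onset_ms = trace$time_ms[a],
                                 duration_ms = dur, amplitude = amp,
                                 peak_velocity = max(speed[a:b])))
  }
  out
}

# clip a trace to [t0, t1) seconds
.epoch <- function(trace, t0, t1) {
  trace[trace$time_ms >= t0 * 1000 & trace$time_ms < t1 * 1000, , drop = FALSE]
}

#' Classify per-trial task compliance
#'
#' Applies the condition-specific rule table to detected fixations and
#' saccades. Fixation epochs are 1 s post onset of item 1, item 2 and the
#' colour wheel; a "fixation on an item" means a fixation (>= 150 ms within
#' 2.5 deg) on the fixation cross of the frame in which that item appeared.
#' Rules: \code{NO_SACCADE} - fixations on both items, no large saccade in
#' any epoch; \code{SAC_AFTER_1} - fixations on both items, a saccade
#' between item-1 offset and item-2 onset, none after wheel onset;
#' \code{SAC_AFTER_2} - fixations on both items, a saccade in the wheel
#' epoch; \code{TWO_SACCADES} - fixations on both items and both saccades.
#' If every sample of a required epoch is masked (e.g. by blinks) the trial
#' is indeterminate rather than non-compliant.
#'
#' @param trace A gaze data frame for the trial (after
#'   \code{\link{remove_blinks}}).
#' @param trial One-row session data frame.
#' @param task A \code{\link{locus_task}}.
#' @return List with \code{compliant} (TRUE/FALSE/NA) and \code{reason}
#'   (character code; "ok", "indeterminate", or the first violated rule).
#' @export
classify_compliance <- function(trace, trial, task = locus_task()) {
  fix1 <- c(trial$fix1_x, trial$fix1_y)
  fix2 <- c(trial$fix2_x, trial$fix2_y)
  ep1 <- .epoch(trace, trial$t_item1_on, trial$t_item1_on + 1)
  ep2 <- .epoch(trace, trial$t_item2_on, trial$t_item2_on + 1)
  epw <- .epoch(trace, trial$t_wheel_on, trial$t_wheel_on + 1)
  if (!any(ep1$valid) || !any(ep2$valid) || !any(epw$valid))
    return(list(compliant = NA, reason = "indeterminate"))
  fx1 <- detect_fixations(ep1, fix1)
  if (nrow(fx1) == 0)
    return(list(compliant = FALSE, reason = "no_fixation_item1"))
  fx2 <- detect_fixations(ep2, fix2)
  if (nrow(fx2) == 0)
    return(list(compliant = FALSE, reason = "no_fixation_item2"))
  sac_between <- detect_saccades(.epoch(trace, trial$t_item1_off, trial$t_item2_on))
  sac_wheel <- detect_saccades(epw)
  cond <- trial$condition
  if (cond == "NO_SACCADE") {
    for (ep in list(ep1, ep2, epw))
      if (nrow(detect_saccades(ep)) > 0)
        return(list(compliant = FALSE, reason = "saccade_in_epoch"))
  } else if (cond == "SAC_AFTER_1") {
    if (nrow(sac_between) == 0)
      return(list(compliant = FALSE, reason = "missing_frame_saccade"))
    if (nrow(sac_wheel) > 0)
      return(list(compliant = FALSE, reason = "saccade_after_wheel"))
  } else if (cond == "SAC_AFTER_2") {
    if (nrow(sac_wheel) == 0)
      return(list(compliant = FALSE, reason = "missing_wheel_saccade"))
  } else if (cond == "TWO_SACCADES") {
    if (nrow(sac_between) == 0)
      return(list(compliant = FALSE, reason = "missing_frame_saccade"))
    if (nrow(sac_wheel) == 0)
      return(list(compliant = FALSE, reason = "missing_wheel_saccade"))
  } else stop("unknown condition: ", cond)
  list(compliant = TRUE, reason = "ok")
}

#' Shortest-arc colour error
#'
#' Absolute angular distance between two colour-wheel angles, in [0, pi].
#'
#' @param a,b Angles in radians.
#' @export
colour_error <- function(a, b) abs(wrap_angle(a - b))

#' Behavioural error summary and saccade cost
#'
#' Computes, over compliant trials, the mean Euclidean location error and
#' mean shortest-arc colour error per condition x probed item, and the
#' saccade cost: the mean location error in the two-saccades condition minus
#' the mean in the matched saccade-after-the-other-item condition (for a
#' probed item 1 that is \code{SAC_AFTER_2}; for item 2, \code{SAC_AFTER_1}),
#' isolating the extra error caused by a saccade made right after the probed
#' item.
#'
#' @param session A \code{\link{generate_session}} data frame.
#' @param responses Matching response data frame.
#' @param compliant Logical vector (one per trial); NA-compliant trials are
#'   excluded too.
#' @return Object of class \code{"locus_behaviour"}: \code{table}
#'   (condition x item means and counts; empty cells flagged NA),
#'   \code{saccade_cost} (deg), \code{n_excluded}.
#' @export
behavioural_errors <- function(session, responses,
                               compliant = rep(TRUE, nrow(session))) {
  m <- match(session$trial_id, responses$trial_id)
  responses <- responses[m, ]
  keep <- !is.na(compliant) & compliant
  tgt <- item_location(session, session$probed)
  loc_err <- sqrt((responses$resp_x - tgt[, 1])^2 +
                  (responses$resp_y - tgt[, 2])^2)
  col_true <- ifelse(session$probed == 1, session$item1_col, session$item2_col)
  col_err <- colour_error(responses$resp_col, col_true)
  cells <- expand.grid(condition = .conditions, item = 1:2,
                       stringsAsFactors = FALSE)
  cells$mean_loc_err <- cells$mean_col_err <- NA_real_
  cells$n <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- keep & session$condition == cells$condition[i] &
      session$probed == cells$item[i]
    cells$n[i] <- sum(sel)
    if (any(sel)) {
      cells$mean_loc_err[i] <- mean(loc_err[sel])
      cells$mean_col_err[i] <- mean(col_err[sel])
    }
  }
  cost_cell <- function(cond, item) {
    v <- cells$mean_loc_err[cells$condition == cond & cells$item == item]
    if (length(v) == 0) NA_real_ else v
  }
  cost <- mean(c(cost_cell("TWO_SACCADES", 1) - cost_cell("SAC_AFTER_2", 1),
                 cost_cell("TWO_SACCADES", 2) - cost_cell("SAC_AFTER_1", 2)),
               na.rm = TRUE)
  structure(list(table = cells, saccade_cost = cost,
                 n_excluded = sum(!keep)),
            class = "locus_behaviour")
}

#' @export
print.locus_behaviour <- function(x, ...) {
  cat("Behavioural summary over compliant trials\n")
  print(transform(x$table,
                  mean_loc_err = round(mean_loc_err, 3),
                  mean_col_err = round(mean_col_err, 3)))
  cat(sprintf("saccade cost: %.3f deg (%d trials excluded)\n",
              x$saccade_cost, x$n_excluded))
  invisible(x)
}
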