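# a bare trace builder: positions given as a (n x 2) matrix at 1000 Hz
make_trace <- function(pos, pupil = 1000) {
  out <- data.frame(time_ms = seq_len(nrow(pos)) - 1, x = pos[, 1],
                    y = pos[, 2], pupil = pupil, valid = TRUE)
  class(out) <- c("locus_gaze", "data.frame")
  out
}

step_trace <- function(from, to, t0, ramp = 30, total = 1000) {
  pos <- matrix(rep(from, each = total), ncol = 2)
  frac <- seq(0, 1, length.out = ramp)
  pos[t0:(t0 + ramp - 1), ] <- cbind(from[1] + frac * (to[1] - from[1]),
                                     from[2] + frac * (to[2] - from[2]))
  pos[(t0 + ramp):total, ] <- matrix(rep(to, each = total - t0 - ramp + 1),
                                     ncol = 2)
  make_trace(pos)
}

test_that("blink samples and their ramp artefacts are masked", {
  pos <- matrix(0, 1000, 2)
  tr <- make_trace(pos)
  expect_identical(remove_blinks(tr)$valid, rep(TRUE, 1000))
  # 100 ms of pupil = 0 with steep ramps on both sides
  tr2 <- tr
  tr2$pupil[450:549] <- 0
  tr2$pupil[440:449] <- seq(1000, 50, length.out = 10)   # pre-blink ramp
  tr2$pupil[550:559] <- seq(50, 1000, length.out = 10)   # post-blink ramp
  out <- remove_blinks(tr2)
  expect_true(all(!out$valid[450:549]))
  expect_true(all(!out$valid[441:449]))  # ramp caught inside the window
  expect_true(all(!out$valid[550:559]))
  expect_true(all(out$valid[1:400]))
})

test_that("fixation detection honours the dispersion and duration criteria", {
  pos <- matrix(5, 1000, 2)
  pos[1:300, ] <- 0          # 300 ms at the target, then away
  fx <- detect_fixations(make_trace(pos), c(0, 0))
  expect_equal(nrow(fx), 1)
  expect_gte(fx$duration_ms, 295)   # ends where the trace leaves the target
  # 100 ms dwell is below the 150 ms criterion
  pos2 <- matrix(5, 1000, 2); pos2[1:100, ] <- 0
  expect_equal(nrow(detect_fixations(make_trace(pos2), c(0, 0))), 0)
  # jittered dwell straddling the 2.5 deg boundary vs a brute-force oracle
  set.seed(23)
  d <- 2.5 + cumsum(rnorm(1000, 0, 0.05))
  pos3 <- cbind(d, 0)
  tr3 <- make_trace(pos3)
  fx3 <- detect_fixations(tr3, c(0, 0))
  ok <- abs(d) <= 2.5
  r <- rle(ok); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  oracle <- cbind(starts[r$values], r$lengths[r$values])
  oracle <- oracle[oracle[, 2] >= 150, , drop = FALSE]
  expect_equal(fx3$onset_ms, oracle[, 1] - 1)
  expect_equal(fx3$duration_ms, oracle[, 2])
  expect_error(detect_fixations(tr3[0, ], c(0, 0)), "no valid")
})

test_that("saccade detection needs velocity, duration and amplitude together", {
  still <- make_trace(matrix(1, 1000, 2))
  expect_equal(nrow(detect_saccades(still)), 0)
  # 10 deg in 30 ms: ~333 deg/s for 30 ms, amplitude 10 -> one saccade
  sac <- detect_saccades(step_trace(c(0, 0), c(10, 0), 500))
  expect_equal(nrow(sac), 1)
  expect_gt(sac$peak_velocity, 150)
  expect_gt(sac$amplitude, 9.2)
  # 5 deg step: fast enough but below the 9.2 deg amplitude criterion
  expect_equal(nrow(detect_saccades(step_trace(c(0, 0), c(5, 0), 500))), 0)
})

test_that("event detection is invariant to time shifts and rotations", {
  tr <- step_trace(c(0, 0), c(10, 0), 500)
  s0 <- detect_saccades(tr)
  shifted <- tr; shifted$time_ms <- shifted$time_ms + 12345
  s1 <- detect_saccades(shifted)
  expect_equal(s1$amplitude, s0$amplitude)
  expect_equal(s1$duration_ms, s0$duration_ms)
  expect_equal(s1$onset_ms - 12345, s0$onset_ms)
  phi <- 1.1
  rotated <- tr
  rotated$x <- cos(phi) * tr$x - sin(phi) * tr$y
  rotated$y <- sin(phi) * tr$x + cos(phi) * tr$y
  s2 <- detect_saccades(rotated)
  expect_equal(s2$amplitude, s0$amplitude, tolerance = 1e-9)
  expect_equal(s2$peak_velocity, s0$peak_velocity, tolerance = 1e-9)
})

test_that("compliance classification closes the loop with the gaze generator", {
  sess <- generate_session(seed = 41, n_trials = 16)
  for (k in seq_len(nrow(sess))) {
    trial <- sess[k, ]
    good <- classify_compliance(simulate_gaze(trial, TRUE, 0, seed = k), trial)
    expect_true(good$compliant)
    bad <- classify_compliance(simulate_gaze(trial, FALSE, 0, seed = k), trial)
    expect_false(bad$compliant)
  }
  # a fully masked trace is indeterminate, not non-compliant
  tr <- simulate_gaze(sess[1, ], TRUE, 0, seed = 1)
  tr$pupil <- 0
  tr <- remove_blinks(tr)
  expect_true(is.na(classify_compliance(tr, sess[1, ])$compliant))
})

test_that("classification stays accurate under gaze jitter", {
  sess <- generate_session(seed = 42, n_trials = 40)
  correct <- 0
  for (k in seq_len(nrow(sess))) {
    trial <- sess[k, ]
    compliant <- k %% 2 == 0
    tr <- simulate_gaze(trial, compliant, noise_sd = 0.5, seed = 100 + k)
    got <- classify_compliance(tr, trial)$compliant
    correct <- correct + identical(got, compliant)
  }
  expect_gte(correct / nrow(sess), 0.95)
})

test_that("colour error is a symmetric shortest arc in [0, pi]", {
  expect_equal(colour_error(0.2, 6.2), colour_error(6.2, 0.2))
  expect_equal(colour_error(0.1, 2 * pi - 0.1), 0.2, tolerance = 1e-12)
  expect_equal(colour_error(1, 1 + pi), pi, tolerance = 1e-12)
  a <- runif(100, 0, 2 * pi); b <- runif(100, 0, 2 * pi)
  expect_true(all(colour_error(a, b) >= 0 & colour_error(a, b) <= pi))
})

test_that("behavioural summaries match hand computation on a toy table", {
  sess <- generate_session(seed = 43, n_trials = 8)
  # respond exactly at the target: all errors zero, zero saccade cost
  tgt <- cbind(ifelse(sess$probed == 1, sess$item1_x, sess$item2_x),
               ifelse(sess$probed == 1, sess$item1_y, sess$item2_y))
  col_true <- ifelse(sess$probed == 1, sess$item1_col, sess$item2_col)
  perfect <- data.frame(trial_id = sess$trial_id, resp_col = col_true,
                        resp_x = tgt[, 1], resp_y = tgt[, 2])
  b0 <- behavioural_errors(sess, perfect)
  expect_true(all(b0$table$mean_loc_err[b0$table$n > 0] == 0))
  # offset each response by a known vector; opposite colour -> error pi
  shift <- cbind(3, 4)  # 5 deg error everywhere
  resp <- data.frame(trial_id = sess$trial_id,
                     resp_col = (col_true + pi) %% (2 * pi),
                     resp_x = tgt[, 1] + shift[, 1],
                     resp_y = tgt[, 2] + shift[, 2])
  b <- behavioural_errors(sess, resp)
  expect_equal(b$table$mean_loc_err[b$table$n > 0],
               rep(5, sum(b$table$n > 0)), tolerance = 1e-12)
  expect_equal(b$table$mean_col_err[b$table$n > 0],
               rep(pi, sum(b$table$n > 0)), tolerance = 1e-12)
  expect_equal(b$saccade_cost, 0, tolerance = 1e-12)
  # excluding trials shrinks the counts
  b2 <- behavioural_errors(sess, resp, compliant = c(TRUE, rep(FALSE, 7)))
  expect_equal(sum(b2$table$n), 1)
  expect_equal(b2$n_excluded, 7)
})
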