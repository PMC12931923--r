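test_that("session generation balances conditions and is reproducible", {
  sess <- generate_session(seed = 7, n_trials = 160)
  expect_equal(unname(table(sess$condition)[c("NO_SACCADE", "SAC_AFTER_1",
                                              "SAC_AFTER_2", "TWO_SACCADES")]),
               rep(40L, 4), ignore_attr = TRUE)
  tiny <- generate_session(seed = 3, n_trials = 4)
  expect_setequal(tiny$condition,
                  c("NO_SACCADE", "SAC_AFTER_1", "SAC_AFTER_2", "TWO_SACCADES"))
  expect_identical(generate_session(seed = 7, n_trials = 160),
                   generate_session(seed = 7, n_trials = 160))
  expect_error(generate_session(seed = 1, n_trials = 30), "divisible by 4")
})

test_that("geometric invariants hold across thousands of random trials", {
  task <- locus_task()
  grid <- frame_grid(task)
  expect_equal(nrow(grid), 15)
  sess <- do.call(rbind, lapply(1:63, function(s)
    as.data.frame(generate_session(seed = s, n_trials = 160))))
  half <- task$frame_size / 2
  # items inside their frame, far enough from the fixation cross
  for (k in 1:2) {
    dx <- sess[[paste0("item", k, "_x")]] - sess[[paste0("fix", k, "_x")]]
    dy <- sess[[paste0("item", k, "_y")]] - sess[[paste0("fix", k, "_y")]]
    expect_true(all(abs(dx) <= half & abs(dy) <= half))
    expect_true(all(sqrt(dx^2 + dy^2) >= task$min_item_dist))
  }
  # instructed saccades have at least the minimum amplitude
  d12 <- sqrt((sess$fix2_x - sess$fix1_x)^2 + (sess$fix2_y - sess$fix1_y)^2)
  d2w <- sqrt((sess$wheel_x - sess$fix2_x)^2 + (sess$wheel_y - sess$fix2_y)^2)
  sac1 <- sess$condition %in% c("SAC_AFTER_1", "TWO_SACCADES")
  sac2 <- sess$condition %in% c("SAC_AFTER_2", "TWO_SACCADES")
  expect_true(all(d12[sac1] >= task$min_saccade))
  expect_true(all(d2w[sac2] >= task$min_saccade))
  expect_true(all(d12[!sac1] == 0) && all(d2w[!sac2] == 0))
  # frame centres on the grid
  on_grid <- function(x, y) {
    apply(cbind(x, y), 1, function(p)
      min((grid[, 1] - p[1])^2 + (grid[, 2] - p[2])^2)) < 1e-18
  }
  expect_true(all(on_grid(sess$fix1_x, sess$fix1_y)))
  expect_true(all(on_grid(sess$wheel_x, sess$wheel_y)))
  # strictly increasing timeline
  tl <- as.matrix(sess[, c("t_item1_on", "t_item1_off", "t_item2_on",
                           "t_item2_off", "t_wheel_on", "t_col_resp",
                           "t_loc_resp")])
  expect_true(all(apply(tl, 1, function(r) all(diff(r) > 0))))
})

test_that("stimulus placement is uniform over the admissible region", {
  task <- locus_task()
  set.seed(1)
  draws <- t(replicate(20000, place_stimulus(c(0, 0), task)))
  expect_true(all(abs(draws) <= task$frame_size / 2 + 1e-12))
  r <- sqrt(rowSums(draws^2))
  expect_true(all(r >= task$min_item_dist))
  # independent rejection-sampling oracle, written inline
  set.seed(2)
  oracle <- matrix(runif(2 * 2e5, -4.9, 4.9), ncol = 2)
  okeep <- sqrt(rowSums(oracle^2)) >= task$min_item_dist
  ks <- suppressWarnings(ks.test(r, sqrt(rowSums(oracle[okeep, ]^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("saccade counts and timing variables follow the condition map", {
  task <- locus_task()
  sess <- generate_session(seed = 5, n_trials = 16)
  # hand-enumerated event times under the default timings: items off at
  # 1.0 s and 2.5 s, wheel at 3.0 s, location response at 6.0 s, saccades
  # executed 0.2 s after the frame change (1.2 s) and wheel onset (3.2 s)
  for (k in seq_len(nrow(sess))) {
    trial <- sess[k, ]
    t1 <- condition_timing(trial, 1, task)
    t2 <- condition_timing(trial, 2, task)
    expect_equal(t1$tau, 5); expect_equal(t2$tau, 3.5)
    expected <- switch(trial$condition,
      NO_SACCADE = list(c(0, 0, 0), c(0, 0, 0)),
      SAC_AFTER_1 = list(c(1, 4.8, 0), c(0, 0, 0)),
      SAC_AFTER_2 = list(c(1, 2.8, 0), c(1, 2.8, 0)),
      TWO_SACCADES = list(c(2, 4.8, 2.8), c(1, 2.8, 0)))
    expect_equal(c(t1$n_saccades, t1$t, t1$T), expected[[1]])
    expect_equal(c(t2$n_saccades, t2$t, t2$T), expected[[2]])
    expect_true(t1$tau >= t1$t && t1$t >= t1$T)
  }
  bad <- sess[1, ]; bad$t_wheel_on <- NA
  expect_error(condition_timing(bad, 1, task), "missing event")
})

test_that("simulated responses collapse onto the stimulus in the zero-variance limit", {
  sess <- generate_session(seed = 2, n_trials = 40)
  kappa <- c(radial_enc = -40, radial_decay = -40, angular_enc = -40,
             angular_decay = -40)
  resp <- simulate_responses(sess, 2, kappa, seed = 1)
  tgt_x <- ifelse(sess$probed == 1, sess$item1_x, sess$item2_x)
  tgt_y <- ifelse(sess$probed == 1, sess$item1_y, sess$item2_y)
  expect_lt(max(abs(resp$resp_x - tgt_x), abs(resp$resp_y - tgt_y)), 1e-6)
})

test_that("interference weight one targets the distractor", {
  sess <- generate_session(seed = 2, n_trials = 40)
  kappa <- c(radial_enc = -40, radial_decay = -40, angular_enc = -40,
             angular_decay = -40, interference = 40)
  resp <- simulate_responses(sess, 5, kappa, seed = 1)
  dis_x <- ifelse(sess$probed == 1, sess$item2_x, sess$item1_x)
  dis_y <- ifelse(sess$probed == 1, sess$item2_y, sess$item1_y)
  # distractor coordinates are taken about the probed item's fixation, so
  # with vanishing variances the response lands on the distractor itself
  expect_lt(max(abs(resp$resp_x - dis_x), abs(resp$resp_y - dis_y)), 1e-6)
})

test_that("simulated radial error matches the analytic variance schedule", {
  sess <- generate_session(seed = 9, n_trials = 160)
  trial <- sess[sess$condition == "TWO_SACCADES", ][1, ]
  big <- rep_trial_session(trial, 10000)
  kappa <- ref_kappa(4)
  resp <- simulate_responses(big, 4, kappa, seed = 3)
  obs <- normalize_trials(big, resp)
  tim <- condition_timing(trial, trial$probed)
  sig <- variance_schedule(4, transform_params(kappa, 4),
                           tim$tau, tim$t, tim$T, tim$n_saccades)
  r <- sqrt(obs$resp_u^2 + obs$resp_v^2)
  stat <- (length(r) - 1) * var(r - obs$target_r) / sig$sigma_r
  # two-sided chi-square goodness-of-fit on the sample variance, alpha 0.01
  expect_gt(stat, qchisq(0.005, length(r) - 1))
  expect_lt(stat, qchisq(0.995, length(r) - 1))
})
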