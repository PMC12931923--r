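test_that("parameter transforms are exp for scales and sigmoid for interference", {
  expect_equal(unname(transform_params(c(0, 0), 1)), c(1, 1))
  p <- transform_params(c(0, 0, 0, 0, 0), 5)
  expect_equal(unname(p[5]), 0.5)
  k1 <- transform_params(ref_kappa(7), 7)
  k2 <- transform_params(ref_kappa(7) + 0.1, 7)
  expect_true(all(k2 > k1))  # strictly monotone per coordinate
  expect_error(transform_params(c(0, NA), 1), "finite")
  expect_error(transform_params(c(0, 0, 0), 1), "expects 2")
})

test_that("variance schedules reduce to encoding terms at time zero and grow with time", {
  for (id in 1:7) {
    p <- transform_params(ref_kappa(id), id)
    s0 <- variance_schedule(id, p, tau = 0, t = 0, T = 0, n = 0)
    if (id == 1) expect_equal(s0$sigma_xy, p[["alloc_enc"]])
    else {
      expect_equal(s0$sigma_r, p[["radial_enc"]])
      expect_equal(s0$sigma_th, p[["angular_enc"]])
    }
    # non-decreasing in each timing argument on a grid
    taus <- seq(0, 8, by = 0.5)
    s <- variance_schedule(id, p, taus, t = pmin(taus, 4), T = pmin(taus, 2),
                           n = rep(2, length(taus)))
    v <- if (id == 1) s$sigma_xy else s$sigma_r
    expect_true(all(diff(v) > 0))
    if (id != 1) expect_true(all(diff(s$sigma_th) > 0))
  }
  expect_error(variance_schedule(2, transform_params(ref_kappa(2), 2),
                                 tau = -1), "non-negative")
})

test_that("nested models agree when their extra parameters vanish", {
  set.seed(4)
  obs <- make_obs(resp_u = rnorm(50, 6, 1), resp_v = rnorm(50, 0, 1),
                  tau = runif(50, 3, 6), t = runif(50, 0, 3),
                  T = runif(50, 0, 1), n = sample(0:2, 50, TRUE))
  base <- ref_kappa(2)
  ll2 <- dataset_loglik(2, base, obs)
  # killing fixation decay / saccade terms (kappa -> -Inf) recovers model 2
  expect_equal(dataset_loglik(3, c(base, fixation_decay = -800), obs), ll2,
               tolerance = 1e-12)
  expect_equal(dataset_loglik(4, c(base, saccade_enc = -800,
                                   saccade_decay = -800), obs), ll2,
               tolerance = 1e-12)
  # and interference weight -> 0 reduces 5 to 2, 6 to 3, 7 to 4
  expect_equal(dataset_loglik(5, c(base, interference = -800), obs), ll2,
               tolerance = 1e-12)
  k4 <- ref_kappa(4)
  expect_equal(dataset_loglik(7, c(k4, interference = -800), obs),
               dataset_loglik(4, k4, obs), tolerance = 1e-12)
})

test_that("allocentric log-density peaks at -log(2 pi) for unit variance", {
  obs <- make_obs(target_r = 5, resp_u = 5, resp_v = 0, tau = 0)
  expect_equal(loglik_trial(1, c(alloc_decay = 0, alloc_enc = 0), obs),
               -log(2 * pi), tolerance = 1e-12)
})

test_that("per-trial log-likelihoods match an independent dnorm oracle", {
  set.seed(11)
  obs <- make_obs(target_r = 6, distr_r = 7, distr_th = 0.8,
                  resp_u = rnorm(50, 6, 1.5), resp_v = rnorm(50, 0, 1.5),
                  tau = 5, t = c(4.8, 0), T = 0, n = c(1, 0),
                  d_tau = 3.5, d_t = 2.8, d_n = 1)
  for (id in c(2, 3, 4, 5, 7)) {
    k <- ref_kappa(id)
    expect_equal(loglik_trial(id, k, obs), oracle_loglik_dual(id, k, obs),
                 tolerance = 1e-10)
    expect_equal(dataset_loglik(id, k, obs), sum(oracle_loglik_dual(id, k, obs)),
                 tolerance = 1e-10)
  }
  expect_equal(dataset_loglik(2, ref_kappa(2), obs[0, ]), 0)
  two <- dataset_loglik(2, ref_kappa(2), obs[1:2, ])
  expect_equal(two, loglik_trial(2, ref_kappa(2), obs[1, ]) +
                 loglik_trial(2, ref_kappa(2), obs[2, ]), tolerance = 1e-12)
})

test_that("mixture density integrates to one over the response plane", {
  for (id in c(5, 7)) {
    kappa <- ref_kappa(id)
    if (id == 7) { kappa[["saccade_enc"]] <- -4; kappa[["saccade_decay"]] <- -4 }
    rr <- seq(0, 20, length.out = 801)
    th <- seq(-pi, pi, length.out = 629)
    g <- expand.grid(r = rr, th = th)
    obs <- make_obs(target_r = 8, distr_r = 7, distr_th = 0.8,
                    resp_u = g$r * cos(g$th), resp_v = g$r * sin(g$th),
                    tau = 5, t = 4.8, T = 2.8, n = 2,
                    d_tau = 3.5, d_t = 2.8, d_n = 1)
    dens <- exp(loglik_trial(id, kappa, obs))
    integral <- sum(dens) * diff(rr[1:2]) * diff(th[1:2])
    expect_equal(integral, 1, tolerance = 1e-3)
  }
})

test_that("normalisation is a rigid motion with target at the reference angle", {
  sess <- generate_session(seed = 21, n_trials = 40)
  resp <- simulate_responses(sess, 2, ref_kappa(2), seed = 1)
  obs <- normalize_trials(sess, resp)
  expect_true(all(obs$target_th == 0))
  # distances preserved to machine precision
  tgt_x <- ifelse(sess$probed == 1, sess$item1_x, sess$item2_x)
  tgt_y <- ifelse(sess$probed == 1, sess$item1_y, sess$item2_y)
  d_raw <- sqrt((resp$resp_x - tgt_x)^2 + (resp$resp_y - tgt_y)^2)
  d_norm <- sqrt((obs$resp_u - obs$target_r)^2 + obs$resp_v^2)
  expect_equal(d_raw, d_norm, tolerance = 1e-12)
  # inverse transform recovers the raw response coordinates
  fx <- ifelse(sess$probed == 1, sess$fix1_x, sess$fix2_x)
  fy <- ifelse(sess$probed == 1, sess$fix1_y, sess$fix2_y)
  alpha <- atan2(tgt_y - fy, tgt_x - fx)
  back_x <- fx + cos(alpha) * obs$resp_u - sin(alpha) * obs$resp_v
  back_y <- fy + sin(alpha) * obs$resp_u + cos(alpha) * obs$resp_v
  expect_equal(back_x, resp$resp_x, tolerance = 1e-10)
  expect_equal(back_y, resp$resp_y, tolerance = 1e-10)
})

test_that("dataset likelihood is invariant to rigid motion of the raw data", {
  sess <- generate_session(seed = 22, n_trials = 40)
  resp <- simulate_responses(sess, 7, ref_kappa(7), seed = 2)
  ll0 <- dataset_loglik(7, ref_kappa(7), normalize_trials(sess, resp))
  # rotate and translate every screen coordinate by the same motion
  phi <- 0.71; shift <- c(3.3, -1.7)
  rot <- function(x, y) list(x = cos(phi) * x - sin(phi) * y + shift[1],
                             y = sin(phi) * x + cos(phi) * y + shift[2])
  s2 <- sess
  for (f in c("fix1", "fix2", "wheel", "item1", "item2")) {
    p <- rot(s2[[paste0(f, "_x")]], s2[[paste0(f, "_y")]])
    s2[[paste0(f, "_x")]] <- p$x; s2[[paste0(f, "_y")]] <- p$y
  }
  r2 <- resp
  p <- rot(resp$resp_x, resp$resp_y)
  r2$resp_x <- p$x; r2$resp_y <- p$y
  ll1 <- dataset_loglik(7, ref_kappa(7), normalize_trials(s2, r2))
  expect_equal(ll1, ll0, tolerance = 1e-9)
})
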