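# Shared fixtures for the locuswm tests. Everything is generated in code.

# a single normalised observation row (or several, vectorised)
make_obs <- function(target_r = 6, target_th = 0, distr_r = 7, distr_th = 0.8,
                     resp_u = target_r, resp_v = 0,
                     tau = 5, t = 0, T = 0, n = 0,
                     d_tau = 3.5, d_t = 0, d_T = 0, d_n = 0) {
  out <- data.frame(trial_id = seq_along(resp_u), target_r = target_r,
                    target_th = target_th, distr_r = distr_r,
                    distr_th = distr_th, resp_u = resp_u, resp_v = resp_v,
                    tau = tau, t = t, T = T, n = n,
                    d_tau = d_tau, d_t = d_t, d_T = d_T, d_n = d_n)
  class(out) <- c("locus_obs", "data.frame")
  out
}

# representative moderate parameter vectors per model
ref_kappa <- function(id) {
  switch(id,
    c(alloc_decay = -1, alloc_enc = 0),
    c(radial_enc = 0, radial_decay = -1, angular_enc = -2.5, angular_decay = -3),
    c(radial_enc = 0, radial_decay = -1, angular_enc = -2.5, angular_decay = -3,
      fixation_decay = -2),
    c(radial_enc = 0, radial_decay = -1, angular_enc = -2.5, angular_decay = -3,
      saccade_enc = -2, saccade_decay = -2),
    c(radial_enc = 0, radial_decay = -1, angular_enc = -2.5, angular_decay = -3,
      interference = -0.5),
    c(radial_enc = 0, radial_decay = -1, angular_enc = -2.5, angular_decay = -3,
      fixation_decay = -2, interference = -0.5),
    c(radial_enc = 0, radial_decay = -1, angular_enc = -2.5, angular_decay = -3,
      saccade_enc = -2, saccade_decay = -2, interference = -0.5))
}

# a session whose rows are one trial repeated (for distribution checks)
rep_trial_session <- function(trial, n) {
  out <- trial[rep(1, n), ]
  out$trial_id <- seq_len(n)
  rownames(out) <- NULL
  class(out) <- class(trial)
  attr(out, "task") <- attr(trial, "task")
  out
}

# parameter vectors with modest variances, so that the radial density has
# negligible mass below r = 0 and posterior calibration checks are clean
calib_kappa <- function(id) {
  base <- c(radial_enc = -0.8, radial_decay = -2.2, angular_enc = -2.1,
            angular_decay = -2.9)
  switch(id,
    c(alloc_decay = -2, alloc_enc = -1),
    base,
    c(base, fixation_decay = -2.2),
    c(base, saccade_enc = -1.5, saccade_decay = -2.5),
    c(base, interference = -0.5),
    c(base, fixation_decay = -2.2, interference = -0.5),
    c(base, saccade_enc = -1.5, saccade_decay = -2.5, interference = -0.5))
}

# multivariate normal draws via a Cholesky factor (sampling oracle)
rmvn_chol <- function(n, mu, S) {
  L <- chol(S)
  matrix(rnorm(n * length(mu)), n) %*% L + rep(mu, each = n)
}

# straight dnorm-based log-density for one dual-model trial, written
# independently of the package internals (mixture in probability space)
oracle_loglik_dual <- function(model_id, kappa, obs) {
  m <- locus_model(model_id)
  p <- exp(kappa)
  wrap <- function(a) { w <- (a + pi) %% (2 * pi) - pi; ifelse(w == -pi, pi, w) }
  sig <- function(tau, t, T, n) {
    ex <- 0
    if (m$fixation) ex <- p[["fixation_decay"]] * t
    if (m$saccade) ex <- n * p[["saccade_enc"]] + p[["saccade_decay"]] * (t + T)
    c(p[["radial_enc"]] + p[["radial_decay"]] * tau + ex,
      p[["angular_enc"]] + p[["angular_decay"]] * tau + ex)
  }
  sapply(seq_len(nrow(obs)), function(i) {
    o <- obs[i, ]
    r <- sqrt(o$resp_u^2 + o$resp_v^2)
    th <- atan2(o$resp_v, o$resp_u)
    st <- sig(o$tau, o$t, o$T, o$n)
    ft <- dnorm(r, o$target_r, sqrt(st[1])) *
      dnorm(wrap(th - o$target_th), 0, sqrt(st[2]))
    if (!m$interference) return(log(ft))
    w <- plogis(kappa[[length(kappa)]])
    sd <- sig(o$d_tau, o$d_t, o$d_T, o$d_n)
    fd <- dnorm(r, o$distr_r, sqrt(sd[1])) *
      dnorm(wrap(th - o$distr_th), 0, sqrt(sd[2]))
    log((1 - w) * ft + w * fd)
  })
}
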