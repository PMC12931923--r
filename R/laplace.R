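#' Optimiser settings for Laplace inversion
#'
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the free-energy improvement (nats).
#' @param fd_step Central finite-difference step in unconstrained space.
#' @param lambda0 Initial Levenberg-Marquardt damping added to the negative
#'   Hessian before solving for the Newton step.
#' @param lambda_max Damping ceiling; a step still rejected here raises an
#'   error.
#' @return List of class \code{"locus_control"}.
#' @export
locus_control <- function(max_iter = 128, tol = 1e-4, fd_step = 1e-3,
                          lambda0 = 1e-6, lambda_max = 1e8) {
  structure(list(max_iter = max_iter, tol = tol, fd_step = fd_step,
                 lambda0 = lambda0, lambda_max = lambda_max),
            class = "locus_control")
}

#' Prior specification for model inversion
#'
#' Zero-mean spherical Gaussian prior over the unconstrained parameters with
#' variance 1/8 per coordinate by default - a conservative prior requiring
#' good evidence for a parameter to move away from a natural scale of 1 (or
#' an interference weight of 0.5).
#'
#' @param model A \code{\link{locus_model}}, id, or an integer dimension.
#' @param variance Prior variance per coordinate.
#' @return List of class \code{"locus_prior"} with \code{mean} and
#'   \code{variance} vectors.
#' @export
locus_prior <- function(model, variance = 1/8) {
  d <- if (inherits(model, "locus_model")) length(model$params)
       else if (length(model) == 1 && model >= 1 && model <= 7 && model == round(model))
         length(locus_model(model)$params)
       else stop("model must be a locus_model or id")
  structure(list(mean = rep(0, d), variance = rep(variance, d)),
            class = "locus_prior")
}

# central finite-difference gradient and Hessian of f at x
fd_grad_hess <- function(f, x, h) {
  d <- length(x)
  f0 <- f(x)
  g <- numeric(d)
  H <- matrix(0, d, d)
  fp <- fm <- numeric(d)
  for (i in seq_len(d)) {
    e <- rep(0, d); e[i] <- h
    fp[i] <- f(x + e); fm[i] <- f(x - e)
    g[i] <- (fp[i] - fm[i]) / (2 * h)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (d > 1) {
    for (i in seq_len(d - 1)) for (j in (i + 1):d) {
      ei <- rep(0, d); ei[i] <- h
      ej <- rep(0, d); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
    }
  }
  list(f0 = f0, grad = g, hess = H)
}

# invert a negative Hessian, damping the diagonal until SPD
spd_inverse <- function(negH, max_tries = 60) {
  d <- nrow(negH)
  jitter <- 0
  base <- max(abs(diag(negH)), 1e-12)
  for (k in 0:max_tries) {
    ch <- tryCatch(chol(negH + diag(jitter, d)), error = function(e) NULL)
    if (!is.null(ch))
      return(list(inv = chol2inv(ch), logdet_inv = -2 * sum(log(diag(ch))),
                  jitter = jitter))
    jitter <- if (jitter == 0) base * 1e-10 else jitter * 10
  }
  stop("degenerate fit: negative Hessian could not be made positive definite")
}

#' Laplace free energy (approximate log model evidence)
#'
#' \code{F = log-joint at the mode + (d/2) log(2*pi) + (1/2) log det(Sigma)},
#' the Gaussian-volume-corrected height of the log-joint. With no data the
#' log-joint at the prior mean cancels the volume term exactly, so F = 0.
#'
#' @param log_joint_at_mode Log-joint (log-likelihood + log-prior) at the
#'   posterior mode (nats).
#' @param posterior_covariance Posterior covariance matrix (SPD).
#' @param dim Parameter count; defaults to the covariance dimension.
#' @return Free energy in nats.
#' @export
free_energy <- function(log_joint_at_mode, posterior_covariance,
                        dim = nrow(posterior_covariance)) {
  ch <- tryCatch(chol(posterior_covariance), error = function(e)
    stop("posterior covariance is not positive definite"))
  log_joint_at_mode + dim / 2 * log(2 * pi) + sum(log(diag(ch)))
}

#' Laplace inversion of an arbitrary log-likelihood
#'
#' Damped-Newton ascent on the log-joint (log-likelihood plus Gaussian
#' log-prior) with central finite-difference derivatives, starting at the
#' prior mean, followed by a Laplace approximation at the mode. Damping is
#' doubled (tenfold) whenever a proposed step decreases the log-joint and
#' relaxed after an accepted step; convergence is declared when the free
#' energy improves by less than \code{control$tol}. Deterministic given its
#' inputs.
#'
#' This is the engine behind \code{\link{locus_fit}} and
#' \code{\link{score_regression}}; it accepts any smooth log-likelihood of a
#' low-dimensional parameter vector.
#'
#' @param loglik Function of the unconstrained parameter vector returning a
#'   scalar log-likelihood (nats).
#' @param prior A \code{\link{locus_prior}} (or list with mean, variance).
#' @param control A \code{\link{locus_control}}.
#' @param init Starting point; the prior mean by default, which makes the
#'   fit deterministic.
#' @return List with \code{mode}, \code{covariance}, \code{free_energy},
#'   \code{log_joint}, \code{iterations}, \code{converged}.
#' @export
laplace_fit <- function(loglik, prior, control = locus_control(),
                        init = prior$mean) {
  mu0 <- prior$mean
  v0 <- prior$variance
  d <- length(mu0)
  logprior <- function(k) sum(.lognorm(k - mu0, v0))
  J <- function(k) loglik(k) + logprior(k)
  x <- init
  if (!is.finite(J(x)))
    stop("initialisation error: non-finite log-joint at the prior mean")
  lambda <- control$lambda0
  F_old <- -Inf
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    fd <- fd_grad_hess(J, x, control$fd_step)
    negH <- -fd$hess
    si <- spd_inverse(negH)
    F_now <- fd$f0 + d / 2 * log(2 * pi) + 0.5 * si$logdet_inv
    if (abs(F_now - F_old) < control$tol) { converged <- TRUE; break }
    F_old <- F_now
    if (iter > control$max_iter) break
    # damped Newton step; increase damping until the log-joint improves
    repeat {
      step <- tryCatch(solve(negH + diag(lambda + si$jitter, d), fd$grad),
                       error = function(e) NULL)
      if (!is.null(step)) {
        x_new <- x + step
        J_new <- tryCatch(J(x_new), error = function(e) -Inf)
        if (is.finite(J_new) && J_new >= fd$f0 - 1e-12) {
          x <- x_new
          lambda <- max(lambda / 10, control$lambda0)
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > control$lambda_max) {
        # cannot improve from here: treat current point as the mode
        lambda <- control$lambda_max
        break
      }
    }
  }
  fd <- fd_grad_hess(J, x, control$fd_step)
  si <- spd_inverse(-fd$hess)
  Sigma <- (si$inv + t(si$inv)) / 2
  list(mode = x, covariance = Sigma,
       free_energy = free_energy(fd$f0, Sigma, d),
       log_joint = fd$f0, iterations = iter, converged = converged)
}

#' Fit a generative model to one subject's data by Laplace inversion
#'
#' The main fitting function. Maximises the log-joint of a
#' \code{\link{locus_model}} over its unconstrained parameters for a single
#' subject's normalised observations, under a zero-mean spherical Gaussian
#' prior (variance 1/8 per coordinate by default), using the damped Newton
#' scheme of \code{\link{laplace_fit}}. Returns the posterior mode,
#' covariance and free energy (approximate log model evidence) used for
#' model selection.
#'
#' @param model A \code{\link{locus_model}} or id 1..7.
#' @param data Normalised observations from \code{\link{normalize_trials}}
#'   (may have zero rows, in which case the posterior equals the prior and
#'   the free energy is exactly 0).
#' @param prior A \code{\link{locus_prior}}.
#' @param control A \code{\link{locus_control}}.
#' @param subject Optional subject identifier carried into the fit object.
#' @param init Starting point in unconstrained space (prior mean by
#'   default).
#' @return Object of class \code{"locus_fit"}; see
#'   \code{\link{summary.locus_fit}}.
#' @examples
#' sess <- generate_session(seed = 1, n_trials = 40)
#' kappa <- c(radial_enc = 0, radial_decay = -1, angular_enc = -2,
#'            angular_decay = -2)
#' resp <- simulate_responses(sess, 2, kappa, seed = 2)
#' obs <- normalize_trials(sess, resp)
#' fit <- locus_fit(2, obs)
#' coef(fit)
#' @export
locus_fit <- function(model, data, prior = locus_prior(model),
                      control = locus_control(), subject = NULL,
                      init = prior$mean) {
  model <- as_locus_model(model)
  d <- length(model$params)
  stopifnot(length(prior$mean) == d)
  if (!is.null(data$subject) && length(unique(data$subject)) > 1)
    stop("data mixes subjects; fit one subject at a time")
  cache <- if (nrow(data) > 0) obs_cache(data) else NULL
  ll <- if (is.null(cache)) function(k) 0 else function(k) {
    p <- transform_params(k, model)
    sum(loglik_vec(model, p, cache))
  }
  res <- laplace_fit(ll, prior, control, init = init)
  names(res$mode) <- model$params
  dimnames(res$covariance) <- list(model$params, model$params)
  structure(list(model = model, subject = subject,
                 mode = res$mode, covariance = res$covariance,
                 free_energy = res$free_energy, log_joint = res$log_joint,
                 loglik = res$log_joint - sum(.lognorm(res$mode - prior$mean,
                                                       prior$variance)),
                 n_trials = nrow(data), prior = prior,
                 iterations = res$iterations, converged = res$converged,
                 call = match.call()),
            class = "locus_fit")
}

#' @export
print.locus_fit <- function(x, ...) {
  cat(sprintf("Laplace fit of model %d (%s)%s\n", x$model$id, x$model$name,
              if (is.null(x$subject)) "" else paste0(", subject ", x$subject)))
  cat(sprintf("  trials: %d   free energy: %.3f nats   converged: %s (%d iterations)\n",
              x$n_trials, x$free_energy, x$converged, x$iterations))
  cat("  posterior mode (unconstrained):\n")
  print(round(x$mode, 4))
  invisible(x)
}

#' Summarise a Laplace model fit
#'
#' Reports, per parameter, the unconstrained posterior mode and standard
#' deviation, the natural-scale value (exp, or sigmoid for interference),
#' and a 90 percent credible interval obtained by transforming the
#' unconstrained interval mode +/- 1.645 sd.
#'
#' @param object A \code{\link{locus_fit}}.
#' @param ... Unused.
#' @export
summary.locus_fit <- function(object, ...) {
  sd <- sqrt(diag(object$covariance))
  lo <- object$mode - 1.645 * sd
  hi <- object$mode + 1.645 * sd
  nat <- transform_params(object$mode, object$model)
  tr <- function(k) transform_params(k, object$model)
  tab <- data.frame(mode = object$mode, sd = sd, natural = nat,
                    nat_lo90 = tr(lo), nat_hi90 = tr(hi))
  out <- list(model = object$model, subject = object$subject, table = tab,
              free_energy = object$free_energy, n_trials = object$n_trials,
              converged = object$converged)
  class(out) <- "summary.locus_fit"
  out
}

#' @export
print.summary.locus_fit <- function(x, ...) {
  cat(sprintf("Model %d (%s), %d trials, free energy %.3f nats\n",
              x$model$id, x$model$name, x$n_trials, x$free_energy))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.locus_fit <- function(object, natural = FALSE, ...) {
  if (natural) transform_params(object$mode, object$model) else object$mode
}

#' @export
vcov.locus_fit <- function(object, ...) object$covariance

#' @export
logLik.locus_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$mode), nobs = object$n_trials,
            class = "logLik")
}

#' Simulate responses from a fitted model
#'
#' Draws new response sets for a session from the fitted model at its
#' posterior mode.
#'
#' @param object A \code{\link{locus_fit}}.
#' @param nsim Number of simulated response sets.
#' @param seed Integer seed.
#' @param session A \code{\link{generate_session}} session to respond to.
#' @param ... Unused.
#' @return A response data frame, or a list of them when \code{nsim > 1}.
#' @export
simulate.locus_fit <- function(object, nsim = 1, seed = 1, session, ...) {
  seeds <- derive_seeds(seed, nsim)
  out <- lapply(seeds, function(s)
    simulate_responses(session, object$model, object$mode, seed = s))
  if (nsim == 1) out[[1]] else out
}

#' Residuals of a fitted model
#'
#' Radial and angular (or Euclidean, for the allocentric model) deviations
#' of each response from the target, in the normalised frame.
#'
#' @param object A \code{\link{locus_fit}}.
#' @param data The normalised observations the model was fitted to.
#' @param ... Unused.
#' @export
residuals.locus_fit <- function(object, data, ...) {
  cache <- obs_cache(data)
  if (object$model$id == 1)
    data.frame(trial_id = data$trial_id, du = cache$du, dv = cache$dv)
  else
    data.frame(trial_id = data$trial_id, dr = cache$dr_t, dth = cache$dth_t)
}

#' Diagnostic plot of a fitted model
#'
#' Plots radial error against retention time tau together with the fitted
#' +/- 1.645 sd band of the model's radial variance schedule (Euclidean
#' error for the allocentric model).
#'
#' @param x A \code{\link{locus_fit}}.
#' @param data The normalised observations the model was fitted to.
#' @param ... Passed to \code{plot}.
#' @export
plot.locus_fit <- function(x, data, ...) {
  cache <- obs_cache(data)
  p <- transform_params(x$mode, x$model)
  if (x$model$id == 1) {
    err <- sqrt(cache$du^2 + cache$dv^2)
    ylab <- "Euclidean error (deg)"
  } else {
    err <- cache$dr_t
    ylab <- "radial error (deg)"
  }
  graphics::plot(cache$tau, err, xlab = "retention time tau (s)", ylab = ylab, ...)
  taus <- sort(unique(cache$tau))
  idx <- match(taus, cache$tau)
  sig <- variance_schedule(x$model, p, cache$tau[idx], cache$t[idx],
                           cache$T[idx], cache$n[idx])
  s <- if (x$model$id == 1) sig$sigma_xy else sig$sigma_r
  graphics::points(taus, 1.645 * sqrt(s), type = "b", pch = 3)
  graphics::points(taus, -1.645 * sqrt(s), type = "b", pch = 3)
  invisible(x)
}
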