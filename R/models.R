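#' Model specifications for the seven generative models
#'
#' The model space spans three distinctions: (i) a single allocentric
#' (screen-centred) representation versus a dual eye-centred (retinotopic)
#' one holding radial and angular coordinates about the fixation at which the
#' probed item was viewed; (ii) within the dual frame, whether remapping
#' error comes from decay of the remembered fixation location (fixation
#' decay, growing from the first saccade after the item) or from noisy
#' memories of the executed saccade vectors (a per-saccade encoding error
#' plus decay of each stored vector); and (iii) whether responses are subject
#' to interference - a probability of responding to the unprobed item's
#' representation instead of the target's.
#'
#' \describe{
#'   \item{1 Allocentric}{isotropic Euclidean encoding error + decay}
#'   \item{2 Dual}{radial/angular encoding error + decay}
#'   \item{3 Dual (Fixation)}{Dual + fixation decay}
#'   \item{4 Dual (Saccade)}{Dual + saccade encoding error + saccade decay}
#'   \item{5 Dual + Interference}{Dual + interference}
#'   \item{6 Dual (Fixation) + Interference}{}
#'   \item{7 Dual (Saccade) + Interference}{}
#' }
#'
#' All parameters are unconstrained reals; scale parameters are
#' exponentiated and the interference parameter passed through a sigmoid
#' (see \code{\link{transform_params}}).
#'
#' @param id Model index 1..7.
#' @return Object of class \code{"locus_model"}: list with \code{id},
#'   \code{name}, \code{params} (unconstrained parameter names),
#'   \code{fixation} / \code{saccade} / \code{interference} component flags.
#' @export
locus_model <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1 || is.na(id) || id < 1 || id > 7)
    stop("model id must be a single integer in 1..7")
  base <- c("radial_enc", "radial_decay", "angular_enc", "angular_decay")
  spec <- switch(id,
    list(name = "Allocentric", params = c("alloc_decay", "alloc_enc"),
         fixation = FALSE, saccade = FALSE, interference = FALSE),
    list(name = "Dual", params = base,
         fixation = FALSE, saccade = FALSE, interference = FALSE),
    list(name = "Dual (Fixation)", params = c(base, "fixation_decay"),
         fixation = TRUE, saccade = FALSE, interference = FALSE),
    list(name = "Dual (Saccade)", params = c(base, "saccade_enc", "saccade_decay"),
         fixation = FALSE, saccade = TRUE, interference = FALSE),
    list(name = "Dual + Interference", params = c(base, "interference"),
         fixation = FALSE, saccade = FALSE, interference = TRUE),
    list(name = "Dual (Fixation) + Interference",
         params = c(base, "fixation_decay", "interference"),
         fixation = TRUE, saccade = FALSE, interference = TRUE),
    list(name = "Dual (Saccade) + Interference",
         params = c(base, "saccade_enc", "saccade_decay", "interference"),
         fixation = FALSE, saccade = TRUE, interference = TRUE))
  structure(c(list(id = id), spec), class = "locus_model")
}

as_locus_model <- function(x) {
  if (inherits(x, "locus_model")) x else locus_model(x)
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("LOCUS generative model %d: %s\n", x$id, x$name))
  cat("  parameters:", paste(x$params, collapse = ", "), "\n")
  invisible(x)
}

#' Map unconstrained parameters to natural scale
#'
#' Every scale parameter is a log-scaling parameter: the natural value is
#' \code{exp(kappa)}, guaranteeing positivity. The interference parameter is
#' a logit: the natural weight is \code{1/(1+exp(-kappa))}, in (0, 1).
#' Radial and Euclidean variances are in squared degrees of visual angle,
#' angular variances in squared radians; decay parameters are variance per
#' second.
#'
#' @param kappa Named (or positionally ordered) unconstrained vector.
#' @param model A \code{\link{locus_model}} or model id.
#' @return Named numeric vector of natural-scale parameters.
#' @export
transform_params <- function(kappa, model) {
  model <- as_locus_model(model)
  d <- length(model$params)
  if (length(kappa) != d)
    stop(sprintf("model %d expects %d parameters, got %d", model$id, d, length(kappa)))
  if (!is.null(names(kappa)) && !all(names(kappa) == model$params))
    kappa <- kappa[model$params]
  if (anyNA(kappa) || any(!is.finite(kappa))) stop("kappa must be finite")
  nat <- exp(kappa)
  if (model$interference) {
    w <- stats::plogis(kappa[d])
    nat[d] <- w
  }
  names(nat) <- model$params
  nat
}

#' Variance schedule of a generative model
#'
#' Evaluates the model's response variance as a function of the timing
#' variables: \code{tau}, time since the probed item disappeared; \code{t},
#' time since the first saccade after the item (0 if none); \code{T}, time
#' since the second (0 if none); and \code{n}, the number of saccades since
#' the item. The allocentric model has a single Euclidean variance
#' \code{sigma_xy = enc + decay * tau}. The dual models have radial and
#' angular components, each \code{enc + decay * tau}; the fixation-decay
#' models add \code{fixation_decay * t} (decay of the remembered fixation
#' begins at the first saccade after the item); the saccade-update models add
#' \code{n * saccade_enc + saccade_decay * (t + T)}, a per-saccade encoding
#' error plus cumulative decay of each stored saccade-vector memory.
#' Fixation and saccade contributions are added to both the radial and the
#' angular component.
#'
#' @param model A \code{\link{locus_model}} or id.
#' @param params Natural-scale parameters (from
#'   \code{\link{transform_params}}).
#' @param tau,t,T Timing variables (s), vectorised; all must be >= 0.
#' @param n Number of saccades since the item (0, 1 or 2), vectorised.
#' @return For model 1, list with \code{sigma_xy} (deg^2); otherwise list
#'   with \code{sigma_r} (deg^2) and \code{sigma_th} (rad^2).
#' @export
variance_schedule <- function(model, params, tau, t = 0, T = 0, n = 0) {
  model <- as_locus_model(model)
  if (any(tau < 0) || any(t < 0) || any(T < 0))
    stop("timing arguments must be non-negative")
  if (any(!n %in% 0:2)) stop("n must be 0, 1 or 2")
  if (model$id == 1)
    return(list(sigma_xy = params[["alloc_enc"]] + params[["alloc_decay"]] * tau))
  extra <- 0
  if (model$fixation) extra <- extra + params[["fixation_decay"]] * t
  if (model$saccade)
    extra <- extra + n * params[["saccade_enc"]] +
      params[["saccade_decay"]] * (t + T)
  list(sigma_r = params[["radial_enc"]] + params[["radial_decay"]] * tau + extra,
       sigma_th = params[["angular_enc"]] + params[["angular_decay"]] * tau + extra)
}

# wrap angle(s) into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# log N(x; mu, sigma2) without the dnorm call overhead, vectorised
.lognorm <- function(resid, sigma2) {
  -0.5 * (log(2 * pi * sigma2) + resid^2 / sigma2)
}

# Precompute everything the likelihood needs from a normalised observation
# table, so each evaluation is a handful of vector ops.
obs_cache <- function(obs) {
  resp_r <- sqrt(obs$resp_u^2 + obs$resp_v^2)
  resp_th <- atan2(obs$resp_v, obs$resp_u)
  list(n_trials = nrow(obs),
       tau = obs$tau, t = obs$t, T = obs$T, n = obs$n,
       d_tau = obs$d_tau, d_t = obs$d_t, d_T = obs$d_T, d_n = obs$d_n,
       dr_t = resp_r - obs$target_r,
       dth_t = wrap_angle(resp_th - obs$target_th),
       dr_d = resp_r - obs$distr_r,
       dth_d = wrap_angle(resp_th - obs$distr_th),
       du = obs$resp_u - obs$target_r * cos(obs$target_th),
       dv = obs$resp_v - obs$target_r * sin(obs$target_th))
}

# per-trial log-likelihood vector at natural params, on a cache
loglik_vec <- function(model, params, cache) {
  if (model$id == 1) {
    s <- params[["alloc_enc"]] + params[["alloc_decay"]] * cache$tau
    return(.lognorm(cache$du, s) + .lognorm(cache$dv, s))
  }
  extra_t <- 0
  if (model$fixation) extra_t <- params[["fixation_decay"]] * cache$t
  if (model$saccade)
    extra_t <- cache$n * params[["saccade_enc"]] +
      params[["saccade_decay"]] * (cache$t + cache$T)
  sr <- params[["radial_enc"]] + params[["radial_decay"]] * cache$tau + extra_t
  sth <- params[["angular_enc"]] + params[["angular_decay"]] * cache$tau + extra_t
  ll_t <- .lognorm(cache$dr_t, sr) + .lognorm(cache$dth_t, sth)
  if (!model$interference) return(ll_t)
  extra_d <- 0
  if (model$fixation) extra_d <- params[["fixation_decay"]] * cache$d_t
  if (model$saccade)
    extra_d <- cache$d_n * params[["saccade_enc"]] +
      params[["saccade_decay"]] * (cache$d_t + cache$d_T)
  srd <- params[["radial_enc"]] + params[["radial_decay"]] * cache$d_tau + extra_d
  sthd <- params[["angular_enc"]] + params[["angular_decay"]] * cache$d_tau + extra_d
  ll_d <- .lognorm(cache$dr_d, srd) + .lognorm(cache$dth_d, sthd)
  w <- params[["interference"]]
  # log((1-w) e^ll_t + w e^ll_d), stably
  a <- log1p(-w) + ll_t
  b <- log(w) + ll_d
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Per-trial log-likelihood
#'
#' Log-density (nats) of one normalised observation under a model at
#' unconstrained parameters. For the allocentric model this is the product of
#' two univariate normals on the response's Euclidean coordinates about the
#' stimulus; for the dual models it is a normal on the response's radial
#' coordinate about the target radius times a normal on the wrapped angular
#' residual. Under interference the density is the mixture
#' \code{(1-w) * target + w * distractor}, the distractor component evaluated
#' at the distractor's own coordinates and timing variables.
#'
#' @param model A \code{\link{locus_model}} or id.
#' @param kappa Unconstrained parameter vector.
#' @param obs One or more rows of a normalised observation table (see
#'   \code{\link{normalize_trials}}).
#' @return Numeric vector of per-trial log-densities (nats).
#' @export
loglik_trial <- function(model, kappa, obs) {
  model <- as_locus_model(model)
  p <- transform_params(kappa, model)
  ll <- loglik_vec(model, p, obs_cache(obs))
  if (any(!is.finite(ll))) stop("non-finite log-density; check inputs")
  ll
}

#' Dataset log-likelihood
#'
#' Sum of per-trial log-densities over a subject's normalised observations;
#' 0 for an empty dataset. Refuses tables mixing subjects.
#'
#' @inheritParams loglik_trial
#' @return Scalar log-likelihood (nats).
#' @export
dataset_loglik <- function(model, kappa, obs) {
  if (!is.null(obs$subject) && length(unique(obs$subject)) > 1)
    stop("observation table mixes subjects; fit one subject at a time")
  if (nrow(obs) == 0) return(0)
  sum(loglik_trial(model, kappa, obs))
}

#' Normalise trials into the model's reference frame
#'
#' Applies, per trial, the rigid transform that every generative model
#' assumes: the origin is moved to the fixation at which the probed item was
#' viewed, and the plane is rotated so the target lies at the reference angle
#' 0 (along the positive x axis). The identical transform is applied to the
#' response and to the distractor location, so all distances are preserved.
#' Timing variables for target and distractor are attached.
#'
#' @param session A \code{\link{generate_session}} data frame.
#' @param responses Data frame with trial_id, resp_x, resp_y (and optionally
#'   resp_col), aligned to the session by trial_id.
#' @param task A \code{\link{locus_task}}; defaults to the session's own.
#' @return Data frame of class \code{c("locus_obs","data.frame")} with
#'   columns trial_id, target_r, target_th, distr_r, distr_th, resp_u,
#'   resp_v, tau, t, T, n, d_tau, d_t, d_T, d_n.
#' @export
normalize_trials <- function(session, responses, task = session_task(session)) {
  m <- match(session$trial_id, responses$trial_id)
  if (anyNA(m)) stop("responses missing for trial(s): ",
                     paste(session$trial_id[is.na(m)], collapse = ", "))
  responses <- responses[m, ]
  if (any(!is.finite(responses$resp_x)) || any(!is.finite(responses$resp_y)))
    stop("non-finite response coordinates")
  probed <- session$probed
  other <- 3L - probed
  fix <- item_fixation(session, probed)
  tgt <- item_location(session, probed) - fix
  dis <- item_location(session, other) - fix
  rsp <- cbind(responses$resp_x, responses$resp_y) - fix
  alpha <- atan2(tgt[, 2], tgt[, 1])
  ca <- cos(-alpha); sa <- sin(-alpha)
  rot <- function(p) cbind(ca * p[, 1] - sa * p[, 2], sa * p[, 1] + ca * p[, 2])
  tgt_n <- rot(tgt); dis_n <- rot(dis); rsp_n <- rot(rsp)
  tim_t <- session_timing(session, probed, task)
  tim_d <- session_timing(session, other, task)
  out <- data.frame(
    trial_id = session$trial_id,
    target_r = sqrt(rowSums(tgt_n^2)), target_th = 0,
    distr_r = sqrt(rowSums(dis_n^2)),
    distr_th = atan2(dis_n[, 2], dis_n[, 1]),
    resp_u = rsp_n[, 1], resp_v = rsp_n[, 2],
    tau = tim_t$tau, t = tim_t$t, T = tim_t$T, n = tim_t$n,
    d_tau = tim_d$tau, d_t = tim_d$t, d_T = tim_d$T, d_n = tim_d$n)
  class(out) <- c("locus_obs", "data.frame")
  out
}
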