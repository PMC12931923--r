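#' Parametric-empirical-Bayes group model over first-level fits
#'
#' Second-level Bayesian linear model over subjects' posterior parameter
#' estimates, run marginally for each model parameter. For parameter p the
#' model is \code{theta_i ~ N((X beta)_i, sigma2_between + v_i)}, where
#' \code{theta_i} is subject i's posterior mode, \code{v_i} its first-level
#' posterior variance for that parameter (so subjects with wider posteriors
#' weigh less), and \code{sigma2_between} is estimated by restricted
#' maximum likelihood within the precision-weighted model. The posterior
#' over \code{beta} is Gaussian; with the default flat coefficient prior it
#' coincides with the generalised-least-squares solution, and a proper
#' zero-mean Gaussian prior can be requested via \code{prior_var}.
#'
#' @param fits List of \code{\link{locus_fit}} objects, one per subject, all
#'   of the same model.
#' @param design Subjects x regressors numeric matrix (e.g. group
#'   indicators); must have full column rank. Column names label the groups.
#' @param prior_var Prior variance per second-level coefficient;
#'   \code{Inf} (default) for a flat prior.
#' @return Object of class \code{"locus_peb"}: \code{beta_mean} (regressors
#'   x parameters), \code{beta_cov} (list of per-parameter covariance
#'   matrices), \code{sigma2_between} per parameter, \code{design}.
#' @export
fit_peb <- function(fits, design, prior_var = Inf) {
  design <- as.matrix(design)
  ids <- vapply(fits, function(f) f$model$id, integer(1))
  if (length(unique(ids)) != 1) stop("all fits must share one model")
  if (nrow(design) != length(fits))
    stop("design must have one row per subject fit")
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  if (is.null(colnames(design)))
    colnames(design) <- paste0("g", seq_len(ncol(design)))
  model <- fits[[1]]$model
  pn <- model$params
  theta <- t(vapply(fits, function(f) f$mode, numeric(length(pn))))
  v <- t(vapply(fits, function(f) diag(f$covariance), numeric(length(pn))))
  q <- ncol(design)
  beta_mean <- matrix(NA_real_, q, length(pn),
                      dimnames = list(colnames(design), pn))
  beta_cov <- vector("list", length(pn)); names(beta_cov) <- pn
  s2b <- numeric(length(pn)); names(s2b) <- pn
  for (j in seq_along(pn)) {
    y <- theta[, j]; vj <- v[, j]
    reml <- function(ls2) {
      w <- 1 / (exp(ls2) + vj)
      A <- crossprod(design * w, design)
      b <- solve(A, crossprod(design * w, y))
      r <- y - design %*% b
      -0.5 * (sum(log(1 / w)) +
                as.numeric(determinant(A, logarithm = TRUE)$modulus) +
                sum(w * r^2))
    }
    opt <- stats::optimize(reml, c(-20, 10), maximum = TRUE)
    s2b[j] <- exp(opt$maximum)
    w <- 1 / (s2b[j] + vj)
    prec <- crossprod(design * w, design)
    if (is.finite(prior_var)) prec <- prec + diag(1 / prior_var, q)
    Sig <- solve(prec)
    beta_cov[[j]] <- (Sig + t(Sig)) / 2
    beta_mean[, j] <- Sig %*% crossprod(design * w, y)
  }
  structure(list(model = model, beta_mean = beta_mean, beta_cov = beta_cov,
                 sigma2_between = s2b, design = design,
                 prior_var = prior_var),
            class = "locus_peb")
}

#' @export
print.locus_peb <- function(x, ...) {
  cat(sprintf("PEB group model for model %d (%s): %d subjects, %d regressors\n",
              x$model$id, x$model$name, nrow(x$design), ncol(x$design)))
  cat("posterior mean of group coefficients:\n")
  print(round(x$beta_mean, 4))
  cat("between-subject variance (REML):\n")
  print(signif(x$sigma2_between, 3))
  invisible(x)
}

#' Directional group-contrast probability
#'
#' Probability, under the Gaussian second-level posterior, that group A's
#' coefficient exceeds group B's for the given parameter:
#' \code{P(beta_A - beta_B > 0)}, a univariate normal tail probability. The
#' \code{significant} flag marks probabilities above 0.95 (strong evidence
#' for a directional difference).
#'
#' @param peb A \code{\link{fit_peb}} result.
#' @param param Parameter name (or index).
#' @param A,B Design column names (or indices).
#' @return List with \code{probability} and \code{significant}.
#' @export
contrast_probability <- function(peb, param, A, B) {
  pn <- colnames(peb$beta_mean)
  j <- if (is.character(param)) match(param, pn) else as.integer(param)
  if (is.na(j) || j < 1 || j > length(pn)) stop("unknown parameter: ", param)
  gn <- rownames(peb$beta_mean)
  a <- if (is.character(A)) match(A, gn) else as.integer(A)
  b <- if (is.character(B)) match(B, gn) else as.integer(B)
  if (anyNA(c(a, b)) || any(c(a, b) < 1) || any(c(a, b) > length(gn)))
    stop("unknown group label")
  S <- peb$beta_cov[[j]]
  mu <- peb$beta_mean[a, j] - peb$beta_mean[b, j]
  sd <- sqrt(S[a, a] + S[b, b] - 2 * S[a, b])
  p <- stats::pnorm(mu / sd)
  list(probability = p, significant = p > 0.95)
}

#' Bayesian regression of behavioural scores on model parameters
#'
#' Predicts a per-subject scalar score (e.g. a figure-copy score) from the
#' subjects' posterior-mode (MAP) model parameters. Scores more than 2
#' standard deviations from the mean are excluded, the remaining scores are
#' mean-centred, and each regressor is centred and divided by the square
#' root of its across-subject variance (so the fit is invariant to affine
#' rescaling of any regressor). The linear model, including a log
#' noise-variance parameter, is inverted with the same Laplace machinery as
#' the first-level models, under zero-mean Gaussian coefficient priors with
#' variance 1/8; the log noise variance gets a broad prior so the noise
#' level is driven by the data. Variance explained is
#' \code{100 * (1 - var(residuals) / var(empirical scores))} at the
#' posterior-mean predictions.
#'
#' @param map_params Subjects x parameters numeric matrix of MAP estimates.
#' @param scores Numeric per-subject scores.
#' @param prior_var Prior variance for the coefficients.
#' @param noise_prior_var Prior variance for the log noise variance.
#' @param control A \code{\link{locus_control}}.
#' @return Object of class \code{"locus_scorereg"}: \code{coefficients}
#'   (posterior mean and sd per regressor), \code{covariance},
#'   \code{variance_explained} (percent), \code{excluded_subjects},
#'   \code{dropped_regressors}, \code{fitted}, \code{residuals}.
#' @export
score_regression <- function(map_params, scores, prior_var = 1/8,
                             noise_prior_var = 16,
                             control = locus_control()) {
  X <- as.matrix(map_params)
  if (is.null(colnames(X))) colnames(X) <- paste0("p", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(scores))
  keep <- abs(scores - mean(scores)) <= 2 * stats::sd(scores)
  excluded <- which(!keep)
  X <- X[keep, , drop = FALSE]
  y <- scores[keep]
  if (nrow(X) < ncol(X) + 2)
    stop("need at least 2 more subjects than parameters after exclusion")
  y <- y - mean(y)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("zero-variance regressor(s) excluded: ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  p <- ncol(Z)
  ll <- function(k) {
    beta <- k[seq_len(p)]
    s2 <- exp(k[p + 1])
    sum(.lognorm(y - Z %*% beta, s2))
  }
  prior <- structure(list(mean = rep(0, p + 1),
                          variance = c(rep(prior_var, p), noise_prior_var)),
                     class = "locus_prior")
  res <- laplace_fit(ll, prior, control)
  beta <- res$mode[seq_len(p)]
  fitted <- drop(Z %*% beta)
  resid <- y - fitted
  varexp <- 100 * (1 - stats::var(resid) / stats::var(y))
  coefs <- data.frame(mean = beta,
                      sd = sqrt(diag(res$covariance))[seq_len(p)],
                      row.names = colnames(Z))
  structure(list(coefficients = coefs,
                 covariance = res$covariance[seq_len(p), seq_len(p), drop = FALSE],
                 noise_variance = exp(res$mode[p + 1]),
                 variance_explained = varexp,
                 excluded_subjects = excluded,
                 dropped_regressors = dropped,
                 fitted = fitted, residuals = resid,
                 free_energy = res$free_energy, converged = res$converged),
            class = "locus_scorereg")
}

#' @export
print.locus_scorereg <- function(x, ...) {
  cat("Bayesian score regression on MAP parameters\n")
  print(round(x$coefficients, 4))
  cat(sprintf("variance explained: %.2f%%   noise variance: %.3f\n",
              x$variance_explained, x$noise_variance))
  if (length(x$excluded_subjects))
    cat("excluded subjects (>2 SD):", paste(x$excluded_subjects, collapse = ", "), "\n")
  invisible(x)
}
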