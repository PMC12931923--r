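#' Fixed-effects Bayesian model comparison
#'
#' Accumulates per-subject log model evidences (free energies) over subjects
#' for each model, applies a softmax to the summed evidences to obtain
#' posterior model probabilities, and reports the Bayes factor as the ratio
#' of the top two posterior probabilities.
#'
#' @param evidences Numeric subjects x models matrix of log evidences
#'   (nats); all entries must be finite and every model must cover the same
#'   subjects (same rows).
#' @return Object of class \code{"locus_comparison"}: list with
#'   \code{summed_evidence}, \code{posterior_prob}, \code{bayes_factor_top2},
#'   \code{winner} (column index / name of the winning model).
#' @export
compare_models <- function(evidences) {
  evidences <- as.matrix(evidences)
  if (any(!is.finite(evidences))) stop("evidences must all be finite")
  if (is.null(colnames(evidences)))
    colnames(evidences) <- paste0("model", seq_len(ncol(evidences)))
  summed <- colSums(evidences)
  z <- summed - max(summed)
  post <- exp(z) / sum(exp(z))
  ord <- order(post, decreasing = TRUE)
  structure(list(summed_evidence = summed, posterior_prob = post,
                 bayes_factor_top2 = unname(post[ord[1]] / post[ord[2]]),
                 winner = colnames(evidences)[ord[1]]),
            class = "locus_comparison")
}

#' @export
print.locus_comparison <- function(x, ...) {
  cat("Fixed-effects Bayesian model comparison\n")
  tab <- data.frame(summed_evidence = round(x$summed_evidence, 2),
                    posterior_prob = round(x$posterior_prob, 4))
  print(tab)
  cat(sprintf("winner: %s (Bayes factor over runner-up: %.3f)\n",
              x$winner, x$bayes_factor_top2))
  invisible(x)
}

#' Model and parameter recovery analysis
#'
#' Simulates synthetic subjects from each generating model with parameters
#' drawn from the prior (zero mean, spherical variance 1/8 in unconstrained
#' space), fits every candidate model to every synthetic subject by Laplace
#' inversion, and accumulates evidence per generating model into a
#' column-stochastic confusion matrix (columns = generating model, rows =
#' fitted model, entries = softmax of summed evidence). For
#' \code{correlation_model}, also reports the Pearson correlation between
#' generating and recovered (posterior-mode) values of each parameter,
#' pooling the subjects generated from that model.
#'
#' @param n_subjects Synthetic subjects per generating model.
#' @param trials_per_subject Trials in each synthetic session.
#' @param seed Integer root seed.
#' @param gen_models Generating model ids.
#' @param fit_models Candidate model ids fitted to every dataset.
#' @param correlation_model Model id whose parameter recovery is correlated
#'   (must be in \code{gen_models} and \code{fit_models}); NULL to skip.
#' @param task,control Passed through to the generator and fitter.
#' @return Object of class \code{"locus_recovery"}: \code{confusion}
#'   (fitted x generating matrix, columns summing to 1),
#'   \code{param_correlations}, \code{evidence} (subject-level array),
#'   \code{true_params} and \code{recovered_params} for
#'   \code{correlation_model}, and \code{failed} (fits that errored,
#'   recorded and excluded with a warning).
#' @export
recovery_analysis <- function(n_subjects = 16, trials_per_subject = 160,
                              seed = 1, gen_models = 1:7, fit_models = 1:7,
                              correlation_model = 7, task = locus_task(),
                              control = locus_control()) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  gen_specs <- lapply(gen_models, locus_model)
  fit_specs <- lapply(fit_models, locus_model)
  seeds <- matrix(derive_seeds(seed, 2 * length(gen_models) * n_subjects),
                  nrow = 2)
  evid <- array(NA_real_,
                dim = c(n_subjects, length(fit_models), length(gen_models)),
                dimnames = list(NULL, paste0("fit", fit_models),
                                paste0("gen", gen_models)))
  truth <- recov <- NULL
  failed <- list()
  col <- 0
  for (gi in seq_along(gen_models)) {
    gm <- gen_specs[[gi]]
    d <- length(gm$params)
    for (s in seq_len(n_subjects)) {
      col <- col + 1
      set.seed(seeds[1, col])
      kappa <- stats::rnorm(d, 0, sqrt(1/8))
      names(kappa) <- gm$params
      sess <- generate_session(seeds[2, col], trials_per_subject, task)
      resp <- simulate_responses(sess, gm, kappa, seed = seeds[2, col] + 1L)
      obs <- normalize_trials(sess, resp)
      for (fi in seq_along(fit_models)) {
        fit <- tryCatch(locus_fit(fit_specs[[fi]], obs, control = control),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          failed[[length(failed) + 1]] <-
            list(gen = gm$id, subject = s, fit = fit_models[fi],
                 message = conditionMessage(fit))
          next
        }
        evid[s, fi, gi] <- fit$free_energy
        if (!is.null(correlation_model) &&
            gm$id == correlation_model && fit$model$id == correlation_model) {
          truth <- rbind(truth, kappa)
          recov <- rbind(recov, fit$mode)
        }
      }
    }
  }
  if (length(failed))
    warning(length(failed), " fit(s) failed and were excluded from recovery")
  confusion <- vapply(seq_along(gen_models), function(gi) {
    z <- colSums(matrix(evid[, , gi], ncol = length(fit_models)), na.rm = TRUE)
    z <- z - max(z)
    exp(z) / sum(exp(z))
  }, numeric(length(fit_models)))
  confusion <- matrix(confusion, nrow = length(fit_models),
                      dimnames = list(paste0("fit", fit_models),
                                      paste0("gen", gen_models)))
  pc <- NULL
  if (!is.null(truth)) {
    pc <- vapply(seq_len(ncol(truth)),
                 function(j) stats::cor(truth[, j], recov[, j]), numeric(1))
    names(pc) <- locus_model(correlation_model)$params
  }
  structure(list(confusion = confusion, param_correlations = pc,
                 evidence = evid, true_params = truth,
                 recovered_params = recov, failed = failed,
                 n_subjects = n_subjects,
                 trials_per_subject = trials_per_subject, seed = seed),
            class = "locus_recovery")
}

#' @export
print.locus_recovery <- function(x, ...) {
  cat(sprintf("Recovery analysis: %d subjects x %d trials per generating model\n",
              x$n_subjects, x$trials_per_subject))
  cat("confusion matrix (columns = generating model, softmax-normalised):\n")
  print(round(x$confusion, 3))
  if (!is.null(x$param_correlations)) {
    cat("parameter recovery correlations:\n")
    print(round(x$param_correlations, 3))
  }
  if (length(x$failed)) cat(length(x$failed), "fits failed and were excluded\n")
  invisible(x)
}
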