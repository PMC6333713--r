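#' @export
print.mdmc_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s fit (%d conditions, %d trials, %d free parameters)\n",
              x$variant, length(x$conditions), sum(x$n_c), x$n_free))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("G2 = %.2f, BIC = %.2f (penalty N = %g)\n",
              x$g2, x$bic, x$n_total))
  invisible(x)
}

#' @export
summary.mdmc_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mdmc_fit")
}

#' @export
print.summary.mdmc_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\nRT filter: [%g, %g] ms (%.2f%% of trials excluded)\n",
              f$filter[1], f$filter[2], 100 * f$excluded_fraction))
  cat(sprintf("Objective: %d simulated trials/condition, seed %d\n",
              f$n_sim, f$seed))
  cat("Starts (Nelder-Mead):\n")
  print(f$starts, row.names = FALSE)
  acc <- vapply(f$observed, `[[`, numeric(1), "accuracy")
  cat("\nObserved accuracy by condition:\n")
  print(round(acc, 3))
  invisible(x)
}

#' Extract fitted free parameters
#'
#' @param object an `mdmc_fit`.
#' @param ... unused.
#' @return named numeric vector of the free parameters.
#' @export
coef.mdmc_fit <- function(object, ...) object$coefficients

#' @export
BIC.mdmc_fit <- function(object, ...) object$bic

#' Model-predicted proportions of a fitted model
#'
#' Re-simulates the fitted model and scores the predictions into the
#' observed bin edges of every condition, reproducing the proportion
#' vectors the objective was computed from.
#'
#' @param object an `mdmc_fit`.
#' @param n_sim simulated trials per condition (default: as fitted).
#' @param seed simulation seed (default: the fit's common-random-number
#'   seed, reproducing the fitted `g2` exactly).
#' @param ... unused.
#' @return matrix (conditions x 10 slots) of predicted proportions, with
#'   attribute `"g2"` holding the G-squared against the observed data.
#' @export
predict.mdmc_fit <- function(object, n_sim = object$n_sim,
                             seed = object$sim_seed, ...) {
  p_pred <- matrix(NA_real_, length(object$conditions), 10L,
                   dimnames = list(names(object$conditions),
                                   c(paste0("cdf", 1:5), paste0("caf", 1:5))))
  for (j in seq_along(object$conditions)) {
    set.seed(child_seed(seed, j))
    p_pred[j, ] <- predicted_proportions(
      object$params, object$conditions[[j]], object$observed[[j]]$edges,
      object$variant, n_sim = n_sim, time_cap = object$time_cap)$proportions
  }
  p_obs <- lapply(object$observed, `[[`, "proportions")
  attr(p_pred, "g2") <- g_squared(p_obs, split(p_pred, row(p_pred)), object$n_c)
  p_pred
}

#' Observed-minus-predicted proportion residuals
#'
#' @inheritParams predict.mdmc_fit
#' @return matrix (conditions x 10 slots) of residuals.
#' @export
residuals.mdmc_fit <- function(object, n_sim = object$n_sim, ...) {
  pred <- predict(object, n_sim = n_sim)
  obs <- t(vapply(object$observed, `[[`, numeric(10), "proportions"))
  colnames(obs) <- colnames(pred)
  obs - pred
}

#' Simulate trial-level data from a fitted model
#'
#' @param object an `mdmc_fit`.
#' @param nsim trials per congruency condition.
#' @param seed integer seed.
#' @param ... unused.
#' @return a trial table (see [simulate_trial()]).
#' @export
simulate.mdmc_fit <- function(object, nsim = 1000L, seed = 1L, ...) {
  simulate_experiment(object$params, object$conditions, nsim,
                      object$variant, seed = seed,
                      time_cap = object$time_cap)
}

#' Plot a fitted model against the observed summaries
#'
#' `type = "cdf"` overlays observed CDF quantile points and model-predicted
#' quantile curves per condition; `type = "caf"` does the same for the
#' conditional accuracy functions; `type = "delta"` shows the model-implied
#' delta functions of each modality's marginal (incongruent minus congruent
#' quantiles at percentiles 5, 10, ..., 95).
#'
#' @param x an `mdmc_fit`.
#' @param type one of `"cdf"`, `"caf"`, `"delta"`.
#' @param n_sim simulated trials per condition behind the predicted curves.
#' @param seed simulation seed.
#' @param ... passed to the underlying plot calls.
#' @return invisibly, the simulated trial table behind the curves.
#' @export
plot.mdmc_fit <- function(x, type = c("cdf", "caf", "delta"),
                          n_sim = 10000L, seed = 1L, ...) {
  type <- match.arg(type)
  sim <- simulate.mdmc_fit(x, nsim = n_sim, seed = seed)
  sim <- filter_rts(sim, x$filter[1], x$filter[2])$table
  codes <- names(x$conditions)
  key_of <- function(tab) {
    k <- rep("", nrow(tab))
    for (m in x$modalities)
      k <- paste0(k, toupper(substr(tab[[m]], 1, 1)),
                  toupper(substr(m, 1, 1)))
    k
  }
  ks <- key_of(sim)
  old <- par(mfrow = c(3, 3), mar = c(3.5, 3.5, 2, 0.5), mgp = c(2, 0.7, 0))
  on.exit(par(old))
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  if (type == "cdf") {
    for (cc in codes) {
      obs_q <- x$observed[[cc]]$edges$cdf_q
      sub <- sim[ks == cc & sim$accuracy == 1L, , drop = FALSE]
      prd_q <- cdf_quantiles(sub$rt, probs)$values
      plot(obs_q, probs, xlim = range(obs_q, prd_q), ylim = c(0, 1),
           xlab = "RT (ms)", ylab = "CDF", main = cc, pch = 16, ...)
      lines(prd_q, probs, col = 2)
    }
  } else if (type == "caf") {
    for (cc in codes) {
      obs <- x$observed[[cc]]
      # reconstruct observed CAF accuracies from the stored proportions
      err <- obs$proportions[6:10]
      bins <- caf_bin_sizes(obs$n, 5L) / obs$n
      obs_acc <- 1 - err / bins
      sub <- sim[ks == cc, , drop = FALSE]
      prd_acc <- caf(sub)$accuracy
      plot(seq_len(5), obs_acc, ylim = c(0, 1), xlab = "RT quintile",
           ylab = "P(correct)", main = cc, pch = 16, ...)
      lines(seq_len(5), prd_acc, col = 2)
    }
  } else {
    old2 <- par(mfrow = c(1, length(x$modalities)))
    probs2 <- seq(0.05, 0.95, by = 0.05)
    for (m in x$modalities) {
      other <- setdiff(x$modalities, m)[1]
      qc <- marginal_cdf(marginal_tables(sim, m, "congruent", other), probs2)
      qi <- marginal_cdf(marginal_tables(sim, m, "incongruent", other), probs2)
      d <- delta_function(qc, qi)
      plot(d$midpoint, d$delta, type = "b", pch = 16,
           xlab = "RT (ms)", ylab = expression(Delta ~ "(ms)"),
           main = paste(m, "delta"), ...)
      abline(h = 0, lty = 3)
    }
    par(old2)
  }
  invisible(sim)
}
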