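# Two-sided paired sign-flip permutation test on a vector of paired
# differences. Returns the permutation p-value for the mean difference; with
# all-zero differences every permutation ties and p = 1.
paired_permutation_test <- function(d, n_perms = 50000L, seed = 1L) {
  n <- length(d)
  obs <- abs(mean(d))
  set.seed(seed)
  exceed <- 0L
  chunk <- 2000L
  left <- n_perms
  while (left > 0L) {
    k <- min(chunk, left)
    signs <- matrix(sample(c(-1, 1), n * k, replace = TRUE), n, k)
    stats <- abs(colMeans(signs * d))
    exceed <- exceed + sum(stats >= obs - 1e-12)
    left <- left - k
  }
  (1 + exceed) / (n_perms + 1)
}

#' Compare two fitted model variants by paired permutation test
#'
#' Simulates `n_sims` independent G-squared (and BIC) values per model at
#' its fitted parameters, each time re-simulating the Monte-Carlo
#' predictions with a fresh seed and scoring them against the fixed observed
#' proportions. The paired per-replicate differences between the two models
#' are tested with a two-sided sign-flip permutation test (`n_perms` random
#' sign assignments) on the mean difference.
#'
#' @param fit_a,fit_b `mdmc_fit` objects fitted to the same data (checked
#'   via their observed proportion vectors).
#' @param n_sims number of simulated fit statistics per model, default 1000.
#' @param n_perms number of sign-flip permutations, default 50000.
#' @param n_sim simulated trials per condition per statistic (default: each
#'   fit's own `n_sim`).
#' @param seed integer seed.
#' @return list of class `mdmc_comparison`: `p_g2`, `p_bic` (two-sided
#'   p-values), `mean_g2`, `mean_bic` (per model), and the simulated
#'   statistic vectors.
#' @export
compare_models <- function(fit_a, fit_b, n_sims = 1000L, n_perms = 50000L,
                           n_sim = NULL, seed = 1L) {
  stopifnot(inherits(fit_a, "mdmc_fit"), inherits(fit_b, "mdmc_fit"))
  obs_a <- lapply(fit_a$observed, `[[`, "proportions")
  obs_b <- lapply(fit_b$observed, `[[`, "proportions")
  if (!isTRUE(all.equal(obs_a, obs_b)) || !isTRUE(all.equal(fit_a$n_c, fit_b$n_c)))
    stop("the two fits are not based on the same data", call. = FALSE)

  g2_samples <- function(fit, ns) {
    vapply(seq_len(n_sims), function(s) {
      p_pred <- lapply(seq_along(fit$conditions), function(j) {
        set.seed(child_seed(child_seed(seed, s), j))
        predicted_proportions(fit$params, fit$conditions[[j]],
                              fit$observed[[j]]$edges, fit$variant,
                              n_sim = ns, time_cap = fit$time_cap)$proportions
      })
      g_squared(lapply(fit$observed, `[[`, "proportions"), p_pred, fit$n_c)
    }, numeric(1))
  }
  g2_a <- g2_samples(fit_a, if (is.null(n_sim)) fit_a$n_sim else n_sim)
  g2_b <- g2_samples(fit_b, if (is.null(n_sim)) fit_b$n_sim else n_sim)
  bic_a <- bic(g2_a, fit_a$n_free, fit_a$n_total)
  bic_b <- bic(g2_b, fit_b$n_free, fit_b$n_total)

  structure(list(
    p_g2 = paired_permutation_test(g2_a - g2_b, n_perms, child_seed(seed, 1L)),
    p_bic = paired_permutation_test(bic_a - bic_b, n_perms, child_seed(seed, 2L)),
    mean_g2 = c(a = mean(g2_a), b = mean(g2_b)),
    mean_bic = c(a = mean(bic_a), b = mean(bic_b)),
    g2 = cbind(a = g2_a, b = g2_b), bic = cbind(a = bic_a, b = bic_b),
    n_sims = n_sims, n_perms = n_perms,
    variants = c(fit_a$variant, fit_b$variant)), class = "mdmc_comparison")
}

#' @export
print.mdmc_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%s vs %s), %d simulated statistics, %d permutations\n",
              x$variants[1], x$variants[2], x$n_sims, x$n_perms))
  cat(sprintf("  mean G2:  %.2f vs %.2f  (p = %.4g)\n",
              x$mean_g2[1], x$mean_g2[2], x$p_g2))
  cat(sprintf("  mean BIC: %.2f vs %.2f  (p = %.4g)\n",
              x$mean_bic[1], x$mean_bic[2], x$p_bic))
  invisible(x)
}
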