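#' Sample diffusion starting points
#'
#' The trial-to-trial starting point of the decision process is drawn from a
#' symmetric Beta(alpha, alpha) distribution rescaled to the open interval
#' (-b, b): `x = 2 * b * Beta(alpha, alpha) - b`. Its mean is 0 and its
#' variance `b^2 / (2 * alpha + 1)`; alpha = 1 gives a uniform start, large
#' alpha concentrates the start at 0.
#'
#' @param n number of draws.
#' @param start_shape Beta shape alpha > 0.
#' @param boundary decision boundary b > 0.
#' @return numeric vector of `n` starting points in (-b, b).
#' @examples
#' set.seed(1); range(sample_start_point(1e4, 3.1, 54.6))
#' @export
sample_start_point <- function(n, start_shape, boundary) {
  if (!is.numeric(start_shape) || start_shape <= 0)
    stop("'start_shape' must be > 0", call. = FALSE)
  if (!is.numeric(boundary) || boundary <= 0)
    stop("'boundary' must be > 0", call. = FALSE)
  2 * boundary * rbeta(n, start_shape, start_shape) - boundary
}

#' Simulate decision times and responses
#'
#' Runs `n` trials of the superimposed diffusion by Euler discretisation:
#' `X(t + dt) = X(t) + mu(t) dt + sigma sqrt(dt) Z`, with total drift
#' `mu(t) = mu_c + sum of automatic drifts` signed by the condition, starting
#' points from [sample_start_point()], and absorption at `+b` (correct) or
#' `-b` (error). Trials not absorbed within `time_cap` ms are flagged
#' censored. Automatic drift on the first step is evaluated at `t = dt`, so
#' the `1/t` singularity of the drift formula at 0 is never touched.
#'
#' Uses R's RNG stream: call `set.seed()` beforehand for reproducibility.
#'
#' @param params an [mdmc_params()] object.
#' @param condition a [congruency_condition()] matching `params`.
#' @param n number of trials.
#' @param time_cap maximum decision time in ms (default 5000).
#' @param fixed_start optional scalar: start every trial at this state
#'   instead of sampling (used for closed-form checks).
#' @return data.frame with columns `decision_time` (ms), `correct` (0/1,
#'   `NA` when censored) and `censored` (logical).
#' @examples
#' p <- mdmc_preset("vt_mdmc")
#' cond <- all_conditions(c("visual", "tactile"))[["CVCT"]]
#' set.seed(1); head(simulate_decision(p, cond, 5))
#' @export
simulate_decision <- function(params, condition, n = 1L, time_cap = 5000,
                              fixed_start = NULL) {
  stopifnot(is.mdmc_params(params))
  condition <- check_condition(params, condition)
  max_steps <- as.integer(ceiling(time_cap / params$dt))
  mu <- drift_on_grid(params, condition, max_steps)
  start <- if (is.null(fixed_start))
    sample_start_point(n, params$start_shape, params$boundary)
  else rep(as.numeric(fixed_start), n)
  out <- cpp_first_passage(start, mu, params$sigma, params$dt, params$boundary)
  data.frame(decision_time = out$decision_time, correct = out$correct,
             censored = out$censored)
}

# Residual (non-decision) times: Normal(mean, sigma_r) truncated to > 0 by
# redraw. At realistic scales (mu_r / sigma_r ~ 9) redraws are vanishingly
# rare, so the truncation bias is negligible.
sample_residual <- function(n, mean, sd) {
  r <- rnorm(n, mean, sd)
  while (any(bad <- r <= 0)) r[bad] <- rnorm(sum(bad), mean, sd)
  r
}

residual_mean <- function(params, condition, variant) {
  if (variant == "FN-MDMC" &&
      identical(unname(condition[["visual"]]), "neutral")) params$mu_rn
  else params$mu_r
}

#' Simulate complete trials (decision + residual time)
#'
#' The reaction time is the sum of the decision time `D` and a residual
#' (non-decision) time `R ~ Normal(mu, sigma_r)` truncated to positive
#' values. Under MDMC the residual mean is always `mu_r`; under FN-MDMC it
#' is `mu_rn` when the visual modality's label is neutral, reflecting faster
#' residual processing of foveal (central) visual stimuli.
#'
#' @inheritParams simulate_decision
#' @param variant `"MDMC"` or `"FN-MDMC"`; defaults to the variant of
#'   `params` (FN-MDMC requires `mu_rn`).
#' @param participant participant identifier stored with each trial.
#' @return A trial table: data.frame with `participant`, one congruency
#'   column per modality, `rt` (ms), `accuracy` (0/1) and `censored`.
#' @export
simulate_trial <- function(params, condition, n = 1L,
                           variant = variant_of(params),
                           participant = 1L, time_cap = 5000) {
  variant <- match.arg(variant, c("MDMC", "FN-MDMC"))
  if (variant == "FN-MDMC" && is.null(params$mu_rn))
    stop("FN-MDMC requires 'mu_rn' in the parameter set", call. = FALSE)
  condition <- check_condition(params, condition)
  dec <- simulate_decision(params, condition, n, time_cap)
  rt <- dec$decision_time +
    sample_residual(n, residual_mean(params, condition, variant), params$sigma_r)
  tab <- data.frame(participant = rep(participant, n))
  for (m in names(condition)) tab[[m]] <- unname(condition[[m]])
  tab$rt <- rt
  tab$accuracy <- dec$correct
  tab$censored <- dec$censored
  tab
}

# Deterministic per-condition child seed below 2^31 so one condition's
# stream does not depend on how many trials the others draw.
child_seed <- function(seed, j) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + 7919 * as.numeric(j)
  as.integer(s %% 2147483647)
}

#' Simulate a full factorial experiment
#'
#' Generates `n_per_condition` trials for each congruency condition, with an
#' independent, deterministically derived RNG sub-stream per condition: the
#' output for one condition is unchanged if another condition's trial count
#' changes, and the whole table is bit-identical under the same `seed`.
#'
#' @inheritParams simulate_trial
#' @param conditions named list of conditions, e.g. from [all_conditions()];
#'   must be non-empty.
#' @param n_per_condition trials per condition (>= 1).
#' @param seed integer root seed.
#' @return A trial table (see [simulate_trial()]) with
#'   `length(conditions) * n_per_condition` rows.
#' @examples
#' p <- mdmc_preset("vt_mdmc")
#' tab <- simulate_experiment(p, all_conditions(c("visual", "tactile")),
#'                            n_per_condition = 100, seed = 1)
#' table(tab$visual, tab$tactile)
#' @export
simulate_experiment <- function(params, conditions, n_per_condition,
                                variant = variant_of(params), seed = 1L,
                                participant = 1L, time_cap = 5000) {
  if (length(conditions) == 0L) stop("'conditions' is empty", call. = FALSE)
  if (n_per_condition < 1L) stop("'n_per_condition' must be >= 1", call. = FALSE)
  out <- vector("list", length(conditions))
  for (j in seq_along(conditions)) {
    set.seed(child_seed(seed, j))
    out[[j]] <- simulate_trial(params, conditions[[j]], n_per_condition,
                               variant, participant, time_cap)
  }
  do.call(rbind, out)
}
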