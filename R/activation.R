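#' Expected automatic activation at time t
#'
#' The expected time course of one automatic process is a pulse shaped like a
#' rescaled Gamma density,
#' \deqn{E[X_a(t)] = A \, e^{-t/\tau} \left[\frac{t e}{(a-1)\tau}\right]^{a-1},}
#' scaled so that its maximum is exactly `A`, attained at \eqn{t = (a-1)\tau}.
#' The sign of the pulse encodes congruency: `sign = +1` (congruent) pushes
#' toward the correct boundary, `-1` (incongruent) toward the error boundary,
#' and `0` (neutral) removes the pulse.
#'
#' @param t time in ms, vectorised; must be >= 0.
#' @param spec an [automatic_spec()].
#' @param sign integer in `{+1, 0, -1}`, from [condition_sign()].
#' @return expected activation (accumulator units), same length as `t`.
#' @examples
#' automatic_activation(39, automatic_spec(13.4, 39), +1)  # the peak, 13.4
#' @export
automatic_activation <- function(t, spec, sign = 1L) {
  stopifnot(inherits(spec, "automatic_spec"), sign %in% c(-1L, 0L, 1L))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  a <- spec$shape
  sign * spec$amplitude * exp(-t / spec$tau) *
    (t * exp(1) / ((a - 1) * spec$tau))^(a - 1)
}

#' Time-dependent drift of an automatic process
#'
#' The drift contributed by an automatic pulse is the time derivative of
#' [automatic_activation()]:
#' \deqn{\mu_a(t) = A \, e^{-t/\tau}
#'   \left[\frac{t e}{(a-1)\tau}\right]^{a-1}
#'   \left[\frac{a-1}{t} - \frac{1}{\tau}\right].}
#' It is positive before the pulse peak at \eqn{(a-1)\tau}, crosses zero
#' there, and is negative afterwards (for `sign = +1`). The expression has a
#' `1/t` factor and is therefore only defined for `t > 0`; the simulator
#' evaluates the first Euler step at `t = dt`, never at 0.
#'
#' @inheritParams automatic_activation
#' @param t time in ms, vectorised; must be > 0.
#' @return drift in activation units per ms, same length as `t`.
#' @examples
#' automatic_drift(39, automatic_spec(13.4, 39), +1)  # zero at the peak
#' @export
automatic_drift <- function(t, spec, sign = 1L) {
  stopifnot(inherits(spec, "automatic_spec"), sign %in% c(-1L, 0L, 1L))
  if (any(t <= 0)) stop("'t' must be > 0", call. = FALSE)
  a <- spec$shape
  sign * spec$amplitude * exp(-t / spec$tau) *
    (t * exp(1) / ((a - 1) * spec$tau))^(a - 1) *
    ((a - 1) / t - 1 / spec$tau)
}

#' Expected path of the superimposed decision process
#'
#' The expected state of the decision process at time `t` is the linear
#' controlled component `mu_c * t` plus the expected automatic activation of
#' every task-irrelevant modality, each signed by its congruency label. With
#' all labels neutral the path is exactly linear.
#'
#' @param t time in ms, vectorised; >= 0.
#' @param params an [mdmc_params()] object.
#' @param condition a [congruency_condition()] (or named label vector) with
#'   exactly the modalities of `params`.
#' @return expected activation, same length as `t`.
#' @examples
#' p <- mdmc_preset("vt_mdmc")
#' expected_decision_path(100, p, congruency_condition(
#'   visual = "neutral", tactile = "neutral"))  # 0.52 * 100
#' @export
expected_decision_path <- function(t, params, condition) {
  stopifnot(is.mdmc_params(params))
  condition <- check_condition(params, condition)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  path <- params$mu_c * t
  for (m in names(params$automatic)) {
    s <- condition_sign(condition[[m]])
    if (s != 0L)
      path <- path + automatic_activation(t, params$automatic[[m]], s)
  }
  path
}

# Total drift of the superimposed process on the Euler grid t = dt, 2 dt, ...
# (the t = 0 singularity of the automatic drift is never evaluated).
drift_on_grid <- function(params, condition, max_steps) {
  tt <- seq_len(max_steps) * params$dt
  mu <- rep(params$mu_c, max_steps)
  for (m in names(params$automatic)) {
    s <- condition_sign(condition[[m]])
    if (s != 0L) mu <- mu + automatic_drift(tt, params$automatic[[m]], s)
  }
  mu
}
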