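# --- the 10-slot proportion vectors behind the G^2 objective ---------------
#
# Each congruency condition contributes ten observed proportions: five from
# the CDF of correct responses and five from the error side of the CAF.
#   CDF slots: the mass of correct responses falling in the inter-quantile
#     bins (-Inf, q.1], (q.1, q.3], (q.3, q.5], (q.5, q.7], (q.7, q.9],
#     where q.p are the RT quantiles of the observed correct responses;
#     relative to all trials these are (0.1, 0.2, 0.2, 0.2, 0.2) times the
#     condition accuracy (up to integer-count granularity).
#   CAF slots: the error mass inside each observed RT quintile bin (bins
#     over all trials, correct and error).
# Predictions are scored into the SAME observed bin edges, so all shape
# information lives in the predicted vector and an observed table scored
# against its own edges reproduces itself exactly.

score_proportions <- function(rt, accuracy, edges) {
  n <- length(rt)
  cdf_breaks <- c(-Inf, edges$cdf_q)
  rt_c <- rt[accuracy == 1L]
  cdf_counts <- if (length(rt_c))
    tabulate(findInterval(rt_c, cdf_breaks, left.open = TRUE), 6L)[1:5]
  else rep(0L, 5L)
  caf_breaks <- c(-Inf, edges$caf_edges, Inf)
  rt_e <- rt[accuracy == 0L]
  caf_counts <- if (length(rt_e))
    tabulate(findInterval(rt_e, caf_breaks, left.open = TRUE), 5L)
  else rep(0L, 5L)
  c(cdf_counts, caf_counts) / n
}

#' Observed proportion vector of one condition
#'
#' Builds the ten observed response proportions of one congruency condition
#' (five CDF-derived correct-response bins, five CAF-derived error bins)
#' together with the bin edges needed to score model predictions in the same
#' bins. See Details in [g_squared()] for how these enter the fit objective.
#'
#' @param table filtered trial table of a single condition.
#' @param probs CDF quantile probabilities, default (0.1, 0.3, 0.5, 0.7, 0.9).
#' @param n_bins number of CAF bins, default 5.
#' @param label condition name for error messages.
#' @return list with `proportions` (length 10), `n` (trial count), `accuracy`
#'   and `edges` (list of `cdf_q`, the correct-RT quantiles, and `caf_edges`,
#'   the four inner RT quintile boundaries).
#' @export
observed_proportions <- function(table, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 n_bins = 5L, label = "condition") {
  n <- nrow(table)
  rt_c <- table$rt[table$accuracy == 1L]
  if (length(rt_c) == 0L)
    stop("no correct responses in ", label, ": degenerate fit input",
         call. = FALSE)
  q <- cdf_quantiles(rt_c, probs, label = label)
  cf <- caf(table, n_bins)
  edges <- list(cdf_q = q$values,
                caf_edges = cf$bin_edges[seq_len(n_bins - 1L)])
  list(proportions = score_proportions(table$rt, table$accuracy, edges),
       n = n, accuracy = mean(table$accuracy), edges = edges)
}

#' Model-predicted proportion vector of one condition
#'
#' Simulates `n_sim` trials at the given parameters and scores the simulated
#' correct and error RTs into the observed bin edges from
#' [observed_proportions()]. Censored trials are dropped before scoring.
#' Each proportion is floored at `floor_at` to protect the logarithm in the
#' fit objective.
#'
#' @inheritParams simulate_trial
#' @param edges `edges` component of an [observed_proportions()] result.
#' @param n_sim number of simulated trials, default 50000.
#' @param floor_at lower floor for predicted proportions, default 1e-5.
#' @return list with `proportions` (length 10) and `n_sim`.
#' @export
predicted_proportions <- function(params, condition, edges,
                                  variant = variant_of(params),
                                  n_sim = 50000L, floor_at = 1e-5,
                                  time_cap = 5000) {
  sim <- simulate_trial(params, condition, n_sim, variant,
                        time_cap = time_cap)
  sim <- sim[!sim$censored, , drop = FALSE]
  p <- score_proportions(sim$rt, sim$accuracy, edges)
  list(proportions = pmax(p, floor_at), n_sim = n_sim)
}

#' G-squared discrepancy between observed and predicted proportions
#'
#' The fit statistic is
#' \deqn{G^2 = 2 \sum_c N_c \sum_i \left| p_{ci} \log(p_{ci}/\pi_{ci}) \right|,}
#' summed over the congruency conditions `c` and the ten proportion slots
#' `i` of each condition, with `0 log(0/pi)` defined as 0. Note the absolute
#' value around each term, which makes every slot's contribution
#' non-negative; `classical = TRUE` drops it and gives the usual signed
#' likelihood-ratio form (for sensitivity analysis).
#'
#' @param p observed proportions: numeric vector (one condition) or list of
#'   numeric vectors (one per condition).
#' @param pi predicted proportions, matching `p` in structure; all entries
#'   must be > 0 where the corresponding `p` is > 0.
#' @param n trial count(s) `N_c`, one per condition.
#' @param classical if `TRUE`, use the signed classical form.
#' @return the G-squared statistic (>= 0 for the default form).
#' @examples
#' g_squared(c(0.5, 0.5), c(0.25, 0.75), 100)  # 109.86
#' @export
g_squared <- function(p, pi, n, classical = FALSE) {
  if (!is.list(p)) p <- list(p)
  if (!is.list(pi)) pi <- list(pi)
  if (length(p) != length(pi) || length(n) != length(p))
    stop("'p', 'pi' and 'n' must have one entry per condition", call. = FALSE)
  total <- 0
  for (c_ in seq_along(p)) {
    pc <- p[[c_]]; qc <- pi[[c_]]
    if (length(pc) != length(qc))
      stop("proportion vectors differ in length in condition ", c_,
           call. = FALSE)
    if (any(qc <= 0 & pc > 0))
      stop("predicted proportion <= 0 where observed > 0 (flooring failed)",
           call. = FALSE)
    term <- ifelse(pc > 0, pc * log(pc / qc), 0)
    if (!classical) term <- abs(term)
    total <- total + n[[c_]] * sum(term)
  }
  2 * unname(total)
}

#' BIC from the G-squared statistic
#'
#' \deqn{BIC = G^2 + f \log N,} where `f` is the number of free parameters
#' and `N` the total number of observations entering the fit (natural log).
#'
#' @param g2 fitted G-squared value.
#' @param n_free number of free parameters `f`.
#' @param n_total total observation count (>= 1).
#' @return the BIC statistic.
#' @examples
#' bic(126.1, 9, 270)  # 176.5
#' @export
bic <- function(g2, n_free, n_total) {
  if (n_total < 1) stop("'n_total' must be >= 1", call. = FALSE)
  g2 + n_free * log(n_total)
}
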