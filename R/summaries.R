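#' Filter reaction times to the analysis window
#'
#' Keeps trials with `lo <= rt <= hi` (closed interval: only RTs strictly
#' outside the window are discarded) and drops censored trials. The standard
#' analysis window for these tasks is 150-1200 ms.
#'
#' @param table a trial table (see [simulate_trial()]).
#' @param lo,hi window bounds in ms, `lo < hi`.
#' @return list with `table` (the kept rows) and `excluded_fraction`, the
#'   fraction of input rows removed (0 for empty input).
#' @examples
#' t <- data.frame(participant = 1, rt = c(100, 200, 1300),
#'                 accuracy = 1, censored = FALSE)
#' filter_rts(t)$excluded_fraction  # 2/3
#' @export
filter_rts <- function(table, lo = 150, hi = 1200) {
  if (lo >= hi) stop("'lo' must be < 'hi'", call. = FALSE)
  n <- nrow(table)
  if (n == 0L) return(list(table = table, excluded_fraction = 0))
  censored <- if ("censored" %in% names(table)) table$censored else FALSE
  keep <- !censored & table$rt >= lo & table$rt <= hi
  list(table = table[keep, , drop = FALSE],
       excluded_fraction = 1 - sum(keep) / n)
}

#' RT distribution quantiles
#'
#' Quantiles of the reaction-time distribution by linear interpolation
#' between order statistics with plotting position `(k-1)/(n-1)`
#' (`stats::quantile()` type 7). The default probabilities are the five CDF
#' quantiles (0.1, 0.3, 0.5, 0.7, 0.9) used for model fitting.
#'
#' @param rts numeric vector of RTs in ms (at least 5 observations).
#' @param probs strictly increasing probabilities in (0, 1).
#' @param label condition name used in error messages.
#' @return list of class `quantile_set` with `probs` and `values` (ms).
#' @examples
#' cdf_quantiles(1:1000)$values  # 100.9 300.7 500.5 700.3 900.1
#' @export
cdf_quantiles <- function(rts, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                          label = "sample") {
  if (any(diff(probs) <= 0) || any(probs <= 0) || any(probs >= 1))
    stop("'probs' must be strictly increasing within (0, 1)", call. = FALSE)
  if (length(rts) < 5L)
    stop("condition '", label, "' has fewer than 5 observations", call. = FALSE)
  structure(list(probs = probs,
                 values = unname(quantile(rts, probs, type = 7, names = FALSE))),
            class = "quantile_set")
}

# Bin sizes for n trials in n_bins near-equal contiguous bins; earlier bins
# absorb the remainder.
caf_bin_sizes <- function(n, n_bins) {
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  r <- n %% n_bins
  if (r > 0) sizes[seq_len(r)] <- base + 1L
  sizes
}

#' Conditional accuracy function
#'
#' Sorts all trials of one condition (correct and error) from fastest to
#' slowest, partitions them into `n_bins` contiguous bins of near-equal
#' count (earlier bins take the remainder; RT ties keep stable input order),
#' and reports the proportion of correct responses per bin.
#'
#' @param table trial table for a single condition (non-empty).
#' @param n_bins number of RT bins, default 5 (quintiles).
#' @return list of class `caf_profile` with `accuracy` (per bin), `counts`,
#'   and `bin_edges` (the slowest RT in each bin, ms).
#' @examples
#' t <- data.frame(rt = 1:10, accuracy = c(0, 0, rep(1, 8)))
#' caf(t)$accuracy  # 0 1 1 1 1
#' @export
caf <- function(table, n_bins = 5L) {
  n <- nrow(table)
  if (n == 0L) stop("empty trial table", call. = FALSE)
  if (n_bins > n) stop("n_bins (", n_bins, ") exceeds trial count (", n, ")",
                       call. = FALSE)
  ord <- order(table$rt)  # stable for ties
  acc <- table$accuracy[ord]
  rt <- table$rt[ord]
  sizes <- caf_bin_sizes(n, n_bins)
  idx <- rep(seq_len(n_bins), sizes)
  structure(list(accuracy = as.numeric(tapply(acc, idx, mean)),
                 counts = as.integer(sizes),
                 bin_edges = as.numeric(tapply(rt, idx, max))),
            class = "caf_profile")
}

#' Delta function (congruency effect across the RT distribution)
#'
#' For matched quantile sets of the congruent and incongruent condition,
#' the delta function is the incongruent-minus-congruent quantile difference
#' plotted against the mean of the two quantiles. Negative-going delta
#' functions (the effect shrinking, then reversing, for slow responses) are
#' the classic Simon-task signature.
#'
#' @param cong,incong `quantile_set` objects with identical `probs`.
#' @return data.frame with `prob`, `midpoint` (ms) and `delta` (ms).
#' @export
delta_function <- function(cong, incong) {
  if (!isTRUE(all.equal(cong$probs, incong$probs)))
    stop("quantile sets have different probabilities", call. = FALSE)
  data.frame(prob = cong$probs,
             midpoint = (cong$values + incong$values) / 2,
             delta = incong$values - cong$values)
}

#' Marginal CDF quantiles for one modality's congruency level
#'
#' Marginalises over the other modality by computing the quantiles per
#' condition and averaging them pointwise across the three conditions (the
#' per-condition-then-average convention used for the figure CDFs), not by
#' pooling trials.
#'
#' @param tables list of exactly three trial tables, one per level of the
#'   other modality, all for one fixed label of the modality of interest.
#' @param probs quantile probabilities.
#' @return A `quantile_set`.
#' @export
marginal_cdf <- function(tables, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (!is.list(tables) || length(tables) != 3L || any(vapply(tables, is.null, logical(1))))
    stop("'tables' must list the three conditions of the other modality",
         call. = FALSE)
  qs <- lapply(seq_along(tables), function(i)
    cdf_quantiles(tables[[i]]$rt, probs, label = paste("table", i))$values)
  structure(list(probs = probs, values = Reduce(`+`, qs) / length(qs)),
            class = "quantile_set")
}

# Split a trial table into per-condition tables keyed by condition code
# (e.g. CVIT for congruent-visual incongruent-tactile).
split_conditions <- function(table, modalities) {
  key <- rep("", nrow(table))
  for (m in modalities)
    key <- paste0(key, toupper(substr(table[[m]], 1, 1)),
                  toupper(substr(m, 1, 1)))
  split(table, key)
}

#' Split out the three tables behind one marginal CDF
#'
#' Selects the trials with `label` on `modality` and returns them split by
#' the `other` modality's three congruency levels, in the order congruent,
#' neutral, incongruent — the inputs [marginal_cdf()] expects.
#'
#' @param table a trial table.
#' @param modality,label the modality and congruency level of interest.
#' @param other the modality marginalised over.
#' @return list of three trial tables.
#' @export
marginal_tables <- function(table, modality, label, other) {
  sub <- table[table[[modality]] == label, , drop = FALSE]
  lapply(.congruency_levels, function(l)
    sub[sub[[other]] == l, , drop = FALSE])
}
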