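#' Read and write trial tables as delimited text
#'
#' The on-disk schema is comma-separated UTF-8 with a header row:
#' `participant, visual_congruency, secondary_modality,
#' secondary_congruency, rt_ms, accuracy, censored`. In memory the table
#' uses one congruency column per modality (named `visual` and the
#' secondary modality's name), `rt`, `accuracy` and `censored`;
#' `write_trials()`/`read_trials()` convert between the two and round-trip
#' exactly. Malformed rows are reported with their file line numbers.
#'
#' @param path file path.
#' @return `read_trials()`: the trial table; `write_trials()`: `path`,
#'   invisibly.
#' @export
read_trials <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "visual_congruency", "secondary_modality",
            "secondary_congruency", "rt_ms", "accuracy", "censored")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  problems <- character(0)
  bad_rt <- !is.finite(raw$rt_ms) | raw$rt_ms <= 0
  if (any(bad_rt))
    problems <- c(problems, paste0("line ", line[bad_rt],
                                   ": rt_ms must be a positive number"))
  bad_acc <- !(raw$accuracy %in% c(0L, 1L))
  if (any(bad_acc))
    problems <- c(problems, paste0("line ", line[bad_acc],
                                   ": accuracy must be 0 or 1"))
  bad_lab <- !(raw$visual_congruency %in% .congruency_levels) |
    !(raw$secondary_congruency %in% .congruency_levels)
  if (any(bad_lab))
    problems <- c(problems, paste0("line ", line[bad_lab],
                                   ": invalid congruency label"))
  if (length(problems))
    stop("invalid rows in ", path, ":\n",
         paste(head(problems, 20), collapse = "\n"), call. = FALSE)
  secondary <- if (nrow(raw)) raw$secondary_modality[1] else "tactile"
  out <- data.frame(participant = raw$participant,
                    visual = raw$visual_congruency)
  out[[secondary]] <- raw$secondary_congruency
  out$rt <- raw$rt_ms
  out$accuracy <- as.integer(raw$accuracy)
  out$censored <- as.logical(raw$censored)
  out
}

#' @rdname read_trials
#' @param table a trial table (see [simulate_trial()]).
#' @export
write_trials <- function(table, path) {
  modalities <- setdiff(names(table), .reserved_cols)
  if (!("visual" %in% modalities) || length(modalities) != 2L)
    stop("trial table must have a 'visual' and one secondary congruency column",
         call. = FALSE)
  secondary <- setdiff(modalities, "visual")
  out <- data.frame(participant = table$participant,
                    visual_congruency = table$visual,
                    secondary_modality = rep(secondary, length.out = nrow(table)),
                    secondary_congruency = table[[secondary]],
                    rt_ms = table$rt,
                    accuracy = table$accuracy,
                    censored = if ("censored" %in% names(table))
                      table$censored else FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
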