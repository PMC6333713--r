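#' Factorial design specification of the multimodal Simon experiments
#'
#' The emulated design crosses 3 visual positions x 3 secondary-modality
#' positions x 2 letters (18 trial types), each repeated `reps_per_block`
#' times in each of `n_blocks` blocks (shuffled within block), for
#' `n_participants` participants; with the defaults each participant
#' contributes 540 trials, 60 per congruency condition. The letter-response
#' mapping is counterbalanced across participants.
#'
#' @param secondary name of the second task-irrelevant modality,
#'   `"tactile"` or `"auditory"` (any string is accepted).
#' @param n_participants number of participants, default 30.
#' @param reps_per_block repetitions of each trial type per block, default 5.
#' @param n_blocks number of blocks, default 6.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(secondary = "tactile", n_participants = 30L,
                        reps_per_block = 5L, n_blocks = 6L) {
  stopifnot(nzchar(secondary), n_participants >= 1L,
            reps_per_block >= 1L, n_blocks >= 1L)
  structure(list(positions = c("left", "center", "right"),
                 letters = c("H", "S"), secondary = secondary,
                 n_participants = as.integer(n_participants),
                 reps_per_block = as.integer(reps_per_block),
                 n_blocks = as.integer(n_blocks)),
            class = "design_spec")
}

#' Congruency of a stimulus position relative to the correct response
#'
#' Same side as the correct response is congruent, the opposite side
#' incongruent, and the central position neutral.
#'
#' @param stimulus_position `"left"`, `"center"` or `"right"` (vectorised).
#' @param correct_response_side `"left"` or `"right"` (vectorised).
#' @return character vector of congruency labels.
#' @examples
#' congruency_of("left", "left")    # congruent
#' congruency_of("center", "right") # neutral
#' @export
congruency_of <- function(stimulus_position, correct_response_side) {
  stopifnot(all(stimulus_position %in% c("left", "center", "right")),
            all(correct_response_side %in% c("left", "right")))
  ifelse(stimulus_position == "center", "neutral",
         ifelse(stimulus_position == correct_response_side,
                "congruent", "incongruent"))
}

#' Build one participant's randomised trial list
#'
#' Expands the 18 trial types (visual position x secondary position x
#' letter) to `reps_per_block` repetitions per block, shuffles uniformly
#' within each block, and labels each trial with its per-modality
#' congruency given the participant's letter-response mapping.
#'
#' @param spec a [design_spec()].
#' @param participant participant id (1-based); participants with odd ids
#'   map H to the left response, even ids the reverse.
#' @return data.frame with one row per trial: `participant`, `block`,
#'   `letter`, `visual_position`, secondary position, `response_side`,
#'   `visual` and secondary congruency labels.
#' @export
build_design <- function(spec, participant = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  types <- expand.grid(visual_position = spec$positions,
                       secondary_position = spec$positions,
                       letter = spec$letters,
                       stringsAsFactors = FALSE)
  mapping <- if (participant %% 2L == 1L) c(H = "left", S = "right")
             else c(H = "right", S = "left")
  blocks <- lapply(seq_len(spec$n_blocks), function(b) {
    block <- types[rep(seq_len(nrow(types)), spec$reps_per_block), ,
                   drop = FALSE]
    block <- block[sample.int(nrow(block)), , drop = FALSE]
    block$block <- b
    block
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$participant <- participant
  out$response_side <- unname(mapping[out$letter])
  out$visual <- congruency_of(out$visual_position, out$response_side)
  out[[spec$secondary]] <- congruency_of(out$secondary_position,
                                         out$response_side)
  names(out)[names(out) == "secondary_position"] <-
    paste0(spec$secondary, "_position")
  out[, c("participant", "block", "letter", "visual_position",
          paste0(spec$secondary, "_position"), "response_side",
          "visual", spec$secondary)]
}

#' Generate a complete synthetic dataset
#'
#' Builds the randomised trial list of every participant with
#' [build_design()] and simulates each trial from the model: within a
#' participant, the trials of each congruency condition are simulated as a
#' batch and written back to their design positions. All participants share
#' one parameter set (the models are fitted to aggregated data); an optional
#' multiplicative jitter on the residual mean adds participant-level
#' variability for robustness experiments.
#'
#' @param params an [mdmc_params()]; its modalities must be `visual` and
#'   `spec$secondary`.
#' @param spec a [design_spec()].
#' @param variant `"MDMC"` or `"FN-MDMC"`.
#' @param seed integer root seed.
#' @param mu_r_jitter_sd SD of a lognormal multiplicative jitter applied to
#'   each participant's `mu_r`/`mu_rn` (0 = identical participants, the
#'   default).
#' @param time_cap censoring cap in ms.
#' @return trial table with columns `participant`, `visual`,
#'   `spec$secondary`, `rt`, `accuracy`, `censored`
#'   (`spec$n_participants * 540` rows under the default design).
#' @examples
#' \donttest{
#' p <- mdmc_preset("vt_mdmc")
#' d <- generate_dataset(p, design_spec(n_participants = 2), seed = 1)
#' nrow(d)  # 1080
#' }
#' @export
generate_dataset <- function(params, spec = design_spec(),
                             variant = variant_of(params), seed = 1L,
                             mu_r_jitter_sd = 0, time_cap = 5000) {
  stopifnot(is.mdmc_params(params), inherits(spec, "design_spec"))
  modalities <- c("visual", spec$secondary)
  if (!setequal(names(params$automatic), modalities))
    stop("parameter modalities (", paste(names(params$automatic), collapse = ", "),
         ") do not match the design (", paste(modalities, collapse = ", "), ")",
         call. = FALSE)
  out <- vector("list", spec$n_participants)
  for (pid in seq_len(spec$n_participants)) {
    set.seed(child_seed(seed, pid))
    design <- build_design(spec, pid)
    pp <- params
    if (mu_r_jitter_sd > 0) {
      f <- exp(rnorm(1, 0, mu_r_jitter_sd))
      pp$mu_r <- params$mu_r * f
      if (!is.null(pp$mu_rn)) pp$mu_rn <- params$mu_rn * f
    }
    design$rt <- NA_real_
    design$accuracy <- NA_integer_
    design$censored <- NA
    key <- paste(design$visual, design[[spec$secondary]], sep = ".")
    for (k in unique(key)) {
      rows <- which(key == k)
      labels <- c(design$visual[rows[1]], design[[spec$secondary]][rows[1]])
      names(labels) <- modalities
      cond <- structure(labels, class = "congruency_condition")
      sim <- simulate_trial(pp, cond, length(rows), variant,
                            participant = pid, time_cap = time_cap)
      design$rt[rows] <- sim$rt
      design$accuracy[rows] <- sim$accuracy
      design$censored[rows] <- sim$censored
    }
    out[[pid]] <- design[, c("participant", "visual", spec$secondary,
                             "rt", "accuracy", "censored")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
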