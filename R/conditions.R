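.congruency_levels <- c("congruent", "neutral", "incongruent")

#' Sign carried by a congruency label
#'
#' A congruent automatic pulse pushes toward the correct boundary (+1), an
#' incongruent pulse toward the error boundary (-1), and a neutral source
#' does not affect the decision process (0).
#'
#' @param label character vector of labels in
#'   `c("congruent", "neutral", "incongruent")`.
#' @return integer vector in `{+1, 0, -1}`.
#' @examples
#' condition_sign(c("congruent", "neutral", "incongruent"))
#' @export
condition_sign <- function(label) {
  bad <- setdiff(unique(label), .congruency_levels)
  if (length(bad))
    stop("unknown congruency label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(c(congruent = 1L, neutral = 0L, incongruent = -1L)[label])
}

#' Congruency condition: one label per task-irrelevant modality
#'
#' @param ... named congruency labels, e.g.
#'   `congruency_condition(visual = "congruent", tactile = "incongruent")`.
#' @return A named character vector of class `congruency_condition`.
#' @export
congruency_condition <- function(...) {
  labels <- c(...)
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be named by modality", call. = FALSE)
  condition_sign(labels)  # validates
  structure(labels, class = "congruency_condition")
}

# Short condition code, e.g. CVIT for congruent-visual incongruent-tactile.
condition_code <- function(condition) {
  paste0(toupper(substr(unname(condition), 1, 1)),
         toupper(substr(names(condition), 1, 1)), collapse = "")
}

#' All factorial congruency conditions for a set of modalities
#'
#' For two modalities this is the nine-cell design (3 x 3 labels); names are
#' condition codes such as `"CVIT"` (congruent visual, incongruent tactile).
#'
#' @param modalities character vector of modality names, e.g.
#'   `c("visual", "tactile")`.
#' @return Named list of [congruency_condition()] objects.
#' @examples
#' names(all_conditions(c("visual", "tactile")))
#' @export
all_conditions <- function(modalities) {
  grids <- rev(expand.grid(rev(setNames(
    rep(list(.congruency_levels), length(modalities)), modalities)),
    stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(grids)), function(i) {
    labels <- unlist(grids[i, , drop = FALSE])
    names(labels) <- modalities
    structure(labels, class = "congruency_condition")
  })
  names(out) <- vapply(out, condition_code, character(1))
  out
}

check_condition <- function(params, condition) {
  if (!setequal(names(condition), names(params$automatic)) ||
      length(condition) != length(params$automatic))
    stop("condition modalities (", paste(names(condition), collapse = ", "),
         ") do not match parameter modalities (",
         paste(names(params$automatic), collapse = ", "), ")", call. = FALSE)
  invisible(condition[names(params$automatic)])
}
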