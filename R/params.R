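#' Automatic-process specification
#'
#' Describes the expected time course of one modality's automatic activation:
#' a pulse shaped like a rescaled Gamma density with amplitude `amplitude`
#' (the peak activation, in accumulator units), scale `tau` (ms) and shape
#' `shape` (dimensionless, fixed at 2 in the standard model). The pulse rises
#' from zero, peaks at `(shape - 1) * tau` ms with value `amplitude`, and
#' decays back to zero.
#'
#' @param amplitude peak activation magnitude (|A| >= 0), accumulator units.
#' @param tau scale of the pulse in ms (> 0).
#' @param shape Gamma shape parameter (> 1); a structural constant, default 2.
#' @return An object of class `automatic_spec`.
#' @examples
#' automatic_spec(13.4, 39)
#' @export
automatic_spec <- function(amplitude, tau, shape = 2) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(tau), length(tau) == 1L,
            is.numeric(shape), length(shape) == 1L)
  if (amplitude < 0) stop("'amplitude' must be a magnitude >= 0", call. = FALSE)
  if (tau <= 0) stop("'tau' must be > 0", call. = FALSE)
  if (shape <= 1) stop("'shape' must be > 1", call. = FALSE)
  structure(list(amplitude = amplitude, tau = tau, shape = shape),
            class = "automatic_spec")
}

#' @export
print.automatic_spec <- function(x, ...) {
  cat(sprintf("automatic process: peak |A| = %g, tau = %g ms, shape a = %g (peak at %g ms)\n",
              x$amplitude, x$tau, x$shape, (x$shape - 1) * x$tau))
  invisible(x)
}

#' Full MDMC / FN-MDMC parameter set
#'
#' Bundles every quantity needed to simulate the model: the controlled drift
#' `mu_c`, the decision boundary `b` (absorption at +b for the correct and -b
#' for the incorrect response), the symmetric-Beta shape `alpha` of the
#' starting-point distribution on (-b, b), the residual-time mean `mu_r` and
#' SD `sigma_r` (ms), one [automatic_spec()] per task-irrelevant modality,
#' and the simulation constants `sigma` (diffusion constant of the
#' superimposed process) and `dt` (Euler step, ms). Supplying `mu_rn` (the
#' residual-time mean used when the visual modality is neutral) makes the set
#' an FN-MDMC parameter set.
#'
#' @param mu_c drift rate of the controlled process, activation units per ms.
#' @param boundary decision boundary b > 0, activation units.
#' @param start_shape Beta shape alpha > 0 of the starting-point distribution.
#' @param mu_r mean residual (non-decision) time, ms.
#' @param sigma_r SD of the residual time, ms (> 0).
#' @param automatic named list of [automatic_spec()] objects, one per
#'   task-irrelevant modality, in a fixed order (the modality named
#'   `"visual"` carries the faster-neutral residual rule in FN-MDMC).
#' @param mu_rn faster-neutral residual mean, ms; present if and only if the
#'   variant is FN-MDMC.
#' @param sigma diffusion constant of the superimposed process, default 4.
#' @param dt Euler time step in ms, default 1.
#' @return An object of class `mdmc_params` with a `variant` attribute of
#'   `"MDMC"` or `"FN-MDMC"`.
#' @examples
#' p <- mdmc_params(mu_c = 0.52, boundary = 54.6, start_shape = 3.1,
#'                  mu_r = 313, sigma_r = 33.4,
#'                  automatic = list(visual = automatic_spec(13.4, 39),
#'                                   tactile = automatic_spec(6.1, 28.5)))
#' p
#' @export
mdmc_params <- function(mu_c, boundary, start_shape, mu_r, sigma_r,
                        automatic, mu_rn = NULL, sigma = 4, dt = 1) {
  if (boundary <= 0) stop("'boundary' must be > 0", call. = FALSE)
  if (start_shape <= 0) stop("'start_shape' must be > 0", call. = FALSE)
  if (sigma_r <= 0) stop("'sigma_r' must be > 0", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)  # 0 = noiseless diagnostics
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (!is.list(automatic) || length(automatic) < 1L ||
      is.null(names(automatic)) || any(!nzchar(names(automatic))))
    stop("'automatic' must be a named list of automatic_spec objects",
         call. = FALSE)
  if (!all(vapply(automatic, inherits, logical(1), "automatic_spec")))
    stop("every element of 'automatic' must be an automatic_spec", call. = FALSE)
  if (!is.null(mu_rn)) {
    stopifnot(is.numeric(mu_rn), length(mu_rn) == 1L)
    if (!("visual" %in% names(automatic)))
      stop("FN-MDMC requires a modality named 'visual'", call. = FALSE)
  }
  structure(list(mu_c = mu_c, boundary = boundary, start_shape = start_shape,
                 mu_r = mu_r, sigma_r = sigma_r, mu_rn = mu_rn,
                 automatic = automatic, sigma = sigma, dt = dt),
            class = "mdmc_params",
            variant = if (is.null(mu_rn)) "MDMC" else "FN-MDMC")
}

#' @export
print.mdmc_params <- function(x, ...) {
  cat(sprintf("%s parameter set\n", attr(x, "variant")))
  cat(sprintf("  controlled drift mu_C = %g /ms, boundary b = %g, start shape alpha = %g\n",
              x$mu_c, x$boundary, x$start_shape))
  if (is.null(x$mu_rn))
    cat(sprintf("  residual time: mean %g ms, sd %g ms\n", x$mu_r, x$sigma_r))
  else
    cat(sprintf("  residual time: mean %g ms (%g ms visual-neutral), sd %g ms\n",
                x$mu_r, x$mu_rn, x$sigma_r))
  for (m in names(x$automatic)) {
    s <- x$automatic[[m]]
    cat(sprintf("  %s automatic pulse: |A| = %g, tau = %g ms, a = %g\n",
                m, s$amplitude, s$tau, s$shape))
  }
  cat(sprintf("  simulation: sigma = %g, dt = %g ms\n", x$sigma, x$dt))
  invisible(x)
}

#' @export
#' @rdname mdmc_params
#' @param x object to test.
is.mdmc_params <- function(x) inherits(x, "mdmc_params")

variant_of <- function(params) attr(params, "variant")

#' Published parameter sets for the visual-tactile and visual-auditory tasks
#'
#' Loads one of the four fitted parameter sets shipped with the package:
#' `"vt_mdmc"` and `"vt_fnmdmc"` (visual Simon task with task-irrelevant
#' tactile stimulation), `"va_mdmc"` and `"va_fnmdmc"` (task-irrelevant
#' auditory stimulation).
#'
#' @param name one of `"vt_mdmc"`, `"vt_fnmdmc"`, `"va_mdmc"`, `"va_fnmdmc"`.
#' @return An [mdmc_params()] object.
#' @examples
#' mdmc_preset("vt_mdmc")
#' @export
mdmc_preset <- function(name = c("vt_mdmc", "vt_fnmdmc", "va_mdmc", "va_fnmdmc")) {
  name <- match.arg(name)
  path <- system.file("extdata", "params", paste0(name, ".yaml"),
                      package = "mdmc", mustWork = TRUE)
  read_params(path)
}

#' Read or write a parameter set as structured text
#'
#' Parameter sets are serialised as YAML: scalar fields at the top level and
#' one nested block per modality under `automatic`.
#'
#' @param path file path.
#' @return `read_params()` returns an [mdmc_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("mu_c", "boundary", "start_shape", "mu_r", "sigma_r", "automatic")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("parameter file ", path, " is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  auto <- lapply(y$automatic, function(a)
    automatic_spec(a$amplitude, a$tau, if (is.null(a$shape)) 2 else a$shape))
  mdmc_params(mu_c = y$mu_c, boundary = y$boundary, start_shape = y$start_shape,
              mu_r = y$mu_r, sigma_r = y$sigma_r, mu_rn = y$mu_rn,
              automatic = auto,
              sigma = if (is.null(y$sigma)) 4 else y$sigma,
              dt = if (is.null(y$dt)) 1 else y$dt)
}

#' @rdname read_params
#' @param params an [mdmc_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(is.mdmc_params(params))
  y <- list(mu_c = params$mu_c, boundary = params$boundary,
            start_shape = params$start_shape, mu_r = params$mu_r,
            sigma_r = params$sigma_r,
            automatic = lapply(params$automatic, function(s)
              list(amplitude = s$amplitude, tau = s$tau, shape = s$shape)),
            sigma = params$sigma, dt = params$dt)
  if (!is.null(params$mu_rn)) y$mu_rn <- params$mu_rn
  yaml::write_yaml(y, path)
  invisible(path)
}
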