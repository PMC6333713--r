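.reserved_cols <- c("participant", "rt", "accuracy", "censored",
                    "decision_time")

detect_modalities <- function(data) {
  m <- setdiff(names(data), .reserved_cols)
  if (length(m) < 1L)
    stop("no congruency columns found in the data", call. = FALSE)
  # keep 'visual' first: it carries the FN-MDMC residual rule
  if ("visual" %in% m) m <- c("visual", setdiff(m, "visual"))
  m
}

free_parameter_names <- function(modalities, variant) {
  c("mu_r", "sigma_r", "start_shape", "boundary", "mu_c",
    as.vector(rbind(paste0("amplitude_", modalities),
                    paste0("tau_", modalities))),
    if (variant == "FN-MDMC") "mu_rn")
}

#' Default multi-start sampling ranges for the free parameters
#'
#' Uniform sampling ranges bracketing the published fits: mu_r and mu_rn in
#' (200, 450) ms, sigma_r in (10, 80) ms, alpha in (1, 6), b in (30, 100),
#' mu_c in (0.2, 1.2) per ms, pulse amplitudes in (1, 40) and scales tau in
#' (10, 120) ms.
#'
#' @param modalities modality names.
#' @param variant `"MDMC"` or `"FN-MDMC"`.
#' @return named list of `c(lo, hi)` ranges, one per free parameter.
#' @export
default_start_ranges <- function(modalities, variant = "MDMC") {
  base <- list(mu_r = c(200, 450), sigma_r = c(10, 80),
               start_shape = c(1, 6), boundary = c(30, 100),
               mu_c = c(0.2, 1.2))
  for (m in modalities) {
    base[[paste0("amplitude_", m)]] <- c(1, 40)
    base[[paste0("tau_", m)]] <- c(10, 120)
  }
  if (variant == "FN-MDMC") base$mu_rn <- c(200, 450)
  base
}

# Hard validity box; the objective returns a large penalty outside it.
hard_box <- function(modalities, variant) {
  box <- list(mu_r = c(50, 1000), sigma_r = c(1, 200),
              start_shape = c(0.1, 20), boundary = c(5, 200),
              mu_c = c(0.01, 3))
  for (m in modalities) {
    box[[paste0("amplitude_", m)]] <- c(0, 80)
    box[[paste0("tau_", m)]] <- c(2, 300)
  }
  if (variant == "FN-MDMC") box$mu_rn <- c(50, 1000)
  box
}

theta_to_params <- function(theta, modalities, variant, sigma = 4, dt = 1) {
  auto <- setNames(lapply(modalities, function(m)
    automatic_spec(theta[[paste0("amplitude_", m)]],
                   theta[[paste0("tau_", m)]])), modalities)
  mdmc_params(mu_c = theta[["mu_c"]], boundary = theta[["boundary"]],
              start_shape = theta[["start_shape"]], mu_r = theta[["mu_r"]],
              sigma_r = theta[["sigma_r"]],
              mu_rn = if (variant == "FN-MDMC") theta[["mu_rn"]] else NULL,
              automatic = auto, sigma = sigma, dt = dt)
}

params_to_theta <- function(params) {
  variant <- variant_of(params)
  modalities <- names(params$automatic)
  theta <- c(mu_r = params$mu_r, sigma_r = params$sigma_r,
             start_shape = params$start_shape, boundary = params$boundary,
             mu_c = params$mu_c)
  for (m in modalities) {
    theta[[paste0("amplitude_", m)]] <- params$automatic[[m]]$amplitude
    theta[[paste0("tau_", m)]] <- params$automatic[[m]]$tau
  }
  if (variant == "FN-MDMC") theta[["mu_rn"]] <- params$mu_rn
  theta[free_parameter_names(modalities, variant)]
}

#' Fit MDMC or FN-MDMC to trial-level conflict-task data
#'
#' Estimates the model parameters by minimising the [g_squared()]
#' discrepancy between the observed ten-slot proportion vectors of every
#' congruency condition (five CDF quantile bins of correct responses, five
#' CAF error bins; see [observed_proportions()]) and Monte-Carlo predictions
#' simulated at candidate parameters. The objective is minimised with a
#' multi-start Nelder-Mead simplex; common random numbers (one simulation
#' seed fixed for the whole fit, with a deterministic sub-stream per
#' condition) make the stochastic objective deterministic for the optimiser.
#'
#' Free parameters are `mu_r`, `sigma_r`, `start_shape` (alpha), `boundary`
#' (b), `mu_c`, and an amplitude/scale pair per task-irrelevant modality
#' (9 parameters for two modalities); FN-MDMC adds the faster-neutral
#' residual mean `mu_rn` (10 parameters).
#'
#' @param data trial table: columns `participant`, one congruency-label
#'   column per modality (`visual` plus one other), `rt` (ms), `accuracy`
#'   (0/1), optionally `censored`. Trials are pooled over participants and
#'   filtered to `filter[1]`-`filter[2]` ms before fitting.
#' @param variant `"MDMC"` or `"FN-MDMC"`.
#' @param n_starts number of Nelder-Mead starts (initial vectors drawn
#'   uniformly from `start_ranges`).
#' @param n_sim simulated trials per condition per objective evaluation.
#' @param seed integer seed controlling both the start draws and the common
#'   random numbers of the objective.
#' @param maxit maximum Nelder-Mead iterations per start (screening stage).
#' @param polish_maxit Nelder-Mead iteration budget per polishing round;
#'   0 disables polishing.
#' @param polish_top number of leading starts that receive polishing.
#' @param polish_rounds restarted simplex rounds per polished start; each
#'   round rebuilds the initial simplex at a progressively tighter scale,
#'   the standard remedy for collapsed simplexes in many dimensions.
#' @param screen_n_sim optional reduced simulation size for the screening
#'   and polishing stages; the winning start is then refined and its final
#'   G-squared evaluated at the full `n_sim` (multi-fidelity schedule). The
#'   `starts` trace reports screening-fidelity values; `g2` is always at
#'   `n_sim`.
#' @param screen_fixed optional named numeric vector of free parameters held
#'   at the given values during the screening stages and released for the
#'   final full-fidelity rounds (staged fitting). Holding `start_shape` at
#'   its mid-range value stabilises the early descent, which otherwise
#'   tends to collapse the starting-point shape toward wide starts to
#'   absorb early misfit. `boundary` and `mu_c` cannot be held.
#' @param start_ranges named list of `c(lo, hi)` sampling ranges; defaults
#'   to [default_start_ranges()].
#' @param start optional list/vector of explicit initial parameter vectors
#'   (named as in [default_start_ranges()]); overrides random starts.
#' @param bic_n `"data"` (total trials entering the fit, the default) or
#'   `"table1"` (fixed 270 = participants x conditions) as the sample size
#'   in the BIC penalty; or a number.
#' @param filter RT analysis window in ms, default `c(150, 1200)`.
#' @param sigma,dt simulation constants of the superimposed process.
#' @param time_cap censoring cap for simulated decision times, ms.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param verbose print per-start progress.
#' @return An object of class `mdmc_fit`; see [coef.mdmc_fit()],
#'   [predict.mdmc_fit()], [simulate.mdmc_fit()], [plot.mdmc_fit()].
#' @examples
#' \donttest{
#' p <- mdmc_preset("vt_mdmc")
#' dat <- simulate_experiment(p, all_conditions(c("visual", "tactile")),
#'                            n_per_condition = 500, seed = 42)
#' fit <- mdmc(dat, variant = "MDMC", n_starts = 2, n_sim = 2000,
#'             maxit = 60, seed = 1)
#' coef(fit)
#' }
#' @export
mdmc <- function(data, variant = c("MDMC", "FN-MDMC"), n_starts = 10L,
                 n_sim = 50000L, seed = 1L, maxit = 300L,
                 start_ranges = NULL, start = NULL,
                 polish_maxit = 2L * maxit, polish_top = 2L,
                 polish_rounds = 3L, screen_n_sim = NULL,
                 screen_fixed = NULL,
                 bic_n = c("data", "table1"), filter = c(150, 1200),
                 sigma = 4, dt = 1, time_cap = 5000, reltol = 1e-6,
                 verbose = FALSE) {
  cl <- match.call()
  variant <- match.arg(variant)
  modalities <- detect_modalities(data)
  conditions <- all_conditions(modalities)
  flt <- filter_rts(data, filter[1], filter[2])
  data <- flt$table

  key <- do.call(paste0, c(lapply(seq_along(modalities), function(i)
    paste0(toupper(substr(data[[modalities[i]]], 1, 1)),
           toupper(substr(modalities[i], 1, 1)))), list()))
  missing_cells <- setdiff(names(conditions), unique(key))
  if (length(missing_cells))
    stop("data do not cover condition(s): ",
         paste(missing_cells, collapse = ", "), call. = FALSE)

  observed <- lapply(names(conditions), function(cc)
    observed_proportions(data[key == cc, , drop = FALSE], label = cc))
  names(observed) <- names(conditions)
  n_c <- vapply(observed, `[[`, numeric(1), "n")
  p_obs <- lapply(observed, `[[`, "proportions")

  par_names <- free_parameter_names(modalities, variant)
  box <- hard_box(modalities, variant)
  if (is.null(start_ranges))
    start_ranges <- default_start_ranges(modalities, variant)
  if (!setequal(names(start_ranges), par_names))
    stop("'start_ranges' must name exactly: ",
         paste(par_names, collapse = ", "), call. = FALSE)

  sim_seed <- child_seed(seed, 999983L)
  lo <- vapply(box[par_names], `[`, numeric(1), 1)
  hi <- vapply(box[par_names], `[`, numeric(1), 2)

  # The simplex works in a transformed space: positive scale parameters on
  # the log scale, and (boundary, mu_c) rotated to (log(b/mu_c), log(b*mu_c))
  # — mean decision time and accuracy axes — which straightens the strong
  # b/mu_c trade-off valley of the raw parameterisation.
  i_b <- match("boundary", par_names); i_mu <- match("mu_c", par_names)
  i_log <- which(par_names %in% c("sigma_r", "start_shape",
                                  paste0("tau_", modalities)))
  to_phi <- function(theta) {
    phi <- theta
    phi[i_log] <- log(theta[i_log])
    phi[i_b] <- log(theta[i_b] / theta[i_mu])
    phi[i_mu] <- log(theta[i_b] * theta[i_mu])
    phi
  }
  to_theta <- function(phi) {
    theta <- phi
    theta[i_log] <- exp(phi[i_log])
    theta[i_b] <- sqrt(exp(phi[i_b]) * exp(phi[i_mu]))
    theta[i_mu] <- sqrt(exp(phi[i_mu]) / exp(phi[i_b]))
    theta
  }
  # Unit parscale in the transformed space: the simplex adapts its own shape
  # quickly, and uniform initial steps (0.1 in log units) explore the valley
  # far better than per-coordinate "natural" scales, which throttle the log
  # coordinates. A separate scale is used only to normalise the finalist
  # diversity distance.
  phi_scale <- rep(1, length(par_names))
  dist_scale <- ifelse(par_names %in% c("mu_r", "mu_rn"), 25,
                       ifelse(par_names %in% paste0("amplitude_", modalities),
                              3, 0.35))

  objective <- function(phi, ns) {
    theta <- to_theta(phi)
    names(theta) <- par_names
    if (any(theta < lo | theta > hi)) {
      dist <- sum(pmax(lo - theta, 0) / (hi - lo)) +
        sum(pmax(theta - hi, 0) / (hi - lo))
      return(1e10 * (1 + dist))
    }
    params <- theta_to_params(as.list(theta), modalities, variant, sigma, dt)
    p_pred <- vector("list", length(conditions))
    for (j in seq_along(conditions)) {
      set.seed(child_seed(sim_seed, j))
      p_pred[[j]] <- predicted_proportions(
        params, conditions[[j]], observed[[j]]$edges, variant,
        n_sim = ns, time_cap = time_cap)$proportions
    }
    g_squared(p_obs, p_pred, n_c)
  }

  if (is.null(start)) {
    set.seed(child_seed(seed, 424243L))
    starts <- lapply(seq_len(n_starts), function(i)
      vapply(start_ranges[par_names], function(r)
        runif(1, r[1], r[2]), numeric(1)))
  } else {
    if (!is.list(start)) start <- list(start)
    starts <- lapply(start, function(s) {
      s <- unlist(s)[par_names]
      if (anyNA(s)) stop("explicit 'start' is missing parameter(s)",
                         call. = FALSE)
      s
    })
    n_starts <- length(starts)
  }

  ns_screen <- if (is.null(screen_n_sim)) n_sim else screen_n_sim
  shrink <- c(1, 0.4, 0.15, 0.08)

  # Optionally hold selected free parameters at fixed values through the
  # screening stages (released for the final full-fidelity rounds). Holding
  # the starting-point shape fixed, in particular, prevents the early
  # descent from collapsing alpha toward wide starting points — a
  # mismatch-absorbing degeneracy that otherwise locks the simplex into a
  # high-gain local basin before the better-identified parameters settle.
  fix_idx <- integer(0); fix_phi <- numeric(0)
  if (!is.null(screen_fixed)) {
    if (any(names(screen_fixed) %in% c("boundary", "mu_c")))
      stop("'screen_fixed' cannot hold 'boundary' or 'mu_c' ",
           "(they share transformed coordinates)", call. = FALSE)
    fix_idx <- match(names(screen_fixed), par_names)
    if (anyNA(fix_idx))
      stop("'screen_fixed' names unknown parameter(s)", call. = FALSE)
    fix_phi <- ifelse(fix_idx %in% i_log, log(unname(screen_fixed)),
                      unname(screen_fixed))
  }
  embed_phi <- function(phi_sub) {
    if (!length(fix_idx)) return(phi_sub)
    phi <- numeric(length(par_names))
    phi[fix_idx] <- fix_phi
    phi[-fix_idx] <- phi_sub
    phi
  }
  strip_phi <- function(phi) if (length(fix_idx)) phi[-fix_idx] else phi
  objective_screen <- function(phi_sub, ns) objective(embed_phi(phi_sub), ns)
  scale_screen <- strip_phi(phi_scale)
  dist_screen <- strip_phi(dist_scale)

  # stage 1: screen every start at the (possibly reduced) screening fidelity
  trace <- data.frame(start = seq_len(n_starts), g2_initial = NA_real_,
                      g2_final = NA_real_, convergence = NA_integer_)
  stage1 <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    phi0 <- strip_phi(to_phi(starts[[i]]))
    g2_init <- objective_screen(phi0, ns_screen)
    opt <- optim(phi0, objective_screen, ns = ns_screen,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol,
                                parscale = scale_screen))
    trace$g2_initial[i] <- g2_init
    trace$g2_final[i] <- opt$value
    trace$convergence[i] <- opt$convergence
    stage1[[i]] <- opt
    if (verbose)
      message(sprintf("start %d/%d: G2 %.2f -> %.2f", i, n_starts,
                      g2_init, opt$value))
  }
  ok <- vapply(stage1, function(o) is.finite(o$value) && o$value < 1e10,
               logical(1))
  if (!any(ok))
    stop("all starts failed (hit the parameter box); optimizer trace:\n",
         paste(utils::capture.output(print(trace)), collapse = "\n"),
         call. = FALSE)

  # Finalist selection: the best start by value plus, for each further slot,
  # the admissible start (value within 5x of the best) farthest from the
  # finalists already chosen in the transformed parameter space. Different
  # starts descend into different local basins of the piecewise-constant
  # surface, and screening value alone is a poor predictor of basin quality,
  # so diversity beats a pure value ranking.
  pick_finalists <- function(k) {
    vals <- vapply(stage1, function(o) o$value, numeric(1))
    vals[!ok] <- Inf
    chosen <- which.min(vals)
    admissible <- setdiff(which(ok & vals <= 5 * vals[chosen]), chosen)
    while (length(chosen) < k && length(admissible)) {
      dist <- vapply(admissible, function(i)
        min(vapply(chosen, function(j)
          sum(((stage1[[i]]$par - stage1[[j]]$par) / dist_screen)^2),
          numeric(1))), numeric(1))
      nxt <- admissible[which.max(dist)]
      chosen <- c(chosen, nxt)
      admissible <- setdiff(admissible, nxt)
    }
    chosen
  }

  # stage 2: restarted simplex polish of the finalists, with a fresh,
  # progressively tighter initial simplex (escapes collapsed simplexes)
  leaders <- pick_finalists(min(polish_top, sum(ok)))
  if (polish_maxit > 0L) {
    for (i in leaders) {
      opt <- stage1[[i]]
      for (round in seq_len(polish_rounds)) {
        sc <- shrink[min(round, length(shrink))]
        nxt <- optim(opt$par, objective_screen, ns = ns_screen,
                     method = "Nelder-Mead",
                     control = list(maxit = polish_maxit, reltol = reltol,
                                    parscale = scale_screen * sc))
        improved <- nxt$value < opt$value * (1 - 1e-3)
        if (nxt$value <= opt$value) opt <- nxt
        if (verbose)
          message(sprintf("polish start %d round %d: G2 -> %.2f",
                          i, round, opt$value))
        if (!improved) break
      }
      stage1[[i]] <- opt
      trace$g2_final[i] <- opt$value
    }
  }
  # stage 3: full-fidelity restart rounds over ALL free parameters (any
  # screen_fixed parameters are released here). When a reduced screening
  # fidelity was used, the leaders are re-optimised on the full-n_sim
  # surface, whose finer Monte-Carlo granularity un-sticks simplexes frozen
  # on the coarse surface. A leader whose round stops improving is
  # abandoned early.
  if (ns_screen != n_sim || length(fix_idx)) {
    # round plan: with staged (screen_fixed) fitting the released parameters
    # first settle on the cheap screening surface, then everything is
    # refined on the full-n_sim surface
    if (length(fix_idx)) {
      plan_ns <- c(ns_screen, ns_screen, n_sim, n_sim, n_sim)
      plan_sc <- c(0.4, 0.15, 0.4, 0.15, 0.08)
      keep <- plan_ns == n_sim | ns_screen != n_sim
      plan_ns <- plan_ns[keep]; plan_sc <- plan_sc[keep]
    } else {
      plan_ns <- rep(n_sim, 3L)
      plan_sc <- c(1, 0.4, 0.15)
    }
    best <- NULL
    for (i in leaders) {
      cur <- list(par = embed_phi(stage1[[i]]$par), value = NA_real_)
      cur_ns <- NA_integer_
      seg_round <- 0L
      for (k in seq_along(plan_ns)) {
        if (!identical(cur_ns, plan_ns[k])) {
          cur$value <- objective(cur$par, plan_ns[k])
          cur_ns <- plan_ns[k]
          seg_round <- 0L
        }
        if (polish_maxit <= 0L) next
        seg_round <- seg_round + 1L
        maxit_k <- if (plan_ns[k] == n_sim) min(polish_maxit, 300L)
                   else polish_maxit
        nxt <- optim(cur$par, objective, ns = plan_ns[k],
                     method = "Nelder-Mead",
                     control = list(maxit = maxit_k, reltol = reltol,
                                    parscale = phi_scale * plan_sc[k]))
        improved <- nxt$value < cur$value * (1 - 3e-3)
        if (nxt$value <= cur$value) cur <- nxt
        if (verbose)
          message(sprintf("release/full start %d round %d (n_sim %d): G2 -> %.2f",
                          i, k, plan_ns[k], cur$value))
        if (!improved && plan_ns[k] == n_sim && seg_round >= 2L) break
      }
      if (!identical(cur_ns, n_sim))
        cur$value <- objective(cur$par, n_sim)
      if (is.null(best) || cur$value < best$value) best <- cur
    }
  } else {
    best <- stage1[[which.min(vapply(stage1, `[[`, numeric(1), "value"))]]
  }

  theta <- setNames(to_theta(best$par), par_names)
  n_total <- if (is.numeric(bic_n)) bic_n
  else if (match.arg(bic_n) == "table1") 270
  else sum(n_c)
  n_free <- length(par_names)
  structure(list(
    call = cl, variant = variant, modalities = modalities,
    coefficients = theta,
    params = theta_to_params(as.list(theta), modalities, variant, sigma, dt),
    g2 = best$value, bic = bic(best$value, n_free, n_total),
    n_free = n_free, n_total = n_total, n_c = n_c,
    observed = observed, conditions = conditions,
    starts = trace, seed = seed, sim_seed = sim_seed, n_sim = n_sim,
    filter = filter, excluded_fraction = flt$excluded_fraction,
    time_cap = time_cap), class = "mdmc_fit")
}
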