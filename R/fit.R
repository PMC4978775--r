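# Two-stage ensemble estimation: particle-swarm global search on the hybrid
# objective (log10 parameter space, very wide bounds), then bounded
# Levenberg-Marquardt least-squares refinement of each swarm result on the
# quantitative objective.  Each global set is refined twice (the second run
# starts from a jittered copy), and both refinements are kept, so a campaign
# of G global runs yields 2G ensemble members.

#' Fitting campaign configuration
#'
#' @param bounds_low,bounds_high Rate bounds (linear scale; defaults 1e-20
#'   and 1e10, the published search box; search is in log10 space).
#' @param n_particles Swarm size (default 31).
#' @param stall_iterations PSO stall termination (default 50).
#' @param max_iterations PSO iteration cap (default 400).
#' @param n_global_sets Number of independent PSO runs (the published
#'   campaign used 1000; the package default is a desk-scale 4).
#' @param refinements_per_set Refinement runs per global set (default 2; the
#'   second starts from a +/- jittered copy).
#' @param jitter Refinement start jitter, dex (default 0.05).
#' @param diff_eps Exclusion floor for the hybrid objective's
#'   difference-term weight during the global search (default 0.05, the
#'   blot noise scale: curve-order information below the noise floor is
#'   not measurable, and its \eqn{1/\Delta C} weights would otherwise
#'   dominate the objective with noise).
#' @param free Names of parameters to fit (default all 38).
#' @param template Parameter set supplying frozen values (default published
#'   medians).
#' @param seed Campaign base seed.
#' @return List of class \code{"fit_config"}.
#' @export
fit_config <- function(bounds_low = 1e-20, bounds_high = 1e10,
                       n_particles = 31, stall_iterations = 50,
                       max_iterations = 400, n_global_sets = 4,
                       refinements_per_set = 2, jitter = 0.05,
                       diff_eps = 0.05, free = param_names(),
                       template = median_params(), seed = 1) {
  stopifnot(bounds_low < bounds_high, n_particles >= 2,
            all(free %in% param_names()))
  structure(list(bounds_low = bounds_low, bounds_high = bounds_high,
                 n_particles = n_particles,
                 stall_iterations = stall_iterations,
                 max_iterations = max_iterations,
                 n_global_sets = n_global_sets,
                 refinements_per_set = refinements_per_set, jitter = jitter,
                 diff_eps = diff_eps, free = free,
                 template = rate_params(template), seed = seed),
            class = "fit_config")
}

#' Bounded least-squares refinement of a parameter set
#'
#' Levenberg-Marquardt minimization (\code{minpack.lm::nls.lm}) of the
#' per-point weighted residual vector of the quantitative WSSR, with box
#' bounds in log10 space.  Never returns a point worse than the start: if
#' the optimizer fails to improve, the start is returned unchanged.
#'
#' @param start_log10 Starting point, log10 of the free parameters.
#' @param residual_fn \code{function(x) -> residual vector} (see
#'   \code{make_residual_fn}).
#' @param lower,upper Bounds in log10 space.
#' @param maxiter Iteration cap (default 100).
#' @return List: \code{par} (log10), \code{wssr} (sum of squared
#'   residuals), \code{improved}.
#' @export
local_refine <- function(start_log10, residual_fn, lower, upper,
                         maxiter = 100) {
  r0 <- residual_fn(start_log10)
  w0 <- sum(r0^2)
  if (!all(is.finite(r0)))
    return(list(par = start_log10, wssr = w0, improved = FALSE))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start_log10, fn = residual_fn,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(par = start_log10, wssr = w0,
                                improved = FALSE))
  w1 <- sum(residual_fn(fit$par)^2)
  if (is.finite(w1) && w1 <= w0)
    list(par = pmin(pmax(fit$par, lower), upper), wssr = w1,
         improved = w1 < w0)
  else list(par = start_log10, wssr = w0, improved = FALSE)
}

#' Two-stage ensemble fit
#'
#' Stage 1 runs \code{n_global_sets} independent PSO searches (31 particles,
#' 50-iteration stall) on the hybrid WSSR in log10 space.  Stage 2 refines
#' each swarm result \code{refinements_per_set} times on the quantitative
#' WSSR; every refinement is kept as an ensemble member.
#'
#' @param datasets Named list of training \code{lck_dataset}s with attached
#'   conditions.
#' @param config \code{\link{fit_config}}.
#' @param progress Print per-run progress (default FALSE).
#' @return List of class \code{"lck_ensemble"}: \code{params} (members x 38
#'   matrix, linear scale), \code{wssr_hybr}, \code{wssr_quant},
#'   \code{provenance} (data.frame: global run, refinement id, seed),
#'   \code{free}, \code{config}.
#' @export
fit_lck <- function(datasets, config = fit_config(), progress = FALSE) {
  free <- config$free
  lower <- rep(log10(config$bounds_low), length(free))
  upper <- rep(log10(config$bounds_high), length(free))
  obj_h <- make_objective(datasets, "hybrid", config$template, free,
                          diff_eps = config$diff_eps)
  res_q <- make_residual_fn(datasets, config$template, free)
  members <- list()
  for (g in seq_len(config$n_global_sets)) {
    seed_g <- config$seed + 1000L * (g - 1L)
    swarm <- pso_minimize(obj_h, lower, upper,
                          n_particles = config$n_particles,
                          stall_iterations = config$stall_iterations,
                          max_iterations = config$max_iterations,
                          seed = seed_g)
    if (progress)
      message(sprintf("global run %d/%d: hybrid WSSR %.4g (%d iterations)",
                      g, config$n_global_sets, swarm$value,
                      swarm$iterations))
    set.seed(seed_g + 500L)
    for (r in seq_len(config$refinements_per_set)) {
      start <- swarm$par
      if (r > 1)
        start <- pmin(pmax(start + stats::runif(length(start),
                                                -config$jitter,
                                                config$jitter),
                           lower), upper)
      ref <- local_refine(start, res_q, lower, upper)
      members[[length(members) + 1L]] <- list(
        par = ref$par, wssr_quant = ref$wssr,
        wssr_hybr_start = swarm$value, g = g, r = r, seed = seed_g)
    }
  }
  par_mat <- do.call(rbind, lapply(members, function(m)
    unclass(params_from_log10(m$par, config$template, free))))
  colnames(par_mat) <- param_names()
  hybr <- vapply(members, function(m) obj_h(m$par), numeric(1))
  structure(list(
    params = par_mat,
    wssr_quant = vapply(members, `[[`, numeric(1), "wssr_quant"),
    wssr_hybr = hybr,
    provenance = data.frame(
      global_run = vapply(members, `[[`, numeric(1), "g"),
      refinement = vapply(members, `[[`, numeric(1), "r"),
      seed = vapply(members, `[[`, numeric(1), "seed")),
    free = free, config = config),
    class = "lck_ensemble")
}

#' @export
print.lck_ensemble <- function(x, ...) {
  cat("LCK fit ensemble:", nrow(x$params), "parameter sets,",
      length(x$free), "free parameters\n")
  cat("  quantitative WSSR range:",
      sprintf("%.4g .. %.4g", min(x$wssr_quant), max(x$wssr_quant)), "\n")
  invisible(x)
}

#' Read / write fit ensembles as JSON
#'
#' @param ensemble \code{lck_ensemble}.
#' @param path File path.
#' @export
write_ensemble <- function(ensemble, path) {
  sets <- lapply(seq_len(nrow(ensemble$params)), function(i) {
    list(params = as.list(ensemble$params[i, ]),
         wssr_quant = ensemble$wssr_quant[i],
         wssr_hybr = ensemble$wssr_hybr[i],
         global_run = ensemble$provenance$global_run[i],
         refinement = ensemble$provenance$refinement[i],
         seed = ensemble$provenance$seed[i])
  })
  jsonlite::write_json(sets, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  sets <- jsonlite::read_json(path)
  par_mat <- do.call(rbind, lapply(sets, function(s)
    unlist(s$params)[param_names()]))
  colnames(par_mat) <- param_names()
  structure(list(
    params = par_mat,
    wssr_quant = vapply(sets, function(s) s$wssr_quant, numeric(1)),
    wssr_hybr = vapply(sets, function(s) s$wssr_hybr, numeric(1)),
    provenance = data.frame(
      global_run = vapply(sets, function(s) s$global_run, numeric(1)),
      refinement = vapply(sets, function(s) s$refinement, numeric(1)),
      seed = vapply(sets, function(s) s$seed, numeric(1))),
    free = param_names(), config = NULL),
    class = "lck_ensemble")
}
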