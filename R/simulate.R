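# Forward simulation of the membrane-reconstitution experiments: LCK (and
# optionally CSK, and optionally catalytically dead LCK) at fixed surface
# densities on a supported bilayer, all LCK starting unphosphorylated apart
# from an optional residual phospho-Y505 fraction.

#' Define an experimental condition
#'
#' @param lck_density Active LCK surface density, molecules/um^2.
#' @param csk_density CSK surface density, molecules/um^2.
#' @param dead_lck_density Catalytically dead LCK density, molecules/um^2.
#' @param initial_p505_fraction Fraction of each LCK pool starting as
#'   U394P505 (residual phospho-Y505 after the pre-experiment
#'   dephosphorylation; measured at ~1.5%, observed up to ~20%). Default 0.
#' @param duration Simulated time, seconds (default 5400 s = 90 min).
#' @param label Condition label.
#' @return List of class \code{"lck_condition"}.
#' @export
condition <- function(lck_density, csk_density = 0, dead_lck_density = 0,
                      initial_p505_fraction = 0, duration = 5400,
                      label = NULL) {
  stopifnot(lck_density >= 0, csk_density >= 0, dead_lck_density >= 0,
            initial_p505_fraction >= 0, initial_p505_fraction <= 1,
            duration > 0)
  if (is.null(label))
    label <- sprintf("lck%g_csk%g_dead%g", lck_density, csk_density,
                     dead_lck_density)
  structure(list(lck_density = lck_density, csk_density = csk_density,
                 dead_lck_density = dead_lck_density,
                 initial_p505_fraction = initial_p505_fraction,
                 duration = duration, label = label),
            class = "lck_condition")
}

#' The five experimental conditions
#'
#' Four training conditions (high/low LCK with and without CSK) and the
#' validation condition in which half of a high-LCK pool is catalytically
#' dead.
#'
#' @param initial_p505_fraction Passed to every condition (default 0).
#' @return Named list of \code{lck_condition} objects: \code{high_lck}
#'   (500 LCK/um^2), \code{high_lck_csk} (500 + 500 CSK), \code{low_lck}
#'   (50), \code{low_lck_csk} (50 + 500 CSK), \code{validation} (250 active
#'   + 250 dead, no CSK).
#' @export
lck_conditions <- function(initial_p505_fraction = 0) {
  f <- initial_p505_fraction
  list(
    high_lck     = condition(500, 0,   0, f, label = "high_lck"),
    high_lck_csk = condition(500, 500, 0, f, label = "high_lck_csk"),
    low_lck      = condition(50,  0,   0, f, label = "low_lck"),
    low_lck_csk  = condition(50,  500, 0, f, label = "low_lck_csk"),
    validation   = condition(250, 0, 250, f, label = "validation")
  )
}

# Network matching a condition: the dead-LCK variant is only built when dead
# molecules are present; CSK rules are omitted when no CSK is present (the
# inactive-LCK validation variant declares CSK without rules).
network_for_condition <- function(cond) {
  if (cond$dead_lck_density > 0)
    lck_network(include_dead = TRUE, dead_policy = "binder",
                csk = if (cond$csk_density > 0) "full" else "species_only")
  else
    lck_network(csk = "full")
}

# Default output grid: dense log-spaced early points (the Y394 burst is over
# within ~15 s) plus an even late grid up to `duration` seconds.
default_times <- function(duration = 5400) {
  sort(unique(c(0, 10^seq(log10(0.1), log10(duration), length.out = 100),
                seq(0, duration, length.out = 25), duration)))
}

initial_state <- function(network, cond) {
  y0 <- stats::setNames(numeric(nrow(network$species)), network$species$id)
  f <- cond$initial_p505_fraction
  y0["L_UU"] <- (1 - f) * cond$lck_density
  if (f > 0) y0["L_UP"] <- f * cond$lck_density
  if (cond$dead_lck_density > 0) {
    y0["Ld_UU"] <- (1 - f) * cond$dead_lck_density
    if (f > 0) y0["Ld_UP"] <- f * cond$dead_lck_density
  }
  if (cond$csk_density > 0) {
    if (!"CSK" %in% names(y0))
      stop("condition has CSK but the network excludes it")
    y0["CSK"] <- cond$csk_density
  }
  y0
}

#' Simulate a condition
#'
#' Integrates the mass-action ODE system with a stiff solver
#' (\code{deSolve::lsoda}; the fitted rates span >15 orders of magnitude).
#' Initial state: all LCK free and unphosphorylated (minus the optional
#' initial phospho-Y505 fraction, assigned to free U394P505), all CSK free,
#' no dimers.
#'
#' @param params \code{lck_params} vector.
#' @param cond \code{lck_condition}.
#' @param network Optional pre-built \code{lck_network}; defaults to the
#'   network implied by the condition.
#' @param times Output times in seconds (default: dense log-spaced early
#'   grid up to \code{cond$duration}).
#' @param rtol,atol Integrator tolerances.
#' @param compiled Use the compiled right-hand side (default); set
#'   \code{FALSE} for the pure-R evaluator from \code{\link{build_rhs}}.
#' @param check_conservation Verify total LCK/CSK drift \eqn{\le} 1e-6
#'   relative (default TRUE).
#' @return List of class \code{"lck_traj"}: \code{times} (s),
#'   \code{densities} (time x species matrix, molecules/um^2),
#'   \code{condition}, \code{network}.
#' @export
#' @examples
#' tr <- simulate_lck(median_params(), lck_conditions()$high_lck)
#' fraction_pp(tr, 5400)
simulate_lck <- function(params, cond, network = NULL, times = NULL,
                         rtol = 1e-8, atol = 1e-12, compiled = TRUE,
                         check_conservation = TRUE) {
  params <- rate_params(params)
  if (is.null(network)) network <- network_for_condition(cond)
  if (is.null(times)) times <- default_times(cond$duration)
  times <- sort(unique(c(0, times)))
  y0 <- initial_state(network, cond)
  out <- if (compiled) {
    deSolve::lsoda(y0, times, func = "lck_derivs",
                   parms = encode_network(network, params),
                   dllname = "lckautoreg", initfunc = "lck_initmod",
                   rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    rhs <- build_rhs(network, params)
    deSolve::lsoda(y0, times, function(t, y, p) list(rhs(t, y)), parms = NULL,
                   rtol = rtol, atol = atol, maxsteps = 50000)
  }
  istate <- attr(out, "istate")
  if (nrow(out) < length(times) || anyNA(out) ||
      (!is.null(istate) && istate[1] < 0))
    stop("ODE integration failed for condition '", cond$label, "'")
  dens <- out[, -1, drop = FALSE]
  colnames(dens) <- network$species$id
  traj <- structure(list(times = times, densities = dens, condition = cond,
                         network = network),
                    class = "lck_traj")
  if (check_conservation) {
    tot <- totals(traj)
    drift <- function(x) if (x[1] > 0) max(abs(x - x[1])) / x[1] else 0
    if (drift(tot$lck) > 1e-6 || drift(tot$csk) > 1e-6)
      stop("conservation violated (> 1e-6 relative) in condition '",
           cond$label, "'")
  }
  traj
}

# Conserved totals along a trajectory.
totals <- function(traj) {
  cons <- traj$network$conservation
  list(lck = drop(traj$densities %*% cons$lck),
       csk = drop(traj$densities %*% cons$csk))
}

# Per-species molecule composition: how many member LCK molecules of each
# phospho-form a species contains, how many carry phospho-Y394/-Y505, how
# many are doubly phosphorylated, and whether the species is a dimer.
species_composition <- function(species) {
  n <- nrow(species)
  counts <- matrix(0, n, 4, dimnames = list(species$id, LCK_FORMS))
  for (i in seq_len(n)) {
    s <- species[i, ]
    if (s$kind == "free_lck") counts[i, s$sub_form] <- 1
    if (s$kind == "lck_lck_dimer") {
      counts[i, s$enz_form] <- counts[i, s$enz_form] + 1
      counts[i, s$sub_form] <- counts[i, s$sub_form] + 1
    }
    if (s$kind == "csk_lck_dimer") counts[i, s$sub_form] <- 1
  }
  list(counts = counts,
       p394 = drop(counts %*% c(0, 1, 0, 1)),   # PU + PP carry phospho-Y394
       p505 = drop(counts %*% c(0, 0, 1, 1)),   # UP + PP carry phospho-Y505
       pp   = counts[, "PP"],
       bound = species$kind %in% c("lck_lck_dimer", "csk_lck_dimer"))
}

#' Phospho-site observables of a trajectory
#'
#' Total phospho-Y394 and phospho-Y505 (summed over all species containing
#' LCK -- free and bound, active and dead), normalized either by the
#' conserved total LCK density (default; what the published simulations use)
#' or by each site's own 90-min value (matching western-blot data whose
#' curves are normalized to the 90-min band).
#'
#' @param traj \code{lck_traj} from \code{\link{simulate_lck}}.
#' @param normalization \code{"total_lck"} or \code{"site90"}.
#' @return Data.frame of class \code{"lck_observables"} with columns
#'   \code{time_s}, \code{time_min}, \code{y394}, \code{y505}; attribute
#'   \code{"species_fractions"} holds the per-form total/free/bound
#'   fractions of total LCK (time x form x {total, free, bound}).
#' @export
observables <- function(traj, normalization = c("total_lck", "site90")) {
  normalization <- match.arg(normalization)
  comp <- species_composition(traj$network$species)
  dens <- pmax(traj$densities, 0)     # clip integrator undershoot
  y394 <- drop(dens %*% comp$p394)
  y505 <- drop(dens %*% comp$p505)
  if (normalization == "total_lck") {
    norm394 <- norm505 <- totals(traj)$lck[1]
  } else {
    t90 <- 5400
    if (max(traj$times) < t90)
      stop("site90 normalization requires the trajectory to cover 90 min")
    norm394 <- stats::approx(traj$times, y394, t90)$y
    norm505 <- stats::approx(traj$times, y505, t90)$y
  }
  if (norm394 <= 0 || norm505 <= 0)
    stop("observable normalizer is zero")
  tot <- totals(traj)$lck[1]
  frac <- array(0, c(length(traj$times), 4, 3),
                dimnames = list(NULL, LCK_FORMS, c("total", "free", "bound")))
  for (f in LCK_FORMS) {
    w <- comp$counts[, f]
    frac[, f, "total"] <- drop(dens %*% w) / tot
    frac[, f, "free"]  <- drop(dens %*% (w * !comp$bound)) / tot
    frac[, f, "bound"] <- drop(dens %*% (w * comp$bound)) / tot
  }
  out <- data.frame(time_s = traj$times, time_min = traj$times / 60,
                    y394 = y394 / norm394, y505 = y505 / norm505)
  attr(out, "species_fractions") <- frac
  attr(out, "normalization") <- normalization
  class(out) <- c("lck_observables", "data.frame")
  out
}

#' Fraction of LCK doubly phosphorylated at a given time
#'
#' Sum of P394P505-containing LCK (free and bound, active and dead) over
#' total LCK.
#'
#' @param traj \code{lck_traj}.
#' @param t Time in seconds (linearly interpolated between output points).
#' @return Fraction in [0, 1].
#' @export
fraction_pp <- function(traj, t = 5400) {
  stopifnot(t >= 0, t <= max(traj$times))
  comp <- species_composition(traj$network$species)
  pp <- drop(pmax(traj$densities, 0) %*% comp$pp)
  stats::approx(traj$times, pp, t)$y / totals(traj)$lck[1]
}
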