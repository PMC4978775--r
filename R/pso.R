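# Particle swarm optimization over a bounded box.  Constriction-coefficient
# variant (inertia 0.729, cognitive = social = 1.49445), velocities clamped
# to a fraction of the box range, positions clipped to the bounds.  The
# search terminates when the global best has not improved for
# `stall_iterations` consecutive iterations (or at `max_iterations`).

#' Particle swarm minimization
#'
#' @param fn Objective: \code{function(x) -> scalar}.  Non-finite values are
#'   replaced by \code{penalty}.
#' @param lower,upper Numeric bounds (equal length; define the search box).
#' @param n_particles Swarm size (default 31).
#' @param stall_iterations Stop after this many iterations without
#'   improvement of the global best (default 50).
#' @param max_iterations Hard iteration cap (default 1000).
#' @param inertia,c_cognitive,c_social Velocity-update coefficients
#'   (constriction defaults 0.729 / 1.49445 / 1.49445).
#' @param vmax_frac Velocity clamp as a fraction of the box range per
#'   dimension (default 0.2).
#' @param reltol Relative improvement of the global best that resets the
#'   stall counter (default 1e-9).
#' @param penalty Replacement value for non-finite objectives (default 1e12).
#' @param seed Optional integer seed (initialization and velocity updates).
#' @return List of class \code{"pso_fit"}: \code{par}, \code{value},
#'   \code{iterations}, \code{evaluations}, \code{trace} (global best per
#'   iteration).
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- pso_minimize(sphere, c(-5, -5), c(5, 5), seed = 1)
#' fit$value
pso_minimize <- function(fn, lower, upper, n_particles = 31,
                         stall_iterations = 50, max_iterations = 1000,
                         inertia = 0.729, c_cognitive = 1.49445,
                         c_social = 1.49445, vmax_frac = 0.2,
                         reltol = 1e-9, penalty = 1e12, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper),
            n_particles >= 2)
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  rng <- upper - lower
  vmax <- vmax_frac * rng
  X <- matrix(stats::runif(n_particles * d, lower, upper), n_particles, d,
              byrow = TRUE)
  V <- matrix(stats::runif(n_particles * d, -vmax, vmax), n_particles, d,
              byrow = TRUE)
  evalf <- function(x) {
    v <- fn(x)
    if (!is.finite(v)) penalty else v
  }
  f <- apply(X, 1, evalf)
  Pbest <- X; fP <- f
  g <- which.min(fP)
  gbest <- Pbest[g, ]; fg <- fP[g]
  trace <- numeric(0)
  stall <- 0L; it <- 0L
  while (it < max_iterations && stall < stall_iterations) {
    it <- it + 1L
    r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
    r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
    V <- inertia * (V + c_cognitive * r1 * (Pbest - X) +
                      c_social * r2 * sweep(X, 2, gbest, function(x, g) g - x))
    V <- pmin(pmax(V, matrix(-vmax, n_particles, d, byrow = TRUE)),
              matrix(vmax, n_particles, d, byrow = TRUE))
    X <- X + V
    out_lo <- sweep(X, 2, lower, `<`)
    out_hi <- sweep(X, 2, upper, `>`)
    X <- pmin(pmax(X, matrix(lower, n_particles, d, byrow = TRUE)),
              matrix(upper, n_particles, d, byrow = TRUE))
    V[out_lo | out_hi] <- 0   # kill velocity at the wall
    f <- apply(X, 1, evalf)
    better <- f < fP
    Pbest[better, ] <- X[better, , drop = FALSE]
    fP[better] <- f[better]
    g <- which.min(fP)
    improvement <- fg - fP[g]
    if (improvement > reltol * max(abs(fg), 1e-30)) {
      stall <- 0L
    } else stall <- stall + 1L
    if (fP[g] < fg) { fg <- fP[g]; gbest <- Pbest[g, ] }
    trace <- c(trace, fg)
  }
  structure(list(par = gbest, value = fg, iterations = it,
                 evaluations = (it + 1L) * n_particles, trace = trace),
            class = "pso_fit")
}
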