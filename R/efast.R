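# Extended Fourier Amplitude Sensitivity Test (eFAST).  All inputs are
# varied together along a space-filling search curve, each at its own
# frequency; the Fourier spectrum of the output attributes variance to the
# parameter driven at each frequency.  First-order indices (Si) use the
# harmonics of the parameter's own frequency; total indices (STi) are one
# minus the variance at the complementary (low) frequencies.

#' eFAST global sensitivity analysis
#'
#' One parameter at a time is assigned the high frequency
#' \code{omega_max = floor((Ns-1)/(2M))}; the remaining parameters share low
#' frequencies \code{1..floor(omega_max/(2M))}.  Samples follow the curve
#' \code{x = 0.5 + asin(sin(omega s + phi))/pi} mapped onto
#' \code{[lower, upper]}, with a random phase per resample curve.  A dummy
#' parameter (ignored by the model) is appended by default; its indices
#' estimate the significance floor of the method.
#'
#' @param fn Model evaluator: \code{function(x)} over the \code{d} real
#'   parameters returning a (preferably named) numeric vector of outputs.
#'   Failures may return \code{NA}s; failed samples are imputed with the
#'   curve mean and counted.
#' @param lower,upper Sampling bounds per parameter (length \code{d}); any
#'   monotone transform of the parameter (e.g. log10) may be used as the
#'   sampling scale as long as \code{fn} inverts it.
#' @param Ns Samples per curve (odd; default 65, the usual minimum).
#' @param M Interference factor (default 4).
#' @param Nr Resample curves per parameter (default 1); variances are
#'   pooled over the curves before the index ratios are formed.
#' @param include_dummy Append an inert dummy parameter (default TRUE).
#' @param par_names Parameter labels.
#' @param seed RNG seed for the phases.
#' @return List of class \code{"efast_result"}: \code{si} and \code{sti}
#'   (parameters x outputs matrices, dummy last when present),
#'   \code{n_failed} (imputed model failures), \code{Ns}, \code{M},
#'   \code{Nr}.
#' @export
#' @examples
#' ishigami <- function(x) c(y = sin(x[1]) + 7 * sin(x[2])^2 +
#'                             0.1 * x[3]^4 * sin(x[1]))
#' r <- efast(ishigami, rep(-pi, 3), rep(pi, 3), Ns = 257, seed = 1)
#' round(r$si[, 1], 2)
efast <- function(fn, lower, upper, Ns = 65, M = 4, Nr = 1,
                  include_dummy = TRUE, par_names = NULL, seed = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower), Ns %% 2 == 1, M >= 1)
  if (!is.null(seed)) set.seed(seed)
  D <- d + include_dummy
  omega_max <- floor((Ns - 1) / (2 * M))
  if (omega_max < 2)
    stop("Ns too small for interference factor M (Nyquist constraint)")
  omega_comp <- max(1, floor(omega_max / (2 * M)))
  s <- -pi + 2 * pi * (seq_len(Ns) - 1) / Ns
  K <- (Ns - 1) / 2
  cosmat <- cos(outer(1:K, s))  # K x Ns
  sinmat <- sin(outer(1:K, s))
  spectrum <- function(y) {
    A <- drop(cosmat %*% y) * (2 / Ns)
    B <- drop(sinmat %*% y) * (2 / Ns)
    (A^2 + B^2) / 2
  }
  si <- sti <- NULL
  n_failed <- 0L
  out_names <- NULL
  for (i in seq_len(D)) {
    freqs <- rep(seq_len(omega_comp), length.out = D - 1)
    omega <- numeric(D)
    omega[i] <- omega_max
    omega[-i] <- freqs
    si_i <- sti_i <- NULL
    for (r in seq_len(Nr)) {
      phi <- stats::runif(D, 0, 2 * pi)
      U <- 0.5 + asin(sin(outer(s, omega) +
                            matrix(phi, Ns, D, byrow = TRUE))) / pi
      X <- sweep(sweep(U[, seq_len(d), drop = FALSE], 2, upper - lower,
                       `*`), 2, lower, `+`)
      rows <- lapply(seq_len(Ns), function(j)
        tryCatch(fn(X[j, ]), error = function(e) NULL))
      ok <- !vapply(rows, is.null, logical(1))
      if (!any(ok)) stop("model failed on every eFAST sample")
      n_out <- length(rows[[which(ok)[1]]])
      if (is.null(out_names)) out_names <- names(rows[[which(ok)[1]]])
      Y <- matrix(NA_real_, Ns, n_out)
      Y[ok, ] <- do.call(rbind, rows[ok])
      bad <- !stats::complete.cases(Y)
      if (any(bad)) {
        n_failed <- n_failed + sum(bad)
        for (cc in seq_len(ncol(Y)))
          Y[bad, cc] <- mean(Y[!bad, cc])
      }
      if (is.null(si_i)) {
        si_i <- sti_i <- numeric(n_out)  # pooled Vi, Vc accumulators
        v_i <- numeric(n_out)
      }
      for (cc in seq_len(n_out)) {
        sp <- spectrum(Y[, cc] - mean(Y[, cc]))
        si_i[cc]  <- si_i[cc] + sum(sp[(1:M) * omega_max])
        sti_i[cc] <- sti_i[cc] + sum(sp[seq_len(floor(omega_max / 2))])
        v_i[cc]   <- v_i[cc] + sum(sp)
      }
    }
    # pool variance over resample curves before forming the ratios
    v_i[v_i <= 0] <- Inf
    si <- rbind(si, si_i / v_i)
    sti <- rbind(sti, 1 - sti_i / v_i)
  }
  if (is.null(par_names))
    par_names <- paste0("p", seq_len(d))
  rn <- c(par_names, if (include_dummy) "dummy")
  rownames(si) <- rownames(sti) <- rn
  colnames(si) <- colnames(sti) <-
    if (!is.null(out_names)) out_names else paste0("out", seq_len(ncol(si)))
  structure(list(si = si, sti = sti, n_failed = n_failed,
                 Ns = Ns, M = M, Nr = Nr),
            class = "efast_result")
}

#' eFAST sensitivity of the LCK model outputs to the 38 kinetic parameters
#'
#' Varies every rate over \code{[median/range_factor,
#' median*range_factor]} (log10-uniform sampling; the published analysis
#' used a 100-fold range about the ensemble medians) and measures total
#' phospho-Y394 and total phospho-Y505 (fractions of total LCK) at the
#' requested times.
#'
#' @param params Baseline parameter set (default published medians).
#' @param cond Condition to simulate (default high LCK + CSK).
#' @param range_factor Fold-variation about the baseline (default 100).
#' @param output_times Times (seconds) at which the outputs are recorded
#'   (default 5400).
#' @inheritParams efast
#' @return \code{efast_result}; rows are the 38 parameters plus the dummy,
#'   columns \code{y394_t<seconds>} and \code{y505_t<seconds>}.
#' @export
efast_lck <- function(params = median_params(),
                      cond = lck_conditions()$high_lck_csk,
                      range_factor = 100, output_times = 5400, Ns = 65,
                      M = 4, Nr = 2, seed = NULL) {
  params <- rate_params(params)
  network <- network_for_condition(cond)
  times <- sort(unique(c(0, output_times)))
  comp <- species_composition(network$species)
  tot <- cond$lck_density + cond$dead_lck_density
  fn <- function(x) {
    theta <- params_from_log10(x)
    traj <- simulate_lck(theta, cond, network = network, times = times,
                         check_conservation = FALSE)
    dens <- pmax(traj$densities[match(output_times, traj$times), ,
                                drop = FALSE], 0)
    stats::setNames(
      c(dens %*% comp$p394, dens %*% comp$p505) / tot,
      c(paste0("y394_t", output_times), paste0("y505_t", output_times)))
  }
  ctr <- log10_params(params)
  efast(fn, ctr - log10(range_factor), ctr + log10(range_factor), Ns = Ns,
        M = M, Nr = Nr, include_dummy = TRUE, par_names = param_names(),
        seed = seed)
}

#' Concordance of sensitivity rankings across conditions
#'
#' @param results Named list of \code{efast_result}s on the same parameter
#'   list (e.g. high- vs low-LCK conditions).
#' @param top_n Size of the top-ranked set compared (default 5).
#' @return Data.frame of pairwise Spearman rank correlations of STi and
#'   top-\code{top_n} overlaps, per output.
#' @export
compare_conditions <- function(results, top_n = 5) {
  stopifnot(length(results) >= 2)
  rn <- rownames(results[[1]]$sti)
  for (r in results)
    if (!identical(rownames(r$sti), rn))
      stop("parameter lists differ between results")
  if (is.null(names(results)))
    names(results) <- paste0("result", seq_along(results))
  combs <- utils::combn(names(results), 2)
  out <- list()
  for (j in seq_len(ncol(combs))) {
    a <- results[[combs[1, j]]]$sti
    b <- results[[combs[2, j]]]$sti
    for (cc in intersect(colnames(a), colnames(b))) {
      rho <- stats::cor(a[, cc], b[, cc], method = "spearman")
      ta <- rn[order(a[, cc], decreasing = TRUE)][seq_len(top_n)]
      tb <- rn[order(b[, cc], decreasing = TRUE)][seq_len(top_n)]
      out[[length(out) + 1L]] <- data.frame(
        a = combs[1, j], b = combs[2, j], output = cc,
        spearman_sti = rho, top_overlap = length(intersect(ta, tb)))
    }
  }
  do.call(rbind, out)
}
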