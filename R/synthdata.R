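# Synthetic phospho-time-course datasets with the statistical structure of
# quantitative western blots: positive band intensities, multiplicative
# (lognormal) noise, each site normalized to its own 90-min value.

#' Default blot sampling grid (minutes)
#'
#' Spans the fast phase (sub-minute points), the intermediate rise and the
#' 90-min anchor used for normalization.
#'
#' @return Numeric vector of times in minutes.
#' @export
default_time_grid <- function() c(0, 0.25, 0.5, 1, 2, 5, 10, 15, 30, 45, 60, 90)

#' Generate a synthetic phospho-time-course dataset
#'
#' Simulates a condition, samples the phospho-Y394/-Y505 observables on a
#' time grid, multiplies each point by independent lognormal noise with the
#' requested coefficient of variation (mean 1), and renormalizes each site
#' by its noisy 90-min value -- so the 90-min point is exactly 1 per site,
#' as in blot data normalized to the final band.  Points whose noiseless
#' value is 0 (e.g. t = 0) stay 0: the noise is multiplicative.
#'
#' @param params True \code{lck_params} used for the simulation.
#' @param cond \code{lck_condition}.
#' @param times_min Sampling grid in minutes; must include 90.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.1).
#' @param seed Integer seed (reproducible); \code{NULL} leaves the RNG state
#'   alone.
#' @return Data.frame of class \code{"lck_dataset"} with columns
#'   \code{time_min}, \code{y394}, \code{y505}; attributes
#'   \code{condition}, \code{condition_label}, \code{truth_params},
#'   \code{noise_cv}, \code{seed}.
#' @export
#' @examples
#' d <- generate_dataset(median_params(), lck_conditions()$high_lck, seed = 1)
#' d[d$time_min == 90, ]  # both sites exactly 1 by construction
generate_dataset <- function(params, cond, times_min = default_time_grid(),
                             noise_cv = 0.1, seed = NULL) {
  stopifnot(noise_cv >= 0, 90 %in% times_min)
  if (!is.null(seed)) set.seed(seed)
  traj <- simulate_lck(params, cond, times = times_min * 60)
  obs <- observables(traj, normalization = "total_lck")
  i <- match(round(times_min * 60, 9), round(obs$time_s, 9))
  noisy <- function(x) {
    if (noise_cv == 0) return(x / x[times_min == 90])
    sdlog <- sqrt(log(1 + noise_cv^2))
    eps <- stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    x <- x * eps
    x / x[times_min == 90]
  }
  out <- data.frame(time_min = times_min, y394 = noisy(obs$y394[i]),
                    y505 = noisy(obs$y505[i]))
  structure(out, condition = cond, condition_label = cond$label,
            truth_params = params, noise_cv = noise_cv, seed = seed,
            class = c("lck_dataset", "data.frame"))
}

#' Generate datasets for a set of conditions
#'
#' @param params True parameter set.
#' @param conditions Named list of \code{lck_condition}s (default: the four
#'   training conditions).
#' @param seed Base seed; condition j uses \code{seed + j - 1}.
#' @inheritParams generate_dataset
#' @return Named list of \code{lck_dataset}s.
#' @export
generate_datasets <- function(params, conditions = lck_conditions()[1:4],
                              times_min = default_time_grid(),
                              noise_cv = 0.1, seed = NULL) {
  out <- vector("list", length(conditions))
  names(out) <- names(conditions)
  for (j in seq_along(conditions))
    out[[j]] <- generate_dataset(params, conditions[[j]], times_min,
                                 noise_cv,
                                 if (is.null(seed)) NULL else seed + j - 1)
  out
}

#' Read / write phospho-time-course datasets as CSV
#'
#' Wide CSV with header \code{time_min,y394,y505}; the condition label is
#' kept in a leading \code{# condition:} comment line.
#'
#' @param dataset \code{lck_dataset}.
#' @param path File path.
#' @param cond Optional \code{lck_condition} to attach on load (otherwise
#'   only the label from the file comment is attached).
#' @return \code{load_dataset} returns an \code{lck_dataset}.
#' @export
write_dataset <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lab <- attr(dataset, "condition_label")
  if (!is.null(lab)) writeLines(paste0("# condition: ", lab), con)
  utils::write.csv(as.data.frame(dataset)[, c("time_min", "y394", "y505")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
load_dataset <- function(path, cond = NULL) {
  first <- readLines(path, n = 1)
  lab <- if (startsWith(first, "# condition:"))
    trimws(sub("# condition:", "", first)) else NULL
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("time_min", "y394", "y505")
  if (!all(need %in% names(d))) {
    if (all(c("time_min", "variable", "value") %in% names(d))) {  # long form
      d <- stats::reshape(d, idvar = "time_min", timevar = "variable",
                          direction = "wide")
      names(d) <- sub("^value\\.", "", names(d))
    } else stop("expected columns time_min, y394, y505 (or long format)")
  }
  d <- d[, need]
  bad_time <- which(is.na(d$time_min) | d$time_min < 0)
  bad_val  <- which(d$y394 < 0 | d$y505 < 0 | is.na(d$y394) | is.na(d$y505))
  dup      <- which(duplicated(d$time_min))
  if (length(c(bad_time, bad_val, dup)))
    stop("invalid dataset rows -- negative/missing time: [",
         paste(bad_time, collapse = ","), "]; negative/missing value: [",
         paste(bad_val, collapse = ","), "]; duplicated time: [",
         paste(dup, collapse = ","), "]")
  if (nrow(d) < 2) stop("dataset needs at least 2 time points")
  d <- d[order(d$time_min), ]
  rownames(d) <- NULL
  structure(d, condition = cond, condition_label = lab,
            class = c("lck_dataset", "data.frame"))
}
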