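#' @useDynLib lckautoreg, .registration = TRUE
"_PACKAGE"

# The four LCK phospho-forms, in the fixed order used throughout the package
# (free-species layout, pair table, parameter vector).
LCK_FORMS <- c("UU", "PU", "UP", "PP")

#' Enzyme-substrate pair table of the LCK/CSK phosphorylation network
#'
#' Each LCK phospho-form (\code{UU} = U394U505, \code{PU} = P394U505,
#' \code{UP} = U394P505, \code{PP} = P394P505) can bind, in trans, any of the
#' four unphosphorylated substrate sites (Y394 on UU and UP; Y505 on UU and
#' PU), giving 16 LCK-LCK enzyme-substrate pairs.  CSK phosphorylates LCK
#' only at Y505, so it has exactly two substrates (Y505 on UU and on PU).
#' Each pair has its own dissociation and catalytic rate; the association
#' rate is shared by all LCK pairs (\code{k_on}) and by both CSK pairs
#' (\code{k_on_csk}).
#'
#' @return A data.frame with one row per enzyme-substrate pair (16 LCK rows
#'   followed by the two CSK rows) and columns \code{pair} (label),
#'   \code{enzyme} (enzyme phospho-form or \code{"CSK"}), \code{sub_form}
#'   (substrate host form), \code{site} (\code{"Y394"} or \code{"Y505"}),
#'   \code{product} (substrate form after catalysis), and the names of the
#'   dissociation/catalytic rate parameters (\code{koff_name},
#'   \code{kcat_name}).
#' @export
#' @examples
#' lck_pairs()
lck_pairs <- function() {
  pairs <- data.frame(
    pair     = c(as.character(1:16), "CSK-UU", "CSK-PU"),
    enzyme   = c("UU", "UU", "UU", "PU", "PU", "UU", "UP", "UP", "PU", "UP",
                 "PU", "UP", "PP", "PP", "PP", "PP", "CSK", "CSK"),
    sub_form = c("UU", "UU", "PU", "UU", "UU", "UP", "UU", "UU", "PU", "PU",
                 "UP", "UP", "UU", "UU", "PU", "UP", "UU", "PU"),
    site     = c("Y394", "Y505", "Y505", "Y394", "Y505", "Y394", "Y394",
                 "Y505", "Y505", "Y505", "Y394", "Y394", "Y394", "Y505",
                 "Y505", "Y394", "Y505", "Y505"),
    stringsAsFactors = FALSE
  )
  pairs$product <- phosphorylate(pairs$sub_form, pairs$site)
  idx <- c(1:16, 1, 2)
  suffix <- c(as.character(1:16), "csk_uu", "csk_pu")
  pairs$koff_name <- paste0("k_off_", suffix)
  pairs$kcat_name <- paste0("k_cat_", suffix)
  pairs
}

# Phosphorylate `site` on host form(s) `form`: U394U505 -> P394U505 etc.
phosphorylate <- function(form, site) {
  out <- character(length(form))
  out[site == "Y394"] <- sub("^U", "P", form[site == "Y394"])
  out[site == "Y505"] <- sub("U$", "P", form[site == "Y505"])
  out
}

#' Canonical parameter-vector names
#'
#' The 38 kinetic parameters: the shared LCK association rate, the shared
#' CSK association rate, 16 + 2 dissociation rates and 16 + 2 catalytic
#' rates, in the fixed order used by every function in the package.
#'
#' @return Character vector of length 38.
#' @export
param_names <- function() {
  p <- lck_pairs()
  c("k_on", "k_on_csk", p$koff_name, p$kcat_name)
}

#' Construct a kinetic rate-parameter set
#'
#' @param x Named numeric vector containing all 38 parameters (any order),
#'   or a list coercible to one.
#' @return Named numeric vector of length 38 in canonical order, class
#'   \code{"lck_params"}.  Units: \code{k_on}, \code{k_on_csk} in
#'   um^2/(molecule s); all dissociation and catalytic rates in 1/s.
#' @export
rate_params <- function(x) {
  x <- unlist(x)
  nm <- param_names()
  if (!all(nm %in% names(x)))
    stop("missing parameters: ", paste(setdiff(nm, names(x)), collapse = ", "))
  x <- x[nm]
  if (anyNA(x) || any(x < 0))
    stop("all 38 rate parameters must be non-negative and non-missing")
  structure(x, class = "lck_params")
}

# Published ensemble-median rates and 90% CIs (median of the 20 best-fit
# parameter sets), transcribed verbatim -- including the rows whose printed
# CI does not bracket the median (see params_ci_flags()).
PARAM_TABLE <- local({
  koff     <- c(1.0e-1, 4.9e2, 6.1e5, 2.6e7, 6.4e2, 7.6e-4, 1.1e-3, 1.2e-3,
                2.3e2, 5.3e1, 7.7e4, 5.4e1, 1.6e1, 5.6e6, 2.4e-11, 1.6e0,
                4.4e-2, 1.3e-6)
  koff_lo  <- c(4.8e-7, 4.1e2, 9.7e4, 4.6e3, 5.5e2, 2.6e-5, 1.2e-3, 1.9e-3,
                1.8e2, 1.3e0, 1.3e0, 1.0e1, 1.8e-3, 1.1e6, 1.8e-11, 6.8e-1,
                2.5e-2, 1.4e-7)
  koff_hi  <- c(3.0e-2, 1.5e3, 2.8e6, 2.8e7, 5.1e3, 1.5e-3, 1.8e-2, 6.1e-2,
                7.0e2, 7.7e3, 2.1e4, 1.1e4, 5.1e1, 9.1e6, 9.7e-10, 2.5e0,
                8.6e-2, 1.4e-5)
  kcat     <- c(2.7e3, 4.2e1, 7.6e-11, 2.2e-3, 3.9e1, 4.6e-6, 5.9e-12,
                6.6e-11, 1.3e1, 6.3e-8, 9.5e-3, 1.9e-6, 9.2e2, 5.8e-11,
                8.1e-4, 6.3e-2, 2.1e-3, 1.8e7)
  kcat_lo  <- c(2.1e3, 2.9e1, 2.5e-11, 5.1e-6, 5.4e-1, 1.2e-8, 8.3e-12,
                1.0e-11, 9.4e0, 1.9e-8, 2.3e-5, 3.4e-7, 2.0e2, 3.0e-12,
                8.1e-4, 9.0e-5, 1.5e-3, 9.3e5)
  kcat_hi  <- c(6.5e3, 8.4e1, 5.2e-8, 1.3e-1, 5.0e1, 6.6e-6, 3.8e-10,
                1.8e-9, 3.0e1, 2.2e-3, 5.4e-1, 1.0e-4, 9.1e3, 6.5e-9,
                8.1e-4, 6.6e-2, 2.0e-3, 2.6e7)
  cbind(lck_pairs(),
        data.frame(koff = koff, koff_lo = koff_lo, koff_hi = koff_hi,
                   kcat = kcat, kcat_lo = kcat_lo, kcat_hi = kcat_hi))
})

KON_MEDIAN     <- 8.9e-4; KON_CI     <- c(6.8e-4, 1.9e-3)
KON_CSK_MEDIAN <- 5.9e-4; KON_CSK_CI <- c(4.4e-4, 1.2e-3)

#' Published median parameter set
#'
#' The ensemble medians of the 20 best-fit parameter sets: the canonical
#' baseline used for forward simulation, sensitivity analysis and as truth
#' for the synthetic-data generator.
#'
#' @return An \code{lck_params} vector (length 38).
#' @export
#' @examples
#' theta <- median_params()
#' theta["k_on"]  # shared LCK association rate, um^2/(molecule s)
median_params <- function() {
  p <- PARAM_TABLE
  v <- c(k_on = KON_MEDIAN, k_on_csk = KON_CSK_MEDIAN,
         stats::setNames(p$koff, p$koff_name),
         stats::setNames(p$kcat, p$kcat_name))
  rate_params(v)
}

#' Parameter table with ensemble medians and 90% confidence intervals
#'
#' @return Data.frame: one row per enzyme-substrate pair with median and
#'   90% CI (5th-95th percentile of the best-fit ensemble) for the
#'   dissociation and catalytic rates, plus two rows for the shared
#'   association rates.
#' @export
param_table <- function() {
  p <- PARAM_TABLE
  long <- rbind(
    data.frame(parameter = "k_on", pair = "shared LCK", median = KON_MEDIAN,
               ci_lo = KON_CI[1], ci_hi = KON_CI[2]),
    data.frame(parameter = "k_on_csk", pair = "shared CSK",
               median = KON_CSK_MEDIAN, ci_lo = KON_CSK_CI[1],
               ci_hi = KON_CSK_CI[2]),
    data.frame(parameter = p$koff_name, pair = p$pair, median = p$koff,
               ci_lo = p$koff_lo, ci_hi = p$koff_hi),
    data.frame(parameter = p$kcat_name, pair = p$pair, median = p$kcat,
               ci_lo = p$kcat_lo, ci_hi = p$kcat_hi)
  )
  rownames(long) <- NULL
  long
}

#' Flag parameter rows whose printed CI does not bracket the median
#'
#' Several rows of the published parameter table have a 90% CI that does not
#' contain the reported median.  The table is transcribed verbatim; this
#' helper reports the internally inconsistent rows rather than silently
#' correcting them.
#'
#' @return Subset of \code{param_table()} rows with \code{median < ci_lo} or
#'   \code{median > ci_hi}.
#' @export
params_ci_flags <- function() {
  tab <- param_table()
  tab[tab$median < tab$ci_lo | tab$median > tab$ci_hi, , drop = FALSE]
}

#' Read / write parameter sets as JSON
#'
#' @param params An \code{lck_params} vector.
#' @param path File path.
#' @return \code{read_params} returns an \code{lck_params} vector.
#' @export
write_params <- function(params, path) {
  params <- rate_params(params)
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  rate_params(unlist(jsonlite::read_json(path)))
}

# log10 transform helpers used by the fitting and sensitivity modules.
log10_params <- function(params) log10(pmax(unclass(params), 1e-300))

params_from_log10 <- function(x, template = NULL, free = NULL) {
  if (is.null(free)) return(rate_params(stats::setNames(10^x, param_names())))
  th <- unclass(rate_params(template))
  th[free] <- 10^x
  rate_params(th)
}
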