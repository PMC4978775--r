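# Reduction of a fitted ensemble to the optimal parameter sets: a
# training-WSSR cutoff on the CDF of the campaign, a validation-WSSR cutoff
# (dead-LCK model vs the validation data), and removal of sets that fail to
# doubly phosphorylate >= 90% of the LCK in the high-LCK condition by
# 90 min; then k-means clustering and ensemble statistics.

#' Selection configuration
#'
#' @param training_cutoff Training WSSR cutoff (published value 7.1).
#' @param validation_cutoff Validation WSSR cutoff (published value 3.3).
#' @param pp_threshold Minimum doubly-phosphorylated fraction at 90 min in
#'   the high-LCK condition (published criterion 0.90).
#' @param cdf_mode \code{"fixed_cutoff"} (use the numeric cutoffs) or
#'   \code{"elbow"} (data-driven: largest second difference of the sorted
#'   log10-WSSR curve; the published cutoffs were chosen visually from the
#'   CDF, which is not reproducible).
#' @return List of class \code{"select_config"}.
#' @export
select_config <- function(training_cutoff = 7.1, validation_cutoff = 3.3,
                          pp_threshold = 0.90,
                          cdf_mode = c("fixed_cutoff", "elbow")) {
  stopifnot(training_cutoff > 0, validation_cutoff > 0,
            pp_threshold > 0, pp_threshold <= 1)
  structure(list(training_cutoff = training_cutoff,
                 validation_cutoff = validation_cutoff,
                 pp_threshold = pp_threshold,
                 cdf_mode = match.arg(cdf_mode)),
            class = "select_config")
}

# Elbow cutoff: the largest second difference of the sorted log10-WSSR
# curve marks the end of the initial low-WSSR step; the cutoff is placed
# between the last set of the step and the first set beyond it.
elbow_cutoff <- function(wssr) {
  s <- sort(log10(wssr))
  if (length(s) < 3) return(max(wssr))
  d2 <- diff(s, differences = 2)
  i <- which.max(d2) + 1
  10^((s[i] + s[i + 1]) / 2)
}

#' Apply the three selection criteria to known per-set statistics
#'
#' Pure filter logic (no simulation): criterion 1 removes sets at or above
#' the training cutoff; criterion 2 removes remaining sets at or above the
#' validation cutoff; criterion 3 removes remaining sets whose
#' doubly-phosphorylated fraction is below the threshold.  Each set is
#' attributed to the first criterion that removed it.
#'
#' @param train_w,val_w,pp Per-set training WSSR, validation WSSR and
#'   doubly-phosphorylated fraction (\code{NA} values never cause removal
#'   by that criterion).
#' @param training_cutoff,validation_cutoff,pp_threshold Numeric cutoffs.
#' @return Character vector: \code{"none"}, \code{"training"},
#'   \code{"validation"} or \code{"double_phospho"} per set.
#' @export
apply_selection <- function(train_w, val_w, pp, training_cutoff,
                            validation_cutoff, pp_threshold) {
  removed <- rep("none", length(train_w))
  removed[!is.na(train_w) & train_w >= training_cutoff] <- "training"
  i <- removed == "none" & !is.na(val_w) & val_w >= validation_cutoff
  removed[i] <- "validation"
  i <- removed == "none" & !is.na(pp) & pp < pp_threshold
  removed[i] <- "double_phospho"
  removed
}

#' Filter a fitted ensemble by the three selection criteria
#'
#' Applies, in order: (1) training-WSSR cutoff, (2) validation-WSSR cutoff
#' (each set's validation WSSR is computed by simulating the dead-LCK model
#' against the validation dataset), (3) removal of sets in which less than
#' \code{pp_threshold} of the LCK is doubly phosphorylated at 90 min in the
#' high-LCK condition.  Each removal is attributed to the criterion that
#' caused it.
#'
#' @param ensemble \code{lck_ensemble}.
#' @param validation_data Validation \code{lck_dataset} (condition
#'   attached), or \code{NULL} to skip criterion 2.
#' @param config \code{\link{select_config}}.
#' @return List of class \code{"lck_selection"}: \code{ensemble} (the
#'   surviving subset), \code{audit} (per-set data.frame: training WSSR,
#'   validation WSSR, PP fraction, \code{removed_by} in
#'   \{none, training, validation, double_phospho\}), and the cutoffs used.
#' @export
select_ensemble <- function(ensemble, validation_data,
                            config = select_config()) {
  n <- nrow(ensemble$params)
  train_w <- ensemble$wssr_quant
  t_cut <- if (config$cdf_mode == "elbow") elbow_cutoff(train_w)
  else config$training_cutoff
  removed <- apply_selection(train_w, NA, NA, t_cut, Inf, 0)
  val_w <- rep(NA_real_, n)
  v_cut <- config$validation_cutoff
  if (!is.null(validation_data)) {
    alive <- which(removed == "none")
    vctx <- make_sim_contexts(list(validation_data))
    for (i in alive) {
      val_w[i] <- tryCatch({
        sims <- simulate_for_datasets(rate_params(ensemble$params[i, ]),
                                      list(validation_data), vctx)
        wssr_quant(sims, list(validation_data))$wssr_quant
      }, error = function(e) Inf)
    }
    if (config$cdf_mode == "elbow" && length(alive) > 2)
      v_cut <- elbow_cutoff(val_w[alive])
    removed <- apply_selection(train_w, val_w, NA, t_cut, v_cut, 0)
  }
  pp <- rep(NA_real_, n)
  high <- lck_conditions()$high_lck
  for (i in which(removed == "none")) {
    pp[i] <- tryCatch(
      fraction_pp(simulate_lck(rate_params(ensemble$params[i, ]), high,
                               times = c(0, 5400),
                               check_conservation = FALSE), 5400),
      error = function(e) 0)
  }
  removed <- apply_selection(train_w, val_w, pp, t_cut, v_cut,
                             config$pp_threshold)
  keep <- removed == "none"
  if (!any(keep))
    warning("no parameter sets survive the selection criteria")
  audit <- data.frame(set = seq_len(n), training_wssr = train_w,
                      validation_wssr = val_w, pp_fraction = pp,
                      removed_by = removed)
  survivors <- list(
    params = ensemble$params[keep, , drop = FALSE],
    wssr_quant = ensemble$wssr_quant[keep],
    wssr_hybr = ensemble$wssr_hybr[keep],
    provenance = ensemble$provenance[keep, , drop = FALSE],
    free = ensemble$free, config = ensemble$config)
  class(survivors) <- "lck_ensemble"
  structure(list(ensemble = survivors, audit = audit,
                 training_cutoff = t_cut, validation_cutoff = v_cut,
                 pp_threshold = config$pp_threshold),
            class = "lck_selection")
}

#' Cluster parameter sets by k-means with silhouette-selected k
#'
#' Clustering is performed on standardized log10 parameters (raw-scale
#' distances would be dominated by the largest rates); constant columns are
#' dropped.  For each candidate k a k-means fit (multiple restarts, fixed
#' seed) is scored by the sum of its silhouette values; the k with the
#' maximal sum wins.
#'
#' @param param_mat Sets x parameters matrix (linear scale), or an
#'   \code{lck_ensemble}.
#' @param k_candidates Candidate cluster counts (default 2:6; values
#'   exceeding n-1 are skipped).
#' @param seed RNG seed for the restarts.
#' @param nstart k-means restarts per k (default 20).
#' @return List of class \code{"lck_clusters"}: \code{labels}, \code{k},
#'   \code{silhouette_sum} (named by candidate k), \code{sizes},
#'   \code{diagnostic}.
#' @export
cluster_parameter_sets <- function(param_mat, k_candidates = 2:6, seed = 1,
                                   nstart = 20) {
  if (inherits(param_mat, "lck_ensemble")) param_mat <- param_mat$params
  X <- log10(pmax(param_mat, 1e-300))
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  n <- nrow(X)
  if (ncol(X) == 0 || n < 3 || max(apply(X, 2, stats::sd)) == 0)
    return(structure(list(labels = rep(1L, n), k = 1L,
                          silhouette_sum = numeric(0), sizes = n,
                          diagnostic = "degenerate input: all sets identical"),
                     class = "lck_clusters"))
  X <- scale(X)
  D <- stats::dist(X)
  sil_sum <- stats::setNames(rep(NA_real_, length(k_candidates)),
                             k_candidates)
  fits <- list()
  for (j in seq_along(k_candidates)) {
    k <- k_candidates[j]
    if (k >= n) next
    set.seed(seed)
    km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100)
    sil <- cluster::silhouette(km$cluster, D)
    sil_sum[j] <- sum(sil[, "sil_width"])
    fits[[as.character(k)]] <- km
  }
  if (all(is.na(sil_sum)))
    return(structure(list(labels = rep(1L, n), k = 1L,
                          silhouette_sum = sil_sum, sizes = n,
                          diagnostic = "no candidate k feasible"),
                     class = "lck_clusters"))
  best <- names(which.max(sil_sum))
  km <- fits[[best]]
  structure(list(labels = km$cluster, k = as.integer(best),
                 silhouette_sum = sil_sum,
                 sizes = as.integer(table(km$cluster)), diagnostic = NULL),
            class = "lck_clusters")
}

#' Ensemble statistics: medians, 90% CIs and enzyme-comparison ANOVA
#'
#' Per-parameter median and 90% CI (5th-95th percentile) across the sets,
#' plus one-way ANOVA comparing, on each common substrate site, the log10
#' catalytic (and dissociation) rates across the four enzyme forms --
#' rates span many decades, so the comparison is on the log scale.
#'
#' @param param_mat Sets x parameters matrix (linear scale), or an
#'   \code{lck_ensemble}.
#' @return List of class \code{"lck_ensemble_stats"}: \code{summary}
#'   (parameter, median, ci_lo, ci_hi), \code{anova} (substrate site, rate
#'   type, p value; \code{NA} when the sets are identical and inference is
#'   undefined).
#' @export
ensemble_stats <- function(param_mat) {
  if (inherits(param_mat, "lck_ensemble")) param_mat <- param_mat$params
  stopifnot(nrow(param_mat) >= 3)
  med <- apply(param_mat, 2, stats::median)
  qs <- apply(param_mat, 2, stats::quantile, probs = c(0.05, 0.95))
  summ <- data.frame(parameter = colnames(param_mat), median = med,
                     ci_lo = qs[1, ], ci_hi = qs[2, ], row.names = NULL)
  pairs <- lck_pairs()
  lckp <- pairs[pairs$enzyme != "CSK", ]
  sites <- unique(lckp[, c("sub_form", "site")])
  an <- list()
  for (i in seq_len(nrow(sites))) {
    rows <- lckp[lckp$sub_form == sites$sub_form[i] &
                   lckp$site == sites$site[i], ]
    for (rt in c("kcat", "koff")) {
      cols <- if (rt == "kcat") rows$kcat_name else rows$koff_name
      df <- data.frame(
        value = log10(pmax(as.vector(param_mat[, cols]), 1e-300)),
        enzyme = factor(rep(rows$enzyme, each = nrow(param_mat))))
      within_sd <- tapply(df$value, df$enzyme, stats::sd)
      # identical sets carry no sampling variability: inference undefined
      p <- if (all(within_sd == 0)) NA_real_
      else summary(stats::aov(value ~ enzyme, data = df))[[1]][
        "enzyme", "Pr(>F)"]
      an[[length(an) + 1L]] <- data.frame(
        substrate = paste0(sites$site[i], " on ", sites$sub_form[i]),
        rate = rt, p_value = p)
    }
  }
  structure(list(summary = summ, anova = do.call(rbind, an)),
            class = "lck_ensemble_stats")
}
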