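# Base-pair-level evaluation of hotspot calls against known truth, and the
# power-study driver: power is the proportion of true hotspot sequence
# called, the false positive rate the proportion of non-hotspot sequence
# called, and the false discovery rate the proportion of called sequence
# not inside a true hotspot.

#' Evaluate hotspot calls against truth at bp resolution
#'
#' @param truth an [interval_set()] of true hotspot intervals (optionally
#'   restricted to one intensity).
#' @param calls an [interval_set()] (or a `call_set`'s `intervals`).
#' @param region_length region length, bp.
#' @return A list of class `hotspot_metrics`: `power`, `fpr`, `fdr`,
#'   bp counts, and `no_calls` (TRUE when nothing was called, in which case
#'   `fdr` is reported as 0).
#' @examples
#' evaluate_calls(interval_set(0, 2000), interval_set(1000, 3000), 10000)
#' @export
evaluate_calls <- function(truth, calls, region_length) {
  if (inherits(calls, "call_set")) calls <- calls$intervals
  true_bp <- interval_total_bp(truth)
  called_bp <- interval_total_bp(calls)
  if ((nrow(truth) && max(truth$end) > region_length) ||
      (nrow(calls) && max(calls$end) > region_length))
    stop("intervals extend beyond the region")
  overlap_bp <- interval_overlap_bp(truth, calls)
  structure(list(
    power = if (true_bp > 0) overlap_bp / true_bp else NA_real_,
    fpr = (called_bp - overlap_bp) / (region_length - true_bp),
    fdr = if (called_bp > 0) (called_bp - overlap_bp) / called_bp else 0,
    true_bp = true_bp, called_bp = called_bp, overlap_bp = overlap_bp,
    region_bp = region_length, no_calls = called_bp == 0),
    class = "hotspot_metrics")
}

#' @export
print.hotspot_metrics <- function(x, ...) {
  cat(sprintf("power %.3f, FPR %.4f, FDR %.3f (%g/%g bp called in %g bp truth)\n",
              x$power, x$fpr, x$fdr, x$overlap_bp, x$called_bp, x$true_bp))
  invisible(x)
}

pool_counts <- function(true_bp, called_bp, overlap_bp, region_bp) {
  list(power = if (true_bp > 0) overlap_bp / true_bp else NA_real_,
       fpr = (called_bp - overlap_bp) / (region_bp - true_bp),
       fdr = if (called_bp > 0) (called_bp - overlap_bp) / called_bp else 0)
}

#' Run a hotspot-caller power study
#'
#' For each replicate, generates a study region with known hotspot truth,
#' scans it at each window size, applies each calling protocol, and pools
#' bp counts across replicates before forming power / false positive rate /
#' false discovery rate ratios (overall and per hotspot intensity).
#' Per-intensity power counts only overlap with that intensity's truth
#' intervals; called bp overlapping no truth contribute only to the false
#' positive and false discovery rates.
#'
#' @param cfg a [study_config()]; its `seed` drives all replicates.
#' @param table a matching two-locus table.
#' @param null_tables named list of [build_null_table()] results, names =
#'   window size in kb (e.g. `list("20" = nt20)`), one per entry of
#'   `window_sizes`.
#' @param protocols subset of `c("auton2012", "auton2014", "mlehot")`.
#' @param window_sizes analysis window sizes in kb.
#' @param alpha,alpha_strict candidate and strict p-value thresholds.
#' @param rho_min tile/peak rate threshold for the profile-based filters
#'   (\eqn{\rho}/kb); `NULL` uses 10x the configured background rate.
#' @param profile_flank flank for [rho_profile()], bp.
#' @return A list of class `study_result` with a `metrics` data.frame
#'   (protocol x window x fold, pooled), the pooled bp counts, and the
#'   config.
#' @export
run_power_study <- function(cfg, table, null_tables,
                            protocols = c("auton2012", "auton2014", "mlehot"),
                            window_sizes = 20, alpha = 0.01,
                            alpha_strict = 0.001, rho_min = 5,
                            profile_flank = 9000) {
  stopifnot(inherits(cfg, "study_config"))
  protocols <- match.arg(protocols, c("auton2012", "auton2014", "mlehot"),
                         several.ok = TRUE)
  if (is.null(rho_min)) rho_min <- 10 * cfg$background_rate
  for (w in window_sizes) {
    if (is.null(null_tables[[as.character(w)]]))
      stop("no null table supplied for window size ", w, " kb")
  }
  folds <- sort(unique(cfg$intensities))
  keys <- expand.grid(protocol = protocols, window_kb = window_sizes,
                      fold = c(as.character(folds), "all"),
                      stringsAsFactors = FALSE)
  acc <- data.frame(keys, true_bp = 0, called_bp = 0, overlap_bp = 0,
                    region_bp = 0)

  for (rep_i in seq_len(cfg$replicates)) {
    reg <- generate_study_region(cfg, rep_i)
    prof <- rho_profile(reg$haps, table, flank = profile_flank)
    for (w in window_sizes) {
      nt <- null_tables[[as.character(w)]]
      tests <- scan_region(reg$haps, w, table, nt,
                           alpha_strict = alpha_strict)
      for (proto in protocols) {
        calls <- switch(proto,
          auton2012 = call_auton2012(tests, prof, alpha = alpha,
                                     rho_min = rho_min),
          auton2014 = call_auton2014(tests, alpha = alpha,
                                     alpha_strict = alpha_strict),
          mlehot = call_mlehot(tests, prof, alpha = alpha,
                               rho_min = rho_min))
        for (f in c(as.character(folds), "all")) {
          tr <- if (f == "all") reg$truth
                else reg$truth[reg$truth$fold == as.numeric(f), , drop = FALSE]
          i <- which(acc$protocol == proto & acc$window_kb == w & acc$fold == f)
          acc$true_bp[i] <- acc$true_bp[i] + interval_total_bp(tr)
          acc$called_bp[i] <- acc$called_bp[i] +
            interval_total_bp(calls$intervals)
          acc$overlap_bp[i] <- acc$overlap_bp[i] +
            interval_overlap_bp(tr, calls$intervals)
          acc$region_bp[i] <- acc$region_bp[i] + cfg$region_length
        }
      }
    }
  }
  acc$power <- ifelse(acc$true_bp > 0, acc$overlap_bp / acc$true_bp, NA)
  acc$fpr <- (acc$called_bp - acc$overlap_bp) / (acc$region_bp - acc$true_bp)
  acc$fdr <- ifelse(acc$called_bp > 0,
                    (acc$called_bp - acc$overlap_bp) / acc$called_bp, 0)
  # calls overlapping another intensity's hotspot are not false positives,
  # so fpr/fdr are only meaningful pooled over all intensities
  acc$fpr[acc$fold != "all"] <- NA
  acc$fdr[acc$fold != "all"] <- NA
  structure(list(metrics = acc, config = cfg,
                 protocols = protocols, window_sizes = window_sizes,
                 alpha = alpha, alpha_strict = alpha_strict,
                 rho_min = rho_min),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d replicate(s) of %g kb, n = %d\n",
              x$config$replicates, x$config$region_length / 1000,
              x$config$n))
  m <- x$metrics[x$metrics$fold == "all", ]
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-10s %3g kb window: power %5.1f%%  FPR %5.2f%%  FDR %5.1f%%\n",
                m$protocol[i], m$window_kb[i], 100 * m$power[i],
                100 * m$fpr[i], 100 * m$fdr[i]))
  invisible(x)
}
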