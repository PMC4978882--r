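# Sliding-window hotspot scan and the three calling protocols: candidate
# regions are merged significant 2 kb windows (P < 0.01); the protocols then
# differ in how candidates are filtered (size + peak-rate filter; a stricter
# per-window P cutoff; or intersection with 1 kb tiles whose estimated rate
# clears a threshold).

#' Scan a region with 2 kb test windows at 1 kb steps
#'
#' Every `test_len` window (stepped by `step`) is tested as a potential
#' hotspot by analyzing the `window_kb` kb region centered on it (truncated
#' at region edges), and its p-value is looked up in the matching null
#' table.  Windows whose analysis window holds fewer than 2 SNPs are
#' emitted with `p = 1` and `insufficient = TRUE`.
#'
#' @param h a [hap_matrix()] for the region.
#' @param window_kb analysis window size, kb.
#' @param table a matching [build_two_locus_table()] result.
#' @param null_table a [build_null_table()] result for `window_kb` and the
#'   same sample size.
#' @param step window step, bp.
#' @param test_len test window length, bp.
#' @param alpha_strict the strictest p-value cutoff any downstream protocol
#'   will apply; the conditioning bin is required to hold enough null
#'   records for that cutoff to be attainable.
#' @param rho0_grid,rho1_grid,const_grid grids passed to [lrt_statistic()].
#' @return A data.frame of class `window_scan`, one row per test window.
#' @export
scan_region <- function(h, window_kb, table, null_table, step = 1000,
                        test_len = 2000, alpha_strict = 0.001,
                        rho0_grid = default_rho0_grid(),
                        rho1_grid = default_rho1_grid(),
                        const_grid = default_const_grid()) {
  stopifnot(inherits(h, "hap_matrix"), inherits(null_table, "null_table"))
  if (null_table$window_kb != window_kb)
    stop("null table was built for a different window size")
  if (null_table$n != nrow(h$alleles))
    stop("null table was built for a different sample size")
  L <- h$region_length
  if (L < window_kb * 1000 && L < test_len)
    stop("region shorter than one test window")
  half <- window_kb * 1000 / 2
  starts <- seq(0, L - test_len, by = step)
  min_m <- max(500, ceiling(1 / alpha_strict))
  rows <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    ti <- c(starts[k], starts[k] + test_len)
    center <- mean(ti)
    win <- c(max(0, center - half), min(L, center + half))
    ns <- sum(h$positions >= win[1] & h$positions < win[2])
    if (ns < 2) {
      rows[[k]] <- data.frame(test_start = ti[1], test_end = ti[2],
                              win_start = win[1], win_end = win[2],
                              S = ns, Lambda = 0,
                              rho0_hat = NA_real_, rho1_hat = NA_real_,
                              rho_hat_const = NA_real_,
                              p = 1, m_used = 0L, insufficient = TRUE)
    } else {
      tr <- lrt_statistic(h, ti, table, window = win,
                          rho0_grid = rho0_grid, rho1_grid = rho1_grid,
                          const_grid = const_grid)
      pv <- p_value(null_table, tr, min_m = min_m)
      rows[[k]] <- data.frame(test_start = ti[1], test_end = ti[2],
                              win_start = win[1], win_end = win[2],
                              S = tr$S_window, Lambda = tr$Lambda,
                              rho0_hat = tr$rho0_hat,
                              rho1_hat = tr$rho1_hat,
                              rho_hat_const = tr$rho_hat_const,
                              p = pv$p, m_used = pv$m_used,
                              insufficient = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "region_length") <- L
  attr(out, "window_kb") <- window_kb
  class(out) <- c("window_scan", "data.frame")
  out
}

#' Merge significant test windows into candidate hotspot regions
#'
#' The union of the extents of all windows with `p < alpha`, merged when
#' overlapping or abutting (windows step by 1 kb inside a 2 kb extent, so
#' abutment counts as overlap).  Idempotent.
#'
#' @param tests a [scan_region()] result.
#' @param alpha candidate significance threshold.
#' @return An [interval_set()] of candidate regions.
#' @export
merge_candidates <- function(tests, alpha = 0.01) {
  sig <- tests[tests$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) return(interval_set())
  interval_merge(data.frame(start = sig$test_start, end = sig$test_end))
}

new_call_set <- function(protocol, intervals, diagnostics) {
  structure(list(protocol = protocol, intervals = intervals,
                 diagnostics = diagnostics),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("call_set [%s]: %d hotspot call(s), %g bp total\n",
              x$protocol, nrow(x$intervals), interval_total_bp(x$intervals)))
  invisible(x)
}

# diagnostics shared by the protocols: min window p and peak profile inside
# each retained interval
call_diagnostics <- function(intervals, tests, profile) {
  if (nrow(intervals) == 0)
    return(data.frame(min_p = numeric(), peak_rho = numeric(),
                      length = numeric()))
  starts <- attr(profile, "start")
  step <- if (length(starts) > 1) starts[2] - starts[1] else 1000
  data.frame(
    min_p = vapply(seq_len(nrow(intervals)), function(i) {
      inside <- tests$test_start >= intervals$start[i] &
        tests$test_end <= intervals$end[i]
      if (!any(inside)) min(tests$p[tests$test_start < intervals$end[i] &
                                      tests$test_end > intervals$start[i]])
      else min(tests$p[inside])
    }, numeric(1)),
    peak_rho = vapply(seq_len(nrow(intervals)), function(i) {
      if (is.null(profile)) return(NA_real_)
      sel <- starts < intervals$end[i] & (starts + step) > intervals$start[i]
      if (!any(sel)) NA_real_ else max(profile[sel])
    }, numeric(1)),
    length = intervals$end - intervals$start)
}

#' Hotspot calls, size- and peak-rate-filtered protocol
#'
#' Candidate regions (window `p < alpha`, merged) are retained only if at
#' most `max_size` bp long and containing a profiled rate of at least
#' `rho_min`/kb somewhere inside.  This is the 200 kb-window protocol's
#' filtering rule.
#'
#' @param tests a [scan_region()] result.
#' @param profile a [rho_profile()] for the same region.
#' @param alpha candidate threshold.
#' @param max_size maximum retained candidate size, bp.
#' @param rho_min peak-rate threshold, \eqn{\rho}/kb.
#' @return A `call_set`.
#' @export
call_auton2012 <- function(tests, profile, alpha = 0.01, max_size = 5000,
                           rho_min = 5) {
  cand <- merge_candidates(tests, alpha)
  diag <- call_diagnostics(cand, tests, profile)
  keep <- diag$length <= max_size & !is.na(diag$peak_rho) &
    diag$peak_rho >= rho_min
  new_call_set("auton2012", cand[keep, c("start", "end"), drop = FALSE],
               diag[keep, , drop = FALSE])
}

#' Hotspot calls, strict-window protocol
#'
#' Candidate regions (window `p < alpha`, merged) are retained, at full
#' extent, iff they contain at least one test window with
#' `p < alpha_strict`.  No size or rate filter.
#'
#' @param tests a [scan_region()] result.
#' @param alpha candidate threshold.
#' @param alpha_strict retention threshold for the best window.
#' @return A `call_set`.
#' @export
call_auton2014 <- function(tests, alpha = 0.01, alpha_strict = 0.001) {
  cand <- merge_candidates(tests, alpha)
  diag <- call_diagnostics(cand, tests, profile = NULL)
  keep <- diag$min_p < alpha_strict
  new_call_set("auton2014", cand[keep, c("start", "end"), drop = FALSE],
               diag[keep, , drop = FALSE])
}

#' Hotspot calls, tile-intersection protocol
#'
#' Candidate regions (window `p < alpha`, merged) are partitioned into
#' non-overlapping 1 kb tiles anchored at coordinate 0; tiles whose
#' profiled rate is at least `rho_min`/kb are kept and adjacent kept tiles
#' are merged.
#'
#' @param tests a [scan_region()] result.
#' @param profile a [rho_profile()] for the same region.
#' @param alpha candidate threshold.
#' @param rho_min per-tile rate threshold, \eqn{\rho}/kb (5/kb for the
#'   headline background of 0.5/kb; use 10x the background rate for other
#'   backgrounds).
#' @param tile tile width, bp (matching the profile step).
#' @return A `call_set`.
#' @export
call_mlehot <- function(tests, profile, alpha = 0.01, rho_min = 5,
                        tile = 1000) {
  cand <- merge_candidates(tests, alpha)
  starts <- attr(profile, "start")
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    t0 <- floor(cand$start[i] / tile)
    t1 <- ceiling(cand$end[i] / tile) - 1
    for (tt in t0:t1) {
      j <- match(tt * tile, starts)
      if (!is.na(j) && profile[j] >= rho_min)
        kept[[length(kept) + 1]] <- c(tt * tile, (tt + 1) * tile)
    }
  }
  if (length(kept) == 0)
    return(new_call_set("mlehot", interval_set(),
                        call_diagnostics(interval_set(), tests, profile)))
  km <- do.call(rbind, kept)
  calls <- interval_merge(data.frame(start = km[, 1], end = km[, 2]))
  new_call_set("mlehot", calls, call_diagnostics(calls, tests, profile))
}
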