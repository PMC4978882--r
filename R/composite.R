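# Composite likelihood machinery: the product over all SNP pairs of
# two-locus sampling probabilities, evaluated under a constant-rate model
# or a two-rate hotspot model (background rho0 everywhere, rho1 inside a
# central test interval), with exhaustive grid maximization so that the
# likelihood-ratio statistic Lambda = 2 ln R is exactly >= 0 (the constant
# model's grid is the diagonal subset of the alternative's).

#' Two-rate hotspot model
#'
#' Background rate `rho0` applies outside `test_interval`, `rho1` inside.
#'
#' @param rho0,rho1 scaled rates, \eqn{\rho}/kb, both >= 0.
#' @param test_interval half-open bp pair `c(start, end)`.
#' @param window optional half-open analysis window; when supplied,
#'   [pair_rho()] refuses positions outside it.
#' @return An object of class `hotspot_model`.
#' @export
hotspot_model <- function(rho0, rho1, test_interval, window = NULL) {
  stopifnot(rho0 >= 0, rho1 >= 0, length(test_interval) == 2,
            test_interval[1] < test_interval[2])
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
    if (test_interval[1] < window[1] || test_interval[2] > window[2])
      stop("test_interval must lie within the analysis window")
  }
  structure(list(rho0 = rho0, rho1 = rho1,
                 test_interval = as.numeric(test_interval),
                 window = window),
            class = "hotspot_model")
}

#' Scaled recombination rate between two sites under a model
#'
#' Integrates the model's piecewise-constant rate over `[pos_i, pos_j)`:
#' the sum over segments of segment length (kb) times segment rate
#' (\eqn{\rho}/kb).
#'
#' @param model a [hotspot_model()] or [recomb_map()].
#' @param pos_i,pos_j bp positions with `pos_i <= pos_j`.
#' @return Scaled \eqn{\rho} between the sites (0 when `pos_i == pos_j`).
#' @export
pair_rho <- function(model, pos_i, pos_j) {
  if (any(pos_j < pos_i)) stop("pair_rho requires pos_i <= pos_j")
  if (inherits(model, "recomb_map")) {
    if (any(pos_i < 0) || any(pos_j > model$region_length))
      stop("positions outside the map region")
    return(map_cumrho(model, pos_j) - map_cumrho(model, pos_i))
  }
  stopifnot(inherits(model, "hotspot_model"))
  if (!is.null(model$window) &&
      (any(pos_i < model$window[1]) || any(pos_j > model$window[2])))
    stop("positions outside the analysis window")
  d_in <- pmax(0, pmin(pos_j, model$test_interval[2]) -
                    pmax(pos_i, model$test_interval[1])) / 1000
  d_out <- (pos_j - pos_i) / 1000 - d_in
  model$rho0 * d_out + model$rho1 * d_in
}

# SNP-pair summaries for a set of columns of h: canonical config column in
# the table, kb of each pair span inside/outside the test interval.
pair_summaries <- function(h, table, cols, test_interval = NULL) {
  X <- h$alleles[, cols, drop = FALSE]
  pos <- h$positions[cols]
  S <- length(pos)
  n <- nrow(X)
  M11 <- crossprod(X)
  m1 <- colSums(X)
  M10 <- outer(m1, m1, function(a, b) a) - M11 # pairs where first=1, second=0
  M01 <- outer(m1, m1, function(a, b) b) - M11
  M00 <- n - M11 - M10 - M01
  iu <- which(upper.tri(M11))
  counts <- cbind(c00 = M00[iu], c01 = M01[iu], c10 = M10[iu], c11 = M11[iu])
  storage.mode(counts) <- "integer"
  cfg_col <- config_cols(table, counts)
  pi <- pos[row(M11)[iu]]
  pj <- pos[col(M11)[iu]]
  d_tot <- (pj - pi) / 1000
  if (is.null(test_interval)) {
    d_in <- numeric(length(iu))
  } else {
    d_in <- pmax(0, pmin(pj, test_interval[2]) - pmax(pi, test_interval[1])) / 1000
  }
  list(cfg_col = cfg_col, d_in = d_in, d_out = d_tot - d_in,
       pos_i = pi, pos_j = pj)
}

#' Composite log-likelihood of a window under a model
#'
#' Sum over all unordered SNP pairs of the interpolated log two-locus
#' sampling probability at the model's inter-pair \eqn{\rho}
#' (see [pair_rho()]).
#'
#' @param h a [hap_matrix()].
#' @param model a [hotspot_model()] or [recomb_map()].
#' @param table a [build_two_locus_table()] result with matching `n`.
#' @param window optional half-open bp window restricting the SNPs used.
#' @return Numeric composite log-likelihood.
#' @export
composite_loglik <- function(h, model, table, window = NULL) {
  stopifnot(inherits(h, "hap_matrix"), inherits(table, "two_locus_table"))
  if (nrow(h$alleles) != table$n) stop("sample size does not match table n")
  cols <- seq_along(h$positions)
  if (!is.null(window))
    cols <- which(h$positions >= window[1] & h$positions < window[2])
  if (length(cols) < 2) stop("insufficient SNPs: need at least 2 in window")
  if (inherits(model, "recomb_map")) {
    ps <- pair_summaries(h, table, cols, test_interval = NULL)
    rho_pair <- pair_rho(model, ps$pos_i, ps$pos_j)
    return(cl_eval_cpp(ps$cfg_col, rho_pair, numeric(length(rho_pair)),
                       table$logp_t, table$rho_grid, 0, 1)[1])
  }
  ps <- pair_summaries(h, table, cols, model$test_interval)
  cl_eval_cpp(ps$cfg_col, ps$d_in, ps$d_out, table$logp_t, table$rho_grid,
              model$rho0, model$rho1)[1]
}

#' Default background-rate grid (rho0), per kb
#' @return Ascending numeric vector including 0.
#' @export
default_rho0_grid <- function() {
  c(0, 0.05, 0.1, 0.2, 0.35, 0.5, 0.75, 1, 1.5, 2, 3, 5)
}

#' Default hotspot-rate grid (rho1), per kb
#' @return Ascending numeric vector including 0.
#' @export
default_rho1_grid <- function() {
  c(0, 0.5, 1, 2, 3, 5, 7.5, 10, 15, 20, 30, 50, 75, 100)
}

#' Default constant-rate grid, per kb
#' @return Ascending numeric vector including 0.
#' @export
default_const_grid <- function() {
  sort(unique(c(default_rho0_grid(), 7.5, 10)))
}

#' Constant-rate composite maximum-likelihood estimate of rho
#'
#' Exhaustive grid argmax of the composite log-likelihood under a constant
#' per-kb rate; ties break toward the smaller rate.
#'
#' @param h a [hap_matrix()].
#' @param table a matching two-locus table.
#' @param rho_grid_perkb candidate rates, \eqn{\rho}/kb.
#' @param window optional half-open bp window restricting the SNPs used.
#' @return Estimated \eqn{\rho} per kb.
#' @export
estimate_rho_constant <- function(h, table,
                                  rho_grid_perkb = default_const_grid(),
                                  window = NULL) {
  stopifnot(inherits(h, "hap_matrix"), inherits(table, "two_locus_table"))
  if (nrow(h$alleles) != table$n) stop("sample size does not match table n")
  cols <- seq_along(h$positions)
  if (!is.null(window))
    cols <- which(h$positions >= window[1] & h$positions < window[2])
  if (length(cols) < 2) stop("insufficient SNPs: need at least 2 in window")
  ps <- pair_summaries(h, table, cols, test_interval = NULL)
  ll <- cl_eval_cpp(ps$cfg_col, ps$d_in, ps$d_out, table$logp_t,
                    table$rho_grid, as.numeric(rho_grid_perkb),
                    numeric(length(rho_grid_perkb)))
  rho_grid_perkb[which.max(ll)] # first max = smallest rate on ties
}

#' Composite likelihood-ratio test for a hotspot in a window
#'
#' Maximizes the composite log-likelihood over an exhaustive
#' (`rho0`, `rho1`) grid (augmented with the constant grid's diagonal) and
#' over the constant-rate grid, and returns
#' \eqn{\Lambda = 2(\max_{alt} - \max_{const}) \ge 0} together with the
#' argmax rates, the SNP count and the constant-rate estimate used for
#' null-table conditioning.
#'
#' @param h a [hap_matrix()].
#' @param test_interval half-open bp pair, the putative hotspot (typically
#'   2 kb).
#' @param table a matching two-locus table.
#' @param window half-open analysis window (default: the whole region).
#' @param rho0_grid,rho1_grid,const_grid per-kb rate grids.
#' @param keep_surface also return `rho1_profile`, the profile
#'   log-likelihood over the `rho1` grid (maximized over `rho0`).
#' @return A list of class `hotspot_test` with elements `Lambda`,
#'   `rho0_hat`, `rho1_hat`, `rho_hat_const`, `S_window`, `test_interval`,
#'   `window`, `p_value` (NA until calibrated).
#' @export
lrt_statistic <- function(h, test_interval, table, window = NULL,
                          rho0_grid = default_rho0_grid(),
                          rho1_grid = default_rho1_grid(),
                          const_grid = default_const_grid(),
                          keep_surface = FALSE) {
  stopifnot(inherits(h, "hap_matrix"), inherits(table, "two_locus_table"),
            length(test_interval) == 2, test_interval[1] < test_interval[2])
  if (nrow(h$alleles) != table$n) stop("sample size does not match table n")
  if (is.null(window)) window <- c(0, h$region_length)
  cols <- which(h$positions >= window[1] & h$positions < window[2])
  if (length(cols) < 2) stop("insufficient SNPs: need at least 2 in window")
  ps <- pair_summaries(h, table, cols, test_interval)
  cross <- expand.grid(r0 = rho0_grid, r1 = rho1_grid)
  r0 <- c(cross$r0, const_grid)
  r1 <- c(cross$r1, const_grid) # trailing block: the constant diagonal
  ll <- cl_eval_cpp(ps$cfg_col, ps$d_in, ps$d_out, table$logp_t,
                    table$rho_grid, r0, r1)
  n_alt <- nrow(cross)
  const_ll <- ll[(n_alt + 1):length(ll)]
  i_const <- which.max(const_ll)
  i_alt <- which.max(ll)
  Lambda <- 2 * (ll[i_alt] - const_ll[i_const])
  out <- structure(list(Lambda = Lambda,
                        rho0_hat = r0[i_alt], rho1_hat = r1[i_alt],
                        rho_hat_const = const_grid[i_const],
                        S_window = length(cols),
                        test_interval = as.numeric(test_interval),
                        window = as.numeric(window),
                        p_value = NA_real_),
                   class = "hotspot_test")
  if (keep_surface) {
    # profile log-likelihood over rho1 (maximized over rho0), for rate
    # estimation with support-interval parsimony
    ll_cross <- matrix(ll[seq_len(n_alt)], nrow = length(rho0_grid))
    out$rho1_profile <- data.frame(rho1 = rho1_grid,
                                   ll = apply(ll_cross, 2, max))
  }
  out
}

#' @export
print.hotspot_test <- function(x, ...) {
  cat(sprintf(
    "hotspot_test: Lambda = %.3f, rho0 = %.2f, rho1 = %.1f /kb, const rho = %.2f /kb, S = %d%s\n",
    x$Lambda, x$rho0_hat, x$rho1_hat, x$rho_hat_const, x$S_window,
    if (is.na(x$p_value)) "" else sprintf(", p = %.4g", x$p_value)))
  invisible(x)
}

#' Per-kb profile of the estimated hotspot rate
#'
#' For each 1 kb window of the region, fits the two-rate model to the 2 kb
#' test interval centered on the window (with `flank` bp of context on each
#' side, truncated at region edges) and records the estimated local rate:
#' the smallest `rho1` grid value whose profile log-likelihood (maximized
#' over `rho0`) lies within `support` log-units of the maximum.  Reporting
#' the lower end of the likelihood-support set rather than the raw argmax
#' guards against the flat-plateau pathology of Monte Carlo composite
#' likelihoods: when a window's data barely constrain the local rate the
#' surface is nearly flat over a wide range and its argmax is arbitrary,
#' while a genuinely elevated rate keeps the whole support set high.  This
#' profiled local rate stands in for an external variable-rate map estimate
#' in the \eqn{\rho \ge 5}/kb calling filters.
#'
#' @param h a [hap_matrix()] for the whole region.
#' @param table a matching two-locus table.
#' @param step profile resolution, bp.
#' @param test_len test interval length, bp.
#' @param flank context on each side of the test interval, bp.
#' @param fallback value recorded for windows whose context holds fewer
#'   than 2 SNPs (no evidence; treated as background).
#' @param support width of the likelihood-support set, log-units; the
#'   profile reports the smallest rate within `support` of the maximum
#'   (the conventional 2-unit support interval).
#' @param smooth apply a running median of 3 across adjacent windows;
#'   genuine hotspots (~2 kb) always span at least two adjacent windows, so
#'   the median suppresses isolated single-window spikes without eroding
#'   real peaks (the same reasoning behind the smoothness priors of
#'   variable-rate map estimators).
#' @inheritParams lrt_statistic
#' @return Numeric vector of length `floor(region_length / step)`, with the
#'   window starts as attribute `"start"`.
#' @export
rho_profile <- function(h, table, step = 1000, test_len = 2000, flank = 9000,
                        fallback = 0, support = 2, smooth = TRUE,
                        rho0_grid = default_rho0_grid(),
                        rho1_grid = default_rho1_grid(),
                        const_grid = default_const_grid()) {
  stopifnot(inherits(h, "hap_matrix"))
  L <- h$region_length
  if (L < test_len + 2 * flank)
    stop("region shorter than test_len + 2 * flank")
  nwin <- floor(L / step)
  out <- numeric(nwin)
  starts <- (seq_len(nwin) - 1) * step
  for (k in seq_len(nwin)) {
    center <- starts[k] + step / 2
    ti <- c(max(0, center - test_len / 2), min(L, center + test_len / 2))
    win <- c(max(0, ti[1] - flank), min(L, ti[2] + flank))
    ns <- sum(h$positions >= win[1] & h$positions < win[2])
    if (ns < 2) {
      out[k] <- fallback
    } else {
      tr <- lrt_statistic(h, ti, table, window = win,
                          rho0_grid = rho0_grid, rho1_grid = rho1_grid,
                          const_grid = const_grid, keep_surface = TRUE)
      prof <- tr$rho1_profile
      out[k] <- min(prof$rho1[prof$ll >= max(prof$ll) - support])
    }
  }
  if (smooth && nwin >= 3)
    out <- as.numeric(stats::runmed(out, 3, endrule = "keep"))
  attr(out, "start") <- starts
  out
}
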