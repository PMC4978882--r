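# Lookup-table null distribution for the composite LRT statistic: many
# constant-rate coalescent simulations of X kb windows across a broad range
# of mutation and recombination rates, each recording (Lambda, S, rho_hat).
# P-values condition on the observed segregating-site count and estimated
# background rate by selecting null records "near the actual values".

#' Build a constant-rate null lookup table
#'
#' Each record simulates an `window_kb` kb region with \eqn{(\theta, \rho)}
#' drawn uniformly from the generation grids (recombination rate constant
#' per bp), computes the LRT statistic \eqn{\Lambda} for the central
#' `test_len` interval, the number of segregating sites `S`, and the
#' constant-rate composite estimate \eqn{\hat\rho}.  Deterministic given
#' `seed`.
#'
#' @param window_kb analysis window size in kb.
#' @param n haploid sample size (must match the two-locus table).
#' @param table a [build_two_locus_table()] result.
#' @param reps number of null simulations.
#' @param seed integer root seed.
#' @param theta_grid,rho_grid per-kb generation grids for the uniform
#'   \eqn{(\theta, \rho)} mixture; the defaults cover the study settings.
#' @param test_len central test interval length, bp.
#' @param rho0_grid,rho1_grid,const_grid grids passed to [lrt_statistic()].
#' @return An object of class `null_table`.
#' @export
build_null_table <- function(window_kb, n, table, reps, seed = 1,
                             theta_grid = c(0.5, 1, 2, 5),
                             rho_grid = c(0.1, 0.2, 0.5, 1, 2.5, 5),
                             test_len = 2000,
                             rho0_grid = default_rho0_grid(),
                             rho1_grid = default_rho1_grid(),
                             const_grid = default_const_grid()) {
  stopifnot(window_kb * 1000 >= test_len, n == table$n, reps >= 1)
  L <- window_kb * 1000
  ti <- c(L / 2 - test_len / 2, L / 2 + test_len / 2)
  Lambda <- S <- rho_hat <- theta_used <- rho_used <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(derive_seed(seed, "nullpick", i))
    th <- theta_grid[sample.int(length(theta_grid), 1)]
    rh <- rho_grid[sample.int(length(rho_grid), 1)]
    params <- sim_params(n, th, L, derive_seed(seed, "nullsim", i))
    h <- simulate_haplotypes(params, recomb_map(L, rh))
    theta_used[i] <- th
    rho_used[i] <- rh
    S[i] <- n_snps(h)
    if (S[i] < 2) {
      Lambda[i] <- 0
      rho_hat[i] <- 0
    } else {
      tr <- lrt_statistic(h, ti, table, rho0_grid = rho0_grid,
                          rho1_grid = rho1_grid, const_grid = const_grid)
      Lambda[i] <- tr$Lambda
      rho_hat[i] <- tr$rho_hat_const
    }
  }
  records <- data.frame(Lambda = Lambda, S = as.integer(S),
                        rho_hat = rho_hat)
  structure(list(window_kb = window_kb, n = as.integer(n),
                 records = records,
                 theta_grid = theta_grid, rho_grid = rho_grid,
                 reps = as.integer(reps), seed = as.integer(seed),
                 test_len = test_len,
                 rho_bin_edges = rho_hat_bin_edges(rho_hat)),
            class = "null_table")
}

# decile edges of the null rho_hat distribution (duplicates collapsed:
# rho_hat lives on the estimation grid, so many records tie)
rho_hat_bin_edges <- function(rho_hat) {
  unique(quantile(rho_hat, probs = seq(0, 1, 0.1), names = FALSE, type = 1))
}

rho_bin_index <- function(nt, rho) {
  edges <- nt$rho_bin_edges
  i <- findInterval(rho, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' @export
print.null_table <- function(x, ...) {
  cat(sprintf("null_table: window %g kb, n = %d, %d records (mean Lambda %.2f)\n",
              x$window_kb, x$n, x$reps, mean(x$records$Lambda)))
  invisible(x)
}

#' Conditional lookup-table p-value for an observed test result
#'
#' Selects null records with `S` within a bin around the observed count
#' (width `max(2, 5%)` of the observed `S`) and \eqn{\hat\rho} in the same
#' decile bin of the null \eqn{\hat\rho} distribution, widening both
#' symmetrically until at least `min_m` records are in hand, and returns
#' the add-one estimate \eqn{p = (1 + \#\{\Lambda_{null} \ge
#' \Lambda_{obs}\}) / (m + 1)}, which is strictly positive and valid under
#' the simulation null.
#'
#' @param nt a [build_null_table()] result whose window size and sample
#'   size match the observation.
#' @param result a [lrt_statistic()] result (or list with `Lambda`,
#'   `S_window`, `rho_hat_const`).
#' @param min_m minimum number of conditioning records.
#' @param randomize use the randomized-rank construction
#'   \eqn{p = (\#\{\Lambda > \Lambda_{obs}\} + U(1 + \#\{\Lambda =
#'   \Lambda_{obs}\}))/(m+1)} instead.  \eqn{\Lambda} is discrete (exact
#'   grid maximization puts an atom at 0), so the deterministic
#'   tie-inclusive estimator is conservative at the atoms — harmless for
#'   hotspot calling, where only small p matter, but only the randomized
#'   variant can be exactly uniform under the null, which is what
#'   calibration checks should use.
#' @return A list with `p`, `m_used`, and the final `s_halfwidth` /
#'   `rho_bin_halfwidth` of the conditioning bin.
#' @export
p_value <- function(nt, result, min_m = 500, randomize = FALSE) {
  stopifnot(inherits(nt, "null_table"))
  if (nrow(nt$records) == 0) stop("empty null table")
  Lobs <- result$Lambda
  Sobs <- result$S_window
  robs <- result$rho_hat_const
  rec <- nt$records
  w_s <- max(2, ceiling(0.05 * Sobs))
  bin_obs <- rho_bin_index(nt, robs)
  bin_rec <- rho_bin_index(nt, rec$rho_hat)
  n_bins <- length(nt$rho_bin_edges) - 1L
  target <- min(min_m, nrow(rec))
  k <- 1L
  repeat {
    sel <- abs(rec$S - Sobs) <= k * w_s & abs(bin_rec - bin_obs) <= (k - 1L)
    if (sum(sel) >= target || k > max(20L, n_bins)) break
    k <- k + 1L
  }
  if (sum(sel) < target) sel <- rep(TRUE, nrow(rec))
  m <- sum(sel)
  if (randomize) {
    ngt <- sum(rec$Lambda[sel] > Lobs)
    neq <- sum(rec$Lambda[sel] == Lobs)
    p <- (ngt + runif(1) * (1 + neq)) / (m + 1)
  } else {
    p <- (1 + sum(rec$Lambda[sel] >= Lobs)) / (m + 1)
  }
  list(p = p, m_used = m, s_halfwidth = k * w_s, rho_bin_halfwidth = k - 1L)
}

#' Write a null table as plain text
#'
#' One JSON metadata header line followed by a TSV of records; reloading
#' with [read_null_table()] reproduces the table bit-exactly.
#'
#' @param nt a `null_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_null_table <- function(nt, path) {
  meta <- jsonlite::toJSON(list(format = "ldhotscan_null_table", version = 1L,
                                window_kb = nt$window_kb, n = nt$n,
                                theta_grid = nt$theta_grid,
                                rho_grid = nt$rho_grid, reps = nt$reps,
                                seed = nt$seed, test_len = nt$test_len),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", meta), con)
  write.table(format(nt$records, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a null table written by [write_null_table()]
#' @param path file path.
#' @return A `null_table`.
#' @export
read_null_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#meta "))
    stop("not a ldhotscan null table: missing metadata header")
  meta <- jsonlite::fromJSON(sub("^#meta ", "", first))
  if (!identical(meta$format, "ldhotscan_null_table") ||
      !identical(as.integer(meta$version), 1L))
    stop("unsupported null table format/version")
  rec <- read.table(path, sep = "\t", header = TRUE, skip = 1)
  rec$S <- as.integer(rec$S)
  structure(list(window_kb = as.numeric(meta$window_kb), n = as.integer(meta$n),
                 records = rec,
                 theta_grid = as.numeric(meta$theta_grid),
                 rho_grid = as.numeric(meta$rho_grid),
                 reps = as.integer(meta$reps), seed = as.integer(meta$seed),
                 test_len = as.numeric(meta$test_len),
                 rho_bin_edges = rho_hat_bin_edges(rec$rho_hat)),
            class = "null_table")
}
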