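# Shared Monte Carlo tables, built once per test run on first use and
# memoized.  Sizes are desk-scale: large enough for the statistical checks,
# small enough to keep the suite fast.

.shared <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.shared[[name]])) .shared[[name]] <- build()
  .shared[[name]]
}

tab30 <- function() memo("tab30", function() {
  build_two_locus_table(30, reps = 10000, seed = 101)
})

tab16 <- function() memo("tab16", function() {
  build_two_locus_table(16, reps = 5000, seed = 102)
})

# null lookup table for 20 kb windows at the headline sample size
null20_30 <- function() memo("null20_30", function() {
  build_null_table(20, 30, tab30(), reps = 8000, seed = 103,
                   theta_grid = c(0.5, 1, 2),
                   rho_grid = c(0.1, 0.2, 0.5, 1, 2.5, 5))
})

# small-sample null table for fast scan tests (10 kb windows, n = 16)
null10_16 <- function() memo("null10_16", function() {
  build_null_table(10, 16, tab16(), reps = 4000, seed = 104,
                   theta_grid = c(0.5, 1, 2),
                   rho_grid = c(0.1, 0.2, 0.5, 1, 2.5, 5))
})

# count of SNP pairs showing all four gametes
four_gamete_violations <- function(h) {
  S <- n_snps(h)
  if (S < 2) return(0L)
  X <- h$alleles
  M11 <- crossprod(X)
  m1 <- colSums(X)
  viol <- 0L
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      c11 <- M11[i, j]
      c10 <- m1[i] - c11
      c01 <- m1[j] - c11
      c00 <- nrow(X) - c11 - c10 - c01
      if (c00 > 0 && c01 > 0 && c10 > 0 && c11 > 0) viol <- viol + 1L
    }
  }
  viol
}

# fabricated window scan (for caller-protocol unit tests)
fake_scan <- function(test_start, p, region_length = 30000, test_len = 2000) {
  df <- data.frame(test_start = test_start, test_end = test_start + test_len,
                   win_start = 0, win_end = region_length,
                   S = 50L, Lambda = 1, rho0_hat = 0.5, rho1_hat = 1,
                   rho_hat_const = 0.5, p = p, m_used = 1000L,
                   insufficient = FALSE)
  attr(df, "region_length") <- region_length
  attr(df, "window_kb") <- 20
  class(df) <- c("window_scan", "data.frame")
  df
}

# profile vector helper: values per 1 kb tile starting at 0
fake_profile <- function(values, step = 1000) {
  attr(values, "start") <- (seq_along(values) - 1) * step
  values
}
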