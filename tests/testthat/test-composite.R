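sim20 <- function(seed, map = recomb_map(20000, 0.5), n = 30, theta = 1) {
  simulate_haplotypes(sim_params(n, theta, map$region_length, seed), map)
}

test_that("pair_rho integrates piecewise rates linearly", {
  m <- hotspot_model(0.5, 25, c(10000, 12000))
  expect_equal(pair_rho(m, 9000, 13000), 0.5 * 1 + 25 * 2 + 0.5 * 1)
  expect_equal(pair_rho(m, 5000, 5000), 0)
  expect_equal(pair_rho(hotspot_model(0.5, 0.5, c(0, 1)), 0, 10000), 5)
  rm <- recomb_map(20000, 0.5, data.frame(start = 10000, end = 12000, rate = 25))
  expect_equal(pair_rho(rm, 9000, 13000), 51)
  expect_error(pair_rho(rm, 9000, 25000), "outside")
  mw <- hotspot_model(0.5, 25, c(10000, 12000), window = c(5000, 15000))
  expect_error(pair_rho(mw, 4000, 13000), "outside")
})

test_that("composite log-likelihood is the sum of pair terms", {
  tab <- tab30()
  h <- sim20(41)
  cols <- which(h$positions >= 8000 & h$positions < 12500)[1:5]
  hw <- hap_matrix(h$positions[cols], h$alleles[, cols], h$region_length)
  model <- hotspot_model(0.5, 10, c(9000, 11000))
  total <- composite_loglik(hw, model, tab)
  manual <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    cfg <- pair_config(hw, i, j)
    manual <- manual + pair_loglik(tab, cfg,
                                   pair_rho(model, hw$positions[i], hw$positions[j]))
  }
  expect_equal(total, manual, tolerance = 1e-10)

  # exactly 2 SNPs: composite equals the single pair term
  h2 <- hap_matrix(hw$positions[1:2], hw$alleles[, 1:2], hw$region_length)
  expect_equal(composite_loglik(h2, model, tab),
               pair_loglik(tab, pair_config(h2, 1, 2),
                           pair_rho(model, h2$positions[1], h2$positions[2]))[1])
  # nesting: rho1 = rho0 equals the constant-rate map model
  mflat <- hotspot_model(0.8, 0.8, c(9000, 11000))
  expect_equal(composite_loglik(hw, mflat, tab),
               composite_loglik(hw, recomb_map(20000, 0.8), tab),
               tolerance = 1e-10)
  expect_error(composite_loglik(h2, model, tab, window = c(0, 1)), "insufficient")
})

test_that("constant-rate estimate equals brute-force grid enumeration", {
  tab <- tab30()
  grid <- default_const_grid()
  for (s in c(61, 62, 63)) {
    h <- sim20(s)
    est <- estimate_rho_constant(h, tab)
    brute <- vapply(grid, function(r)
      composite_loglik(h, recomb_map(20000, max(r, 0)), tab), numeric(1))
    expect_equal(est, grid[which.max(brute)])
  }
})

test_that("strong LD with no four-gamete violations drives the estimate to the grid floor", {
  hits <- vapply(1:60, function(i) {
    h <- sim20(derive_seed(15, "rho0", i), recomb_map(20000, 1e-9))
    if (n_snps(h) < 2) return(NA)
    estimate_rho_constant(h, tab30()) == 0
  }, logical(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.5)
})

test_that("the LRT is nonnegative, nested, and matches brute-force maximization", {
  tab <- tab30()
  h <- sim20(71)
  tr <- lrt_statistic(h, c(9000, 11000), tab)
  expect_gte(tr$Lambda, 0)
  expect_equal(tr$S_window, n_snps(h))

  # restricting the alternative to rho1 = rho0 forces Lambda = 0 exactly
  tr0 <- lrt_statistic(h, c(9000, 11000), tab,
                       rho0_grid = default_const_grid(),
                       rho1_grid = numeric(0))
  expect_identical(tr0$Lambda, 0)

  # brute force on a 10-SNP window over the full double grid
  cols <- seq_len(min(10, n_snps(h)))
  hw <- hap_matrix(h$positions[cols], h$alleles[, cols], h$region_length)
  ti <- c(h$positions[3] + 1, h$positions[7] + 1)
  trb <- lrt_statistic(hw, ti, tab)
  best_alt <- -Inf
  for (r0 in default_rho0_grid()) for (r1 in c(default_rho1_grid(), r0))
    best_alt <- max(best_alt,
                    composite_loglik(hw, hotspot_model(r0, r1, ti), tab))
  for (r in default_const_grid())
    best_alt <- max(best_alt, composite_loglik(hw, hotspot_model(r, r, ti), tab))
  best_const <- max(vapply(default_const_grid(), function(r)
    composite_loglik(hw, hotspot_model(r, r, ti), tab), numeric(1)))
  expect_equal(trb$Lambda, 2 * (best_alt - best_const), tolerance = 1e-9)
})

test_that("Lambda is invariant under allele relabeling and coordinate reversal", {
  tab <- tab30()
  h <- sim20(81, recomb_map(20000, 0.5,
                            data.frame(start = 9000, end = 11000, rate = 25)))
  ti <- c(9000, 11000)
  tr <- lrt_statistic(h, ti, tab)
  # flip alleles at a third of the SNPs
  al <- h$alleles
  flip <- seq(1, ncol(al), by = 3)
  al[, flip] <- 1L - al[, flip]
  hf <- hap_matrix(h$positions, al, h$region_length)
  expect_equal(lrt_statistic(hf, ti, tab)$Lambda, tr$Lambda, tolerance = 1e-9)
  # mirror the coordinate axis continuously (x -> L - x); the test interval
  # mirrors with it and every pair's in/out split is preserved exactly
  L <- h$region_length
  pos_m <- rev(L - h$positions)
  al_m <- h$alleles[, rev(seq_len(ncol(h$alleles)))]
  hm <- hap_matrix(pos_m, al_m, L + 1)
  ti_m <- c(L - ti[2], L - ti[1])
  trm <- lrt_statistic(hm, ti_m, tab, window = c(0, L + 1))
  expect_equal(trm$Lambda, tr$Lambda, tolerance = 1e-8)
})

test_that("Lambda separates simulated hotspots from the null", {
  tab <- tab30()
  null_map <- recomb_map(20000, 0.5)
  hot_map <- recomb_map(20000, 0.5,
                        data.frame(start = 9000, end = 11000, rate = 25))
  l_null <- vapply(1:100, function(i) {
    h <- sim20(derive_seed(21, "mwnull", i), null_map)
    if (n_snps(h) < 2) return(NA)
    lrt_statistic(h, c(9000, 11000), tab)$Lambda
  }, numeric(1))
  l_hot <- vapply(1:100, function(i) {
    h <- sim20(derive_seed(21, "mwhot", i), hot_map)
    if (n_snps(h) < 2) return(NA)
    lrt_statistic(h, c(9000, 11000), tab)$Lambda
  }, numeric(1))
  wt <- wilcox.test(l_hot, l_null, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("rho profiles have the right geometry and flag hotspots", {
  tab <- tab16()
  h <- simulate_haplotypes(sim_params(16, 1, 100000, 5), recomb_map(100000, 0.5))
  prof <- rho_profile(h, tab, flank = 9000)
  expect_length(prof, 100)
  expect_equal(attr(prof, "start")[1:3], c(0, 1000, 2000))

  # constant-rate data at the study sample size: few 1 kb windows reach the
  # 5/kb calling threshold
  t30 <- tab30()
  frac_high <- vapply(1:20, function(i) {
    hh <- simulate_haplotypes(sim_params(30, 1, 50000, derive_seed(33, "profnull", i)),
                              recomb_map(50000, 0.5))
    mean(rho_profile(hh, t30, flank = 9000) >= 5)
  }, numeric(1))
  expect_lt(mean(frac_high), 0.10)

  # a 100-fold hotspot lifts its own tiles above 5/kb in most replicates
  hot <- vapply(1:50, function(i) {
    m <- recomb_map(30000, 0.5, data.frame(start = 14000, end = 16000, rate = 50))
    hh <- simulate_haplotypes(sim_params(30, 1, 30000, derive_seed(33, "profhot", i)), m)
    p <- rho_profile(hh, t30, flank = 9000)
    st <- attr(p, "start")
    max(p[st >= 14000 & st < 16000]) >= 5
  }, logical(1))
  expect_gt(mean(hot), 0.5)
})
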