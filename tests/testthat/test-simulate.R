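test_that("recombination maps validate and integrate linearly", {
  m <- recomb_map(1e6, 0.5, data.frame(start = 499000, end = 501000, rate = 25))
  expect_equal(total_map_length(m), 549)
  expect_equal(total_map_length(recomb_map(1e6, 0.5)), 500)
  expect_error(recomb_map(1e6, 0.5,
                          data.frame(start = c(1000, 2000), end = c(3000, 4000),
                                     rate = c(5, 5))),
               "disjoint")
  expect_error(recomb_map(1e6, 0.5,
                          data.frame(start = 999000, end = 1000001, rate = 5)),
               "within")
  expect_error(recomb_map(1e6, 0.5,
                          data.frame(start = 1000, end = 2000, rate = -1)))
})

test_that("segregating-site counts match Watterson's expectation", {
  # E[S] = theta_total * sum_{i=1}^{n-1} 1/i, checked within 3 SE at three
  # (n, theta) settings
  settings <- list(c(n = 10, theta = 1, L = 5000),
                   c(n = 30, theta = 1, L = 5000),
                   c(n = 20, theta = 2, L = 10000))
  for (st in settings) {
    nrep <- 1000
    S <- vapply(seq_len(nrep), function(i) {
      p <- sim_params(st["n"], st["theta"], st["L"],
                      derive_seed(2024, "watterson", i * 1000 + st["n"]))
      n_snps(simulate_haplotypes(p, recomb_map(st["L"], 0.5)))
    }, numeric(1))
    expected <- st["theta"] * st["L"] / 1000 * sum(1 / seq_len(st["n"] - 1))
    se <- sd(S) / sqrt(nrep)
    expect_lt(abs(mean(S) - expected), 3 * se)
  }
})

test_that("identical seed and parameters reproduce haplotypes bit-exactly", {
  p <- sim_params(15, 1, 20000, 77)
  m <- recomb_map(20000, 0.5, data.frame(start = 9000, end = 11000, rate = 10))
  h1 <- simulate_haplotypes(p, m)
  h2 <- simulate_haplotypes(p, m)
  expect_identical(h1$positions, h2$positions)
  expect_identical(h1$alleles, h2$alleles)
  expect_identical(attr(h1, "breakpoints"), attr(h2, "breakpoints"))
})

test_that("zero recombination yields a single genealogy: no four-gamete violations", {
  for (i in 1:5) {
    h <- simulate_haplotypes(sim_params(12, 2, 10000, derive_seed(5, "fourg", i)),
                             recomb_map(10000, 0))
    expect_identical(four_gamete_violations(h), 0L)
    expect_length(attr(h, "breakpoints"), 0)
  }
})

test_that("zero segregating sites give an empty matrix, not an error", {
  h <- simulate_haplotypes(sim_params(4, 1e-8, 1000, 1), recomb_map(1000, 0.5))
  expect_identical(n_snps(h), 0L)
  expect_identical(dim(h$alleles), c(4L, 0L))
})

test_that("recombination breakpoints concentrate inside hotspots", {
  # 2 kb hotspot at 50x background: the hotspot interval should hold more
  # breakpoints than an equal-length background window in most replicates
  m <- recomb_map(20000, 0.5, data.frame(start = 9000, end = 11000, rate = 25))
  wins <- vapply(1:40, function(i) {
    h <- simulate_haplotypes(sim_params(10, 1, 20000, derive_seed(9, "bkpt", i)), m)
    b <- attr(h, "breakpoints")
    sum(b >= 9000 & b < 11000) > sum(b >= 4000 & b < 6000)
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("mean pairwise r2 decays with inter-SNP scaled rho", {
  r2_by_bin <- matrix(0, nrow = 0, ncol = 2)
  vals <- list(sum = c(0, 0, 0), n = c(0, 0, 0))
  breaks <- c(0, 4, 12, 40)
  for (i in 1:50) {
    h <- simulate_haplotypes(sim_params(20, 1, 20000, derive_seed(11, "r2", i)),
                             recomb_map(20000, 2))
    S <- n_snps(h)
    if (S < 2) next
    X <- h$alleles
    f <- colMeans(X)
    C <- crossprod(X) / nrow(X)
    D <- C - outer(f, f)
    denom <- outer(f * (1 - f), f * (1 - f))
    r2 <- D^2 / denom
    d <- abs(outer(h$positions, h$positions, "-")) / 1000 * 2 # scaled rho
    iu <- upper.tri(r2)
    bin <- cut(d[iu], breaks, labels = FALSE)
    for (b in 1:3) {
      sel <- !is.na(bin) & bin == b
      vals$sum[b] <- vals$sum[b] + sum(r2[iu][sel])
      vals$n[b] <- vals$n[b] + sum(sel)
    }
  }
  means <- vals$sum / vals$n
  expect_true(all(diff(means) < 0))
})

test_that("study regions carry the configured hotspot truth", {
  cfg <- study_config(replicates = 2, seed = 31)
  reg <- generate_study_region(cfg, 1)
  tr <- reg$truth
  expect_equal(nrow(tr), 8)
  expect_true(all(tr$end - tr$start == 2000))
  expect_equal(interval_total_bp(tr), 16000)
  expect_equal(sort(tr$fold), c(10, 10, 20, 20, 50, 50, 100, 100))
  expect_equal(sort(tr$rate), sort(tr$fold * 0.5))
  # placement: clear of edges and well separated
  expect_true(min(tr$start) >= 50000)
  expect_true(max(tr$end) <= 1e6 - 50000)
  expect_true(all(diff(tr$start) - 2000 >= cfg$min_spacing))
  # deterministic given (seed, replicate); different replicates differ
  reg2 <- generate_study_region(cfg, 1)
  expect_identical(reg$truth, reg2$truth)
  expect_identical(reg$haps$positions, reg2$haps$positions)
  reg3 <- generate_study_region(cfg, 2)
  expect_false(identical(reg$haps$positions, reg3$haps$positions))
})

test_that("study config validates intensity balance", {
  expect_error(study_config(hotspots_per_region = 6), "multiple")
  expect_error(study_config(intensities = c(0.5, 2)))
})
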