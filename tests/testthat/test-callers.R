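test_that("candidate regions merge overlapping and abutting significant windows", {
  sc <- fake_scan(test_start = c(10000, 11000, 20000, 25000),
                  p = c(0.005, 0.008, 0.5, 0.002))
  cand <- merge_candidates(sc, alpha = 0.01)
  expect_equal(cand$start, c(10000, 25000))
  expect_equal(cand$end, c(13000, 27000))
  # idempotence and the empty case
  expect_equal(interval_merge(cand), cand)
  expect_equal(nrow(merge_candidates(fake_scan(10000, 0.5))), 0)
})

test_that("the size-and-peak-filter protocol drops long or flat candidates", {
  # candidate 1: [10000,16000) = 6 kb; candidate 2: [20000,23000) = 3 kb
  sc <- fake_scan(test_start = c(10000, 11000, 12000, 13000, 14000, 20000, 21000),
                  p = c(rep(0.001, 5), 0.004, 0.004))
  prof <- fake_profile(rep(10, 30))
  cs <- call_auton2012(sc, prof)
  expect_equal(cs$intervals$start, 20000) # 6 kb candidate removed despite rho
  expect_equal(cs$intervals$end, 23000)
  expect_true(all(cs$diagnostics$length <= 5000))
  # flat profile: peak below 5/kb removes everything
  cs2 <- call_auton2012(sc, fake_profile(rep(2, 30)))
  expect_equal(nrow(cs2$intervals), 0)
  # peak 6/kb on a 3 kb candidate is retained
  prof3 <- fake_profile(c(rep(2, 21), 6, rep(2, 8)))
  cs3 <- call_auton2012(sc, prof3)
  expect_equal(nrow(cs3$intervals), 1)
})

test_that("the strict-window protocol keys on the best window p-value", {
  sc <- fake_scan(test_start = c(10000, 11000, 20000),
                  p = c(0.005, 0.005, 0.0005))
  cs <- call_auton2014(sc)
  # candidate [10000,13000) has best p = 0.005 -> rejected;
  # candidate [20000,22000) contains p = 0.0005 -> retained at full extent
  expect_equal(cs$intervals$start, 20000)
  expect_equal(cs$intervals$end, 22000)
  sc2 <- fake_scan(test_start = c(10000, 11000), p = c(0.0005, 0.009))
  cs2 <- call_auton2014(sc2)
  expect_equal(cs2$intervals$end, 13000) # full merged candidate reported
})

test_that("the tile-intersection protocol keeps exactly the high-rate tiles", {
  sc <- fake_scan(test_start = c(10000, 11000, 12000), p = rep(0.001, 3))
  # candidate [10000,14000); profile >= 5 only on tile [11000,12000)
  prof <- fake_profile(c(rep(1, 11), 8, rep(1, 18)))
  cs <- call_mlehot(sc, prof)
  expect_equal(cs$intervals$start, 11000)
  expect_equal(cs$intervals$end, 12000)
  # no tile passes: no call
  expect_equal(nrow(call_mlehot(sc, fake_profile(rep(1, 30)))$intervals), 0)
  # adjacent passing tiles merge, and calls are whole tiles inside candidates
  prof2 <- fake_profile(c(rep(1, 11), 8, 9, rep(1, 17)))
  cs2 <- call_mlehot(sc, prof2)
  expect_equal(cs2$intervals$start, 11000)
  expect_equal(cs2$intervals$end, 13000)
  expect_true(all(cs2$intervals$start %% 1000 == 0))
  # configurable threshold (10x background rule)
  cs3 <- call_mlehot(sc, prof2, rho_min = 10)
  expect_equal(nrow(cs3$intervals), 0)
})

test_that("every protocol's calls are contained in its candidate regions", {
  set.seed(1)
  p <- runif(28, 0, 0.05)
  sc <- fake_scan(test_start = seq(0, 27000, by = 1000), p = p)
  prof <- fake_profile(runif(30, 0, 12))
  cand <- merge_candidates(sc)
  for (cs in list(call_auton2012(sc, prof), call_auton2014(sc),
                  call_mlehot(sc, prof))) {
    if (nrow(cs$intervals) == 0) next
    expect_equal(interval_overlap_bp(cs$intervals, cand),
                 interval_total_bp(cs$intervals))
  }
  # protocols are deterministic functions of (tests, profile)
  expect_identical(call_mlehot(sc, prof), call_mlehot(sc, prof))
})

test_that("region scans have the right window geometry and are reproducible", {
  h <- simulate_haplotypes(sim_params(16, 1, 30000, 201), recomb_map(30000, 0.5))
  sc <- scan_region(h, 10, tab16(), null10_16())
  expect_equal(nrow(sc), (30000 - 2000) / 1000 + 1)
  expect_equal(sc$test_start, seq(0, 28000, by = 1000))
  expect_true(all(sc$p > 0 & sc$p <= 1))
  expect_true(all(sc$Lambda >= 0))
  # analysis windows truncate at region edges
  expect_equal(sc$win_start[1], 0)
  expect_equal(sc$win_end[nrow(sc)], 30000)
  sc2 <- scan_region(h, 10, tab16(), null10_16())
  expect_identical(sc, sc2)
  # mismatched tables are refused
  expect_error(scan_region(h, 20, tab16(), null10_16()), "window size")
})

test_that("null regions yield few significant windows", {
  h <- simulate_haplotypes(sim_params(16, 1, 100000, 301), recomb_map(100000, 0.5))
  sc <- scan_region(h, 10, tab16(), null10_16())
  expect_lte(mean(sc$p < 0.01), 0.10)
})
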