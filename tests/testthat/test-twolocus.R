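test_that("pair configurations are canonical and symmetry-invariant", {
  al <- cbind(rep(c(0L, 1L), each = 15), rep(c(0L, 1L), each = 15))
  h <- hap_matrix(c(10, 20), al, 100)
  cfg <- pair_config(h, 1, 2)
  # perfect LD with a 15/15 split: same canonical class as (15,0,0,15)
  key_expected <- canon_key_cpp(matrix(c(15L, 0L, 0L, 15L), nrow = 1), 30)
  key_got <- canon_key_cpp(matrix(cfg, nrow = 1), 30)
  expect_equal(key_got, key_expected)
  expect_equal(sum(cfg), 30)

  # flipping alleles at one locus leaves the canonical config unchanged
  al2 <- al
  al2[, 2] <- 1L - al2[, 2]
  h2 <- hap_matrix(c(10, 20), al2, 100)
  expect_identical(pair_config(h2, 1, 2), cfg)
  # exchanging loci too
  expect_identical(pair_config(h, 2, 1), cfg)

  # canonical form is a fixed point of re-canonicalization
  recanon <- ldhotscan:::canonicalize_counts
  expect_equal(unname(recanon(cfg, 30)), unname(cfg))

  # monomorphic columns cannot enter a hap_matrix at all
  expect_error(hap_matrix(c(1, 5), cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 1L, 0L)), 100),
               "biallelic")
  hm <- hap_matrix(c(1, 5), cbind(c(0L, 1L, 0L, 1L), c(1L, 1L, 0L, 1L)), 100)
  expect_error(pair_config(hm, 1, 1))
})

test_that("table columns are normalized and obey the four-gamete theorem at rho = 0", {
  tab <- tab30()
  cs <- colSums(tab$prob)
  expect_true(all(abs(cs - 1) < 0.01))
  four <- rowSums(tab$configs > 0) == 4
  expect_identical(sum(tab$counts[four, 1]), 0L)
  expect_gt(sum(tab$prob[four, length(tab$rho_grid)]), 0.05)
})

test_that("tables rebuild bit-exactly from the same seed and agree across seeds", {
  g <- c(0, 1, 10)
  t1 <- build_two_locus_table(6, rho_grid = g, reps = 4000, seed = 7)
  t1b <- build_two_locus_table(6, rho_grid = g, reps = 4000, seed = 7)
  expect_identical(t1$counts, t1b$counts)
  expect_identical(t1$logp, t1b$logp)

  t2 <- build_two_locus_table(6, rho_grid = g, reps = 4000, seed = 8)
  # independent builds agree within 4 combined MC standard errors wherever
  # the probability is non-negligible
  for (j in seq_along(g)) {
    p1 <- t1$prob[, j]
    p2 <- t2$prob[, j]
    sel <- p1 > 1e-3
    se <- sqrt(p1 * (1 - p1) / t1$reps + p2 * (1 - p2) / t2$reps)
    expect_true(all(abs(p1 - p2)[sel] <= 4 * se[sel] + 1e-9))
  }
})

test_that("perfect-LD configurations lose probability as rho grows", {
  tab <- tab30()
  key <- canon_key_cpp(matrix(c(15L, 0L, 0L, 15L), nrow = 1), 30)
  row <- match(key, tab$key)
  p <- tab$prob[row, ]
  expect_gt(p[1], p[length(p)])
  expect_lt(cor(seq_along(p), p, method = "kendall"), -0.5)
})

test_that("at large rho the joint configuration factorizes into marginal spectra", {
  # closed-form oracle for two independent loci, n = 4: a mutation with k
  # derived copies has probability (1/k)/H_3, and by exchangeability the
  # carrier subset is uniform among size-k subsets
  n <- 4
  tab <- build_two_locus_table(n, rho_grid = c(0, 5, 50, 500), reps = 20000,
                               seed = 12)
  subsets <- lapply(1:(2^n - 2), function(b) which(bitwAnd(b, 2^(0:(n - 1))) > 0))
  H <- sum(1 / (1:(n - 1)))
  psub <- vapply(subsets, function(s) {
    k <- length(s)
    (1 / k) / H / choose(n, k)
  }, numeric(1))
  expected <- new.env()
  for (i in seq_along(subsets)) for (j in seq_along(subsets)) {
    A <- subsets[[i]]; B <- subsets[[j]]
    c11 <- length(intersect(A, B))
    c10 <- length(setdiff(A, B))
    c01 <- length(setdiff(B, A))
    c00 <- n - c11 - c10 - c01
    key <- as.character(canon_key_cpp(matrix(c(c00, c01, c10, c11), nrow = 1), n))
    expected[[key]] <- (if (is.null(expected[[key]])) 0 else expected[[key]]) +
      psub[i] * psub[j]
  }
  got <- tab$prob[, 4]
  tv <- 0
  for (r in seq_along(tab$key)) {
    key <- as.character(tab$key[r])
    e <- if (is.null(expected[[key]])) 0 else expected[[key]]
    tv <- tv + abs(got[r] - e) / 2
  }
  expect_lt(tv, 0.03)
})

test_that("pair_loglik interpolates, clamps, and hits grid points exactly", {
  tab <- tab16()
  cfg <- c(8L, 4L, 4L, 0L)
  key <- canon_key_cpp(matrix(cfg, nrow = 1), 16)
  row <- match(key, tab$key)
  g <- tab$rho_grid
  # exactly on a grid point: the stored value
  expect_equal(pair_loglik(tab, cfg, g[5]), tab$logp[row, 5])
  # midway: between the bracketing entries
  mid <- (g[5] + g[6]) / 2
  v <- pair_loglik(tab, cfg, mid)
  expect_true(v >= min(tab$logp[row, 5:6]) && v <= max(tab$logp[row, 5:6]))
  expect_equal(v, mean(tab$logp[row, 5:6]))
  # above the grid maximum: clamped to the last column
  expect_equal(pair_loglik(tab, cfg, 10 * max(g)), tab$logp[row, length(g)])
  # n mismatch is refused
  expect_error(pair_loglik(tab, c(15L, 0L, 0L, 15L), 1), "does not match")
})

test_that("two-locus tables round-trip through their text format bit-exactly", {
  t1 <- build_two_locus_table(6, rho_grid = c(0, 1, 10), reps = 2000, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_two_locus_table(t1, f)
  t2 <- read_two_locus_table(f)
  expect_identical(t2$counts, t1$counts)
  expect_equal(t2$logp, t1$logp)
  expect_equal(t2$rho_grid, t1$rho_grid)
  expect_identical(t2$n, t1$n)
  # a corrupted header is refused
  writeLines(c("#meta {\"format\":\"other\"}", "x"), f)
  expect_error(read_two_locus_table(f), "format")
})
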