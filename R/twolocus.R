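# Monte Carlo two-locus sampling-probability tables: the probability of
# each canonical two-locus gamete-count configuration under the neutral
# coalescent with scaled recombination rate rho between the loci, in the
# theta -> 0 limit (one mutation per locus, placed proportional to branch
# length, conditioned on both loci being polymorphic).

#' Default scaled-rho grid for two-locus tables
#'
#' Dense below 10 scaled units, coarser above, maximum 500: the grid must
#' exceed the largest hotspot rate times the widest pair span analysed.
#' @return Ascending numeric vector starting at 0.
#' @export
default_rho_grid <- function() {
  c(0, 0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 7.5, 10, 15, 20, 30,
    40, 50, 75, 100, 150, 200, 300, 500)
}

# enumerate all canonical configurations with both loci polymorphic
enumerate_pair_configs <- function(n) {
  grid <- expand.grid(c01 = 0:n, c10 = 0:n, c11 = 0:n)
  grid <- grid[rowSums(grid) <= n, , drop = FALSE]
  c00 <- n - rowSums(grid)
  m <- cbind(c00 = c00, c01 = grid$c01, c10 = grid$c10, c11 = grid$c11)
  polyA <- (m[, "c10"] + m[, "c11"]) %in% 1:(n - 1)
  polyB <- (m[, "c01"] + m[, "c11"]) %in% 1:(n - 1)
  m <- m[polyA & polyB, , drop = FALSE]
  keys <- canon_key_cpp(m, n)
  keep <- !duplicated(keys)
  list(key = keys[keep],
       counts = decode_config_key(keys[keep], n))
}

decode_config_key <- function(key, n) {
  base <- n + 1
  c11 <- key %% base
  key <- (key - c11) / base
  c10 <- key %% base
  key <- (key - c10) / base
  c01 <- key %% base
  c00 <- (key - c01) / base
  cbind(c00 = c00, c01 = c01, c10 = c10, c11 = c11)
}

#' Build a Monte Carlo two-locus sampling-probability table
#'
#' For each grid value of the scaled recombination rate \eqn{\rho} between
#' two loci, simulates `reps` two-locus genealogies for `n` haplotypes and
#' tallies the canonical gamete-count configuration obtained by dropping
#' one mutation per locus (in the \eqn{\theta \to 0} limit).  Canonical
#' configurations never observed at a grid point receive a floor
#' probability of `0.5 / reps` so that a single rare pair cannot dominate a
#' whole window's composite likelihood.
#'
#' @param n haploid sample size (4 or more recommended; at most 64).
#' @param rho_grid ascending scaled-rho grid starting at 0.
#' @param reps Monte Carlo replicates per grid point.
#' @param seed integer seed; same seed reproduces the table bit-exactly.
#' @param floor_prob probability assigned to unobserved configurations
#'   (default `0.5 / reps`).
#' @return An object of class `two_locus_table`.
#' @export
build_two_locus_table <- function(n, rho_grid = default_rho_grid(),
                                  reps = 10000, seed = 1,
                                  floor_prob = NULL) {
  stopifnot(n >= 2, n <= 64, reps >= 1)
  rho_grid <- as.numeric(rho_grid)
  if (rho_grid[1] != 0 || is.unsorted(rho_grid, strictly = TRUE))
    stop("rho_grid must be strictly ascending and start at 0")
  if (is.null(floor_prob)) floor_prob <- 0.5 / reps
  uni <- enumerate_pair_configs(n)
  K <- length(uni$key)
  counts <- matrix(0L, nrow = K, ncol = length(rho_grid))
  for (g in seq_along(rho_grid)) {
    set.seed(derive_seed(seed, "twolocus", g))
    tl <- sim_two_locus_cpp(as.integer(n), rho_grid[g], as.integer(reps))
    idx <- match(tl$key, uni$key)
    if (any(is.na(idx))) stop("internal error: unenumerated configuration")
    counts[idx, g] <- tl$count
  }
  prob <- counts / reps
  logp <- log(pmax(prob, floor_prob))
  structure(list(n = as.integer(n), rho_grid = rho_grid,
                 reps = as.integer(reps), seed = as.integer(seed),
                 floor_prob = floor_prob,
                 key = uni$key, configs = uni$counts,
                 counts = counts, prob = prob,
                 logp = logp, logp_t = t(logp)),
            class = "two_locus_table")
}

#' @export
print.two_locus_table <- function(x, ...) {
  cat(sprintf(
    "two_locus_table: n = %d, %d canonical configs, %d rho grid points (0..%g), %d reps/point\n",
    x$n, length(x$key), length(x$rho_grid), max(x$rho_grid), x$reps))
  invisible(x)
}

#' Canonical two-locus gamete configuration of a SNP pair
#'
#' Counts the four gametes (00, 01, 10, 11) across haplotypes for columns
#' `i` and `j`, then canonicalizes so the result is invariant under allele
#' relabeling at either locus and under exchanging the loci.
#'
#' @param h a [hap_matrix()].
#' @param i,j distinct column indices.
#' @return Named integer vector `c(c00, c01, c10, c11)`.
#' @export
pair_config <- function(h, i, j) {
  stopifnot(inherits(h, "hap_matrix"), i != j)
  a <- h$alleles[, i]
  b <- h$alleles[, j]
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("both columns must be biallelic")
  c11 <- sum(a & b)
  c10 <- sum(a & !b)
  c01 <- sum(!a & b)
  c00 <- sum(!a & !b)
  n <- length(a)
  key <- canon_key_cpp(matrix(c(c00, c01, c10, c11), nrow = 1), n)
  cfg <- decode_config_key(key, n)[1, ]
  storage.mode(cfg) <- "integer"
  cfg
}

canonicalize_counts <- function(counts, n) {
  key <- canon_key_cpp(matrix(as.integer(counts), nrow = 1), n)
  decode_config_key(key, n)[1, ]
}

#' Log two-locus sampling probability of a configuration
#'
#' Linear interpolation of the stored log-probabilities in \eqn{\rho}
#' between bracketing grid points; rates above the grid maximum clamp to
#' the last grid column.
#'
#' @param table a [build_two_locus_table()] result.
#' @param cfg gamete counts `c(c00, c01, c10, c11)` (canonicalized
#'   internally); must sum to `table$n`.
#' @param rho scaled recombination rate(s) between the two sites.
#' @return Numeric log-probability, vectorized over `rho`.
#' @export
pair_loglik <- function(table, cfg, rho) {
  stopifnot(inherits(table, "two_locus_table"))
  if (sum(cfg) != table$n)
    stop("configuration sample size does not match table n")
  cfg <- canonicalize_counts(cfg, table$n)
  key <- canon_key_cpp(matrix(as.integer(cfg), nrow = 1), table$n)
  row <- match(key, table$key)
  if (is.na(row)) stop("configuration not biallelic at both loci")
  cl_eval_cpp(rep(row - 1L, length(rho)), numeric(length(rho)),
              rep(1, length(rho)), table$logp_t, table$rho_grid,
              as.numeric(rho), numeric(length(rho)))
}

# map pair configurations (rows of counts) to 0-based table columns
config_cols <- function(table, counts4) {
  keys <- canon_key_cpp(counts4, table$n)
  idx <- match(keys, table$key)
  if (any(is.na(idx))) stop("configuration not found in table")
  idx - 1L
}

#' Write a two-locus table as plain text
#'
#' One JSON metadata header line, then a TSV of canonical configurations
#' and integer Monte Carlo counts per grid point.  Reloading with
#' [read_two_locus_table()] reproduces the table bit-exactly.
#'
#' @param table a `two_locus_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_two_locus_table <- function(table, path) {
  meta <- jsonlite::toJSON(list(format = "ldhotscan_two_locus_table", version = 1L,
                                n = table$n, rho_grid = table$rho_grid,
                                reps = table$reps, seed = table$seed,
                                floor_prob = table$floor_prob),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", meta), con)
  df <- cbind(as.data.frame(table$configs), as.data.frame(table$counts))
  names(df) <- c("c00", "c01", "c10", "c11",
                 paste0("rho", seq_along(table$rho_grid)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-locus table written by [write_two_locus_table()]
#'
#' @param path file path.
#' @return A `two_locus_table`; refuses files whose header does not
#'   identify this format/version.
#' @export
read_two_locus_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#meta "))
    stop("not a ldhotscan two-locus table: missing metadata header")
  meta <- jsonlite::fromJSON(sub("^#meta ", "", first))
  if (!identical(meta$format, "ldhotscan_two_locus_table") ||
      !identical(as.integer(meta$version), 1L))
    stop("unsupported two-locus table format/version")
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1)
  configs <- as.matrix(df[, c("c00", "c01", "c10", "c11")])
  counts <- as.matrix(df[, -(1:4), drop = FALSE])
  dimnames(counts) <- NULL
  dimnames(configs) <- list(NULL, c("c00", "c01", "c10", "c11"))
  keys <- canon_key_cpp(configs, meta$n)
  prob <- counts / meta$reps
  logp <- log(pmax(prob, meta$floor_prob))
  structure(list(n = as.integer(meta$n), rho_grid = as.numeric(meta$rho_grid),
                 reps = as.integer(meta$reps), seed = as.integer(meta$seed),
                 floor_prob = meta$floor_prob,
                 key = keys, configs = configs,
                 counts = counts, prob = prob,
                 logp = logp, logp_t = t(logp)),
            class = "two_locus_table")
}
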