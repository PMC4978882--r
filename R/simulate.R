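# Coalescent simulation of phased haplotypes under piecewise-constant
# recombination maps, and generation of study regions with known hotspot
# truth.

#' Piecewise-constant recombination map
#'
#' A background scaled recombination rate (\eqn{\rho = 4N_e r}, per kb) over
#' `[0, region_length)` plus disjoint hotspot intervals with their own
#' rates.
#'
#' @param region_length region length in bp.
#' @param background_rate scaled background rate, \eqn{\rho}/kb.
#' @param hotspots `NULL`, or a data.frame with columns `start`, `end`
#'   (half-open bp) and `rate` (\eqn{\rho}/kb inside the interval).
#' @return An object of class `recomb_map`.
#' @examples
#' m <- recomb_map(1e6, 0.5, data.frame(start = 499000, end = 501000, rate = 25))
#' total_map_length(m) # 0.5 * 998 + 25 * 2 = 549
#' @export
recomb_map <- function(region_length, background_rate, hotspots = NULL) {
  stopifnot(region_length >= 1, background_rate >= 0)
  if (is.null(hotspots)) {
    hotspots <- data.frame(start = numeric(), end = numeric(), rate = numeric())
  }
  stopifnot(all(c("start", "end", "rate") %in% names(hotspots)))
  hotspots <- hotspots[order(hotspots$start), , drop = FALSE]
  rownames(hotspots) <- NULL
  if (nrow(hotspots) > 0) {
    if (any(hotspots$rate < 0)) stop("hotspot rates must be >= 0")
    if (any(hotspots$end <= hotspots$start)) stop("hotspot intervals must have start < end")
    if (any(hotspots$start < 0) || any(hotspots$end > region_length))
      stop("hotspot intervals must lie within [0, region_length)")
    if (nrow(hotspots) > 1 &&
        any(hotspots$start[-1] < hotspots$end[-nrow(hotspots)]))
      stop("hotspot intervals must be pairwise disjoint")
  }
  structure(list(region_length = region_length,
                 background_rate = background_rate,
                 hotspots = hotspots),
            class = "recomb_map")
}

# piece boundaries and per-bp rates for the C++ simulator and pair_rho()
map_pieces <- function(map) {
  hs <- map$hotspots
  bounds <- sort(unique(c(0, map$region_length, hs$start, hs$end)))
  rates <- rep(map$background_rate, length(bounds) - 1L)
  if (nrow(hs) > 0) {
    mids <- (head(bounds, -1) + tail(bounds, -1)) / 2
    for (i in seq_len(nrow(hs))) {
      rates[mids >= hs$start[i] & mids < hs$end[i]] <- hs$rate[i]
    }
  }
  list(bounds = bounds, rates_perkb = rates, rates_bp = rates / 1000)
}

#' Total map length of a recombination map
#'
#' The scaled recombination rate integrated over the region, in
#' \eqn{4N_e r} units.
#' @param map a [recomb_map()].
#' @return Numeric scalar.
#' @export
total_map_length <- function(map) {
  p <- map_pieces(map)
  sum(diff(p$bounds) * p$rates_bp)
}

# cumulative scaled rho at physical positions (vectorized)
map_cumrho <- function(map, pos) {
  p <- map_pieces(map)
  cum <- c(0, cumsum(diff(p$bounds) * p$rates_bp))
  i <- findInterval(pos, p$bounds, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(p$rates_bp))
  cum[i] + (pos - p$bounds[i]) * p$rates_bp[i]
}

#' Coalescent simulation parameters
#'
#' @param n haploid sample size (>= 2).
#' @param theta scaled mutation rate \eqn{\theta = 4N_e\mu} per kb.
#' @param region_length region length in bp (>= 1000).
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n, theta, region_length, seed) {
  stopifnot(n >= 2, theta > 0, region_length >= 1000)
  structure(list(n = as.integer(n), theta = theta,
                 region_length = region_length, seed = as.integer(seed)),
            class = "sim_params")
}

#' Phased haplotype matrix
#'
#' @param positions strictly increasing integer bp positions in
#'   `[0, region_length)`.
#' @param alleles n x S binary matrix, one row per haplotype.
#' @param region_length region length in bp.
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(positions, alleles, region_length) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  if (length(positions) != ncol(alleles))
    stop("positions must have one entry per column of alleles")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(positions) > 0 &&
      (min(positions) < 0 || max(positions) >= region_length))
    stop("positions must lie in [0, region_length)")
  if (any(is.na(alleles)) || !all(alleles %in% c(0L, 1L)))
    stop("alleles must be a complete 0/1 matrix")
  if (ncol(alleles) > 0) {
    cs <- colSums(alleles)
    if (any(cs == 0L) || any(cs == nrow(alleles)))
      stop("every column must be biallelic (both alleles present)")
  }
  structure(list(positions = positions, alleles = alleles,
                 region_length = region_length),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes, %d SNPs, region %g bp\n",
              nrow(x$alleles), length(x$positions), x$region_length))
  invisible(x)
}

#' Number of SNPs in a haplotype matrix
#' @param h a [hap_matrix()].
#' @return Integer SNP count.
#' @export
n_snps <- function(h) length(h$positions)

# push colliding integer positions to the next free integer (infinite-sites
# mutations are continuous; downstream code indexes integer bp)
make_unique_positions <- function(pos, region_length) {
  pos <- floor(pos)
  if (length(pos) == 0) return(integer())
  if (!anyDuplicated(pos)) return(as.integer(pos))
  out <- numeric(length(pos))
  taken <- new.env(hash = TRUE, size = length(pos) * 2L)
  for (i in seq_along(pos)) {
    p <- pos[i]
    key <- as.character(p)
    while (!is.null(taken[[key]])) {
      p <- p + 1
      key <- as.character(p)
    }
    if (p >= region_length) { # walk down instead when pushed off the end
      p <- pos[i] - 1
      key <- as.character(p)
      while (p >= 0 && !is.null(taken[[key]])) {
        p <- p - 1
        key <- as.character(p)
      }
      if (p < 0) stop("more mutations than integer positions in region")
    }
    taken[[key]] <- TRUE
    out[i] <- p
  }
  as.integer(out)
}

#' Simulate phased haplotypes under a recombination map
#'
#' Neutral constant-size coalescent with recombination; infinite-sites
#' mutations are placed on the ancestral recombination graph and reported as
#' biallelic SNPs at unique integer bp positions (collisions after rounding
#' are moved to the next free integer).  Recombination breakpoint positions
#' observed during the simulation are attached as attribute
#' `"breakpoints"`.
#'
#' @param params a [sim_params()].
#' @param map a [recomb_map()] with the same region length.
#' @return A [hap_matrix()]; zero segregating sites give a 0-column matrix.
#' @examples
#' p <- sim_params(n = 10, theta = 1, region_length = 5000, seed = 1)
#' h <- simulate_haplotypes(p, recomb_map(5000, 0.5))
#' @export
simulate_haplotypes <- function(params, map) {
  stopifnot(inherits(params, "sim_params"), inherits(map, "recomb_map"))
  if (map$region_length != params$region_length)
    stop("params and map disagree on region length")
  pieces <- map_pieces(map)
  set.seed(params$seed)
  raw <- sim_region_cpp(params$n, params$region_length, pieces$bounds,
                        pieces$rates_bp, params$theta / 1000)
  ord <- order(raw$positions)
  pos <- make_unique_positions(raw$positions[ord], params$region_length)
  al <- raw$alleles[, ord, drop = FALSE]
  reord <- order(pos) # jitter can reorder near-collisions
  h <- hap_matrix(pos[reord], al[, reord, drop = FALSE], params$region_length)
  attr(h, "breakpoints") <- raw$breakpoints
  h
}

#' Configuration for a hotspot power study
#'
#' Defaults are the headline study conditions: n = 30 haploid sequences,
#' \eqn{\theta} = 1/kb, background \eqn{\rho} = 0.5/kb, 1 Mb regions each
#' containing eight 2 kb hotspots at 10-, 20-, 50- and 100-fold the
#' background rate (two hotspots per intensity).
#'
#' @param n haploid sample size.
#' @param theta scaled mutation rate per kb.
#' @param background_rate scaled background recombination rate per kb.
#' @param hotspot_width hotspot width, bp.
#' @param intensities fold-increases over background (> 1 each).
#' @param hotspots_per_region number of hotspots per region (a multiple of
#'   `length(intensities)`; each intensity appears equally often).
#' @param region_length region length, bp.
#' @param replicates number of regions.
#' @param seed root seed; all per-replicate randomness is derived from it.
#' @param edge_margin minimum distance between a hotspot and a region edge, bp.
#' @param min_spacing minimum gap between hotspots, bp (validated).
#' @return An object of class `study_config`.
#' @export
study_config <- function(n = 30, theta = 1, background_rate = 0.5,
                         hotspot_width = 2000,
                         intensities = c(10, 20, 50, 100),
                         hotspots_per_region = 8, region_length = 1e6,
                         replicates = 100, seed = 1,
                         edge_margin = 50000, min_spacing = 10000) {
  stopifnot(n >= 2, theta > 0, background_rate > 0, hotspot_width > 0,
            all(intensities > 1), hotspots_per_region >= 1,
            replicates >= 1)
  if (hotspots_per_region %% length(intensities) != 0)
    stop("hotspots_per_region must be a multiple of length(intensities)")
  if (hotspots_per_region * hotspot_width > region_length / 5)
    stop("hotspots must cover much less than the region")
  cfg <- structure(list(n = as.integer(n), theta = theta,
                        background_rate = background_rate,
                        hotspot_width = hotspot_width,
                        intensities = intensities,
                        hotspots_per_region = as.integer(hotspots_per_region),
                        region_length = region_length,
                        replicates = as.integer(replicates),
                        seed = as.integer(seed),
                        edge_margin = edge_margin,
                        min_spacing = min_spacing),
                   class = "study_config")
  ctr <- study_hotspot_centers(cfg)
  gap <- diff(ctr) - hotspot_width
  if (length(gap) && any(gap < min_spacing))
    stop("hotspots too close together; reduce hotspots_per_region or width")
  cfg
}

# evenly spaced hotspot centers, edge_margin clear of both region edges
study_hotspot_centers <- function(cfg) {
  m <- cfg$hotspots_per_region
  interior <- cfg$region_length - 2 * cfg$edge_margin - cfg$hotspot_width
  if (interior <= 0) stop("region too short for the configured edge margin")
  cfg$edge_margin + cfg$hotspot_width / 2 +
    (seq_len(m) - 0.5) * interior / m
}

#' Generate one study region with known hotspot truth
#'
#' Hotspot centers are evenly spaced across the region interior; the
#' assignment of intensities to positions is shuffled with a seed derived
#' from the config's root seed and the replicate index, so every replicate
#' is reproducible in isolation.
#'
#' @param cfg a [study_config()].
#' @param replicate replicate index (1-based).
#' @return A list with elements `haps` (a [hap_matrix()]) and `truth` (an
#'   [interval_set()] with per-interval `fold` and `rate` columns).
#' @export
generate_study_region <- function(cfg, replicate = 1L) {
  stopifnot(inherits(cfg, "study_config"))
  centers <- study_hotspot_centers(cfg)
  folds <- rep(cfg$intensities, cfg$hotspots_per_region / length(cfg$intensities))
  set.seed(derive_seed(cfg$seed, "placement", replicate))
  folds <- sample(folds)
  truth <- interval_set(start = round(centers - cfg$hotspot_width / 2),
                        end = round(centers + cfg$hotspot_width / 2),
                        fold = folds,
                        rate = folds * cfg$background_rate)
  map <- recomb_map(cfg$region_length, cfg$background_rate,
                    data.frame(start = truth$start, end = truth$end,
                               rate = truth$rate))
  params <- sim_params(cfg$n, cfg$theta, cfg$region_length,
                       derive_seed(cfg$seed, "region", replicate))
  list(haps = simulate_haplotypes(params, map), truth = truth, map = map)
}
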