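# File formats.  All coordinates are 0-based half-open internally; VCF
# positions are converted from 1-based on read/write; BED is native.

#' Write phased haplotypes to a file
#'
#' Two formats: `"txt"` — a header line `n S region_length`, a line of
#' space-separated bp positions, then one 0/1 string per haplotype — and
#' `"vcf"` — a phased VCF with one haploid sample column per haplotype.
#'
#' @param h a [hap_matrix()].
#' @param path output path.
#' @param format `"txt"` or `"vcf"`.
#' @param chrom chromosome name used in VCF output.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(h, path, format = c("txt", "vcf"),
                             chrom = "region1") {
  stopifnot(inherits(h, "hap_matrix"))
  format <- match.arg(format)
  n <- nrow(h$alleles)
  S <- length(h$positions)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "txt") {
    writeLines(paste(n, S, h$region_length), con)
    writeLines(paste(h$positions, collapse = " "), con)
    apply(h$alleles, 1, function(r) writeLines(paste(r, collapse = ""), con))
  } else {
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=ldhotscan",
                 sprintf("##contig=<ID=%s,length=%d>", chrom,
                         as.integer(h$region_length)),
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT",
                         paste0("hap", seq_len(n))), collapse = "\t")), con)
    if (S > 0) {
      gt <- apply(h$alleles, 2, function(col) paste(col, collapse = "\t"))
      writeLines(paste(chrom, h$positions + 1L, ".", "A", "T", ".", "PASS",
                       ".", "GT", gt, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read phased haplotypes from a file
#'
#' Accepts the plain-text format written by [write_haplotypes()] or a
#' phased VCF (haploid calls, or phased diploid calls which are split into
#' two haplotypes per sample).  Monomorphic, multiallelic and
#' missing-containing sites are dropped with a message; an unphased
#' genotype is an error naming the offending record.
#'
#' @param path input path.
#' @param format `"auto"` (by extension/sniffing), `"txt"` or `"vcf"`.
#' @param region_length region length override; for VCF input the contig
#'   header length is used when available, else `max(position) + 1`.
#' @return A [hap_matrix()].
#' @export
read_haplotypes <- function(path, format = c("auto", "txt", "vcf"),
                            region_length = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "txt"
  }
  if (format == "txt") read_haplotypes_txt(path, region_length)
  else read_haplotypes_vcf(path, region_length)
}

read_haplotypes_txt <- function(path, region_length = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1 || !nzchar(lines[1])) stop("empty haplotype file")
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 3) stop("header must be 'n S region_length'")
  n <- hdr[1]; S <- hdr[2]
  L <- if (is.null(region_length)) hdr[3] else region_length
  pos <- if (S > 0) as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]]) else integer()
  if (length(pos) != S) stop("position count does not match header S")
  rows <- lines[2 + seq_len(n)]
  al <- do.call(rbind, lapply(rows, function(r) {
    v <- as.integer(strsplit(r, "")[[1]])
    if (length(v) != S) stop("haplotype row length does not match S")
    v
  }))
  if (S == 0) al <- matrix(integer(), nrow = n, ncol = 0)
  drop_bad_columns(pos, al, L)
}

read_haplotypes_vcf <- function(path, region_length = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("empty VCF: no variant records")
  pos1 <- as.integer(v@fix[, "POS"])
  alt <- v@fix[, "ALT"]
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(v@fix))
  multi <- grepl(",", alt) | is.na(alt)
  unphased <- apply(gt, 1, function(r) any(grepl("/", r, fixed = TRUE)))
  if (any(unphased & !multi)) {
    bad <- pos1[which(unphased & !multi)[1]]
    stop("unphased genotype at position ", bad, "; phased input required")
  }
  keep_site <- which(!multi)
  if (length(keep_site) < length(pos1))
    message(length(pos1) - length(keep_site), " multiallelic site(s) dropped")
  site_haps <- lapply(keep_site, function(i) {
    suppressWarnings(as.integer(unlist(strsplit(gt[i, ], "|", fixed = TRUE))))
  })
  nh <- unique(lengths(site_haps))
  if (length(nh) != 1)
    stop("inconsistent ploidy across VCF records")
  al <- do.call(cbind, site_haps) # haplotypes x sites
  L <- region_length
  if (is.null(L)) {
    m <- regmatches(v@meta, regexec("##contig=<ID=[^,>]+,length=([0-9]+)", v@meta))
    len <- unlist(lapply(m, function(x) if (length(x) == 2) x[2] else NULL))
    L <- if (length(len)) as.numeric(len[1]) else max(pos1)
  }
  drop_bad_columns(pos1[keep_site] - 1L, al, L)
}

# shared validation: drop sites with missing data or without both alleles
drop_bad_columns <- function(pos, alleles, region_length) {
  S0 <- length(pos)
  if (S0 == 0) return(hap_matrix(integer(), matrix(integer(), nrow = nrow(alleles), ncol = 0), region_length))
  ok_missing <- colSums(is.na(alleles)) == 0
  cs <- colSums(alleles, na.rm = TRUE)
  ok_biallelic <- cs > 0 & cs < nrow(alleles)
  keep <- ok_missing & ok_biallelic
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " site(s) dropped (monomorphic, multiallelic or missing)")
  ord <- order(pos[keep])
  hap_matrix(pos[keep][ord], alleles[, keep, drop = FALSE][, ord, drop = FALSE],
             region_length)
}

#' Write hotspot calls as BED
#'
#' 0-based half-open BED with columns chrom, start, end, protocol,
#' -log10(min window p), peak profiled rate.  An empty call set writes the
#' header comment only.
#'
#' @param calls a `call_set` (from [call_mlehot()] and friends).
#' @param path output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path, chrom = "region1") {
  stopifnot(inherits(calls, "call_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tprotocol\tneglog10_min_p\tpeak_rho", con)
  iv <- calls$intervals
  if (nrow(iv) > 0) {
    d <- calls$diagnostics
    writeLines(sprintf("%s\t%d\t%d\t%s\t%.4f\t%s", chrom,
                       as.integer(iv$start), as.integer(iv$end),
                       calls$protocol, -log10(d$min_p),
                       ifelse(is.na(d$peak_rho), ".",
                              sprintf("%.3f", d$peak_rho))), con)
  }
  invisible(path)
}

#' Read a BED file of hotspot calls written by [write_calls_bed()]
#' @param path input path.
#' @return An [interval_set()] (with `protocol` column when present).
#' @export
read_calls_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(interval_set())
  parts <- strsplit(lines, "\t")
  interval_set(start = as.numeric(vapply(parts, `[`, "", 2)),
               end = as.numeric(vapply(parts, `[`, "", 3)),
               protocol = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, ""))
}

#' Write an interval set (e.g. hotspot truth) as BED
#'
#' 0-based half-open; a `fold` column, when present, is written as BED
#' column 4.
#'
#' @param x an [interval_set()] (such as `generate_study_region()$truth`).
#' @param path output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(x, path, chrom = "region1") {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(x) == 0) {
    writeLines("#chrom\tstart\tend", con)
    return(invisible(path))
  }
  name <- if (!is.null(x$fold)) as.character(x$fold) else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, as.integer(x$start),
                     as.integer(x$end), name), con)
  invisible(path)
}

#' Write per-window scan statistics as TSV
#' @param tests a [scan_region()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(tests, path) {
  write.table(as.data.frame(tests), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
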