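# Candidate-region calling from thresholded genome-scan tracks, interval
# intersection, QTL overlap and length arithmetic. All coordinates are
# 1-based inclusive; length = end - start + 1.

#' Call candidate regions from an above-threshold SNP track
#'
#' Above-threshold SNPs (strictly greater than the cutoff) are clustered per
#' chromosome: consecutive above-threshold SNPs separated by at most
#' `max_gap` bp stay in one region, so runs of above-threshold SNPs whose
#' boundary SNPs are within `max_gap` are merged. A region's start/end are
#' its first/last above-threshold SNP positions; regions with fewer than
#' `min_snps` contributing SNPs are discarded.
#'
#' @param track Tibble with `chrom`, `pos` (non-decreasing within
#'   chromosome) and `value` (NA = missing).
#' @param cutoff Numeric cutoff, or a `scan_threshold` from
#'   [median_3sd_threshold()].
#' @param min_snps Minimum above-threshold SNPs per region, default 3.
#' @param max_gap Maximum bp between consecutive above-threshold SNPs of one
#'   region, default 200 kb.
#' @return Region tibble: `chrom`, `start`, `end`, `length`, `n_snps`,
#'   `cutoff`; zero rows if nothing exceeds the cutoff.
#' @export
call_regions <- function(track, cutoff, min_snps = 3, max_gap = 2e5) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(track)))
  if (inherits(cutoff, "scan_threshold")) cutoff <- cutoff$cutoff
  stopifnot(is.numeric(cutoff), length(cutoff) == 1)
  out <- list()
  for (ch in unique(track$chrom)) {
    pos <- track$pos[track$chrom == ch]
    val <- track$value[track$chrom == ch]
    if (is.unsorted(pos)) {
      stop("track must be position-sorted within chromosome", call. = FALSE)
    }
    above <- which(!is.na(val) & val > cutoff)
    if (!length(above)) next
    p <- pos[above]
    grp <- cumsum(c(1L, as.integer(diff(p) > max_gap)))
    starts <- tapply(p, grp, min)
    ends <- tapply(p, grp, max)
    nsnp <- tapply(p, grp, length)
    out[[ch]] <- tibble(chrom = ch,
                        start = as.integer(starts), end = as.integer(ends),
                        length = as.integer(ends - starts + 1),
                        n_snps = as.integer(nsnp), cutoff = cutoff)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    tibble(chrom = character(), start = integer(), end = integer(),
           length = integer(), n_snps = integer(), cutoff = numeric())
  }
  res <- res[res$n_snps >= min_snps, , drop = FALSE]
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Intersect two candidate region sets
#'
#' Per chromosome, the maximal intervals contained in some interval of `a`
#' and some interval of `b` (pairwise 1-based inclusive interval
#' intersection), computed on GenomicRanges. Commutative, associative and
#' idempotent; the output total length never exceeds either input's.
#'
#' @param a,b Region tibbles with `chrom`, `start`, `end` (sorted, disjoint
#'   within chromosome).
#' @return Region tibble: `chrom`, `start`, `end`, `length` (`n_snps` is not
#'   carried through; recount against a track if needed).
#' @export
intersect_region_sets <- function(a, b) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  gr <- GenomicRanges::intersect(.as_granges(a), .as_granges(b))
  if (length(gr) == 0) return(empty)
  res <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr),
                end = GenomicRanges::end(gr),
                length = GenomicRanges::width(gr))
  res[order(res$chrom, res$start), , drop = FALSE]
}

.as_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start, regions$end))
}

#' Overlap of candidate regions with a QTL interval
#'
#' For every region on the QTL's chromosome, the intersected span and its
#' 1-based inclusive length; regions on other chromosomes get an empty
#' overlap (with a warning if no region shares the QTL's chromosome).
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, optionally
#'   `length`).
#' @param qtl List or one-row data frame with `chrom`, `start`, `end`.
#' @return List: `overlaps` (regions plus `overlap_start`, `overlap_end`,
#'   `overlap_length`), `total_region_length` (summed full lengths of the
#'   overlapping regions), `total_overlap_length`.
#' @export
overlap_with_qtl <- function(regions, qtl) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(c("chrom", "start", "end") %in% names(qtl)))
  qchrom <- qtl$chrom[[1]]
  qs <- qtl$start[[1]]
  qe <- qtl$end[[1]]
  if (nrow(regions) && !any(regions$chrom == qchrom)) {
    warning("no region on the QTL chromosome (", qchrom, ")", call. = FALSE)
  }
  os <- pmax(regions$start, qs)
  oe <- pmin(regions$end, qe)
  hit <- regions$chrom == qchrom & os <= oe
  res <- regions
  res$overlap_start <- ifelse(hit, os, NA_integer_)
  res$overlap_end <- ifelse(hit, oe, NA_integer_)
  res$overlap_length <- ifelse(hit, oe - os + 1, NA_integer_)
  full_len <- if ("length" %in% names(regions)) regions$length else
    regions$end - regions$start + 1
  list(overlaps = res,
       total_region_length = sum(full_len[hit]),
       total_overlap_length = sum(res$overlap_length[hit]))
}

#' Length of a 1-based inclusive interval
#'
#' @param start,end Coordinates (vectors), `start <= end`.
#' @return `end - start + 1` in bp.
#' @export
#' @examples
#' interval_length(17130008, 41839226)  # 24709219, about 24.7 Mb
#' interval_length(5, 5)                # 1
interval_length <- function(start, end) {
  if (any(start > end)) stop("interval start exceeds end", call. = FALSE)
  end - start + 1
}

#' Export regions as BED (0-based half-open)
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, 1-based inclusive).
#' @param path Optional output path; written tab-separated without header.
#' @return Tibble with BED columns `chrom`, `start` (0-based), `end`, `name`.
#' @export
regions_to_bed <- function(regions, path = NULL) {
  bed <- tibble(chrom = regions$chrom,
                start = regions$start - 1L,
                end = regions$end,
                name = paste0(regions$chrom, ":", regions$start, "-",
                              regions$end))
  if (!is.null(path)) {
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(bed)
}

#' Count track SNPs falling inside each region
#'
#' @param regions Region tibble.
#' @param track Tibble with `chrom`, `pos`.
#' @return `regions` with an `n_snps` column (recomputed).
#' @export
recount_region_snps <- function(regions, track) {
  n <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    n[i] <- sum(track$chrom == regions$chrom[i] &
                  track$pos >= regions$start[i] &
                  track$pos <= regions$end[i])
  }
  regions$n_snps <- n
  regions
}

#' Full BSA scan: statistics, thresholds, regions and their intersection
#'
#' The end-to-end analysis on one set of pool counts: per-SNP statistics,
#' median+3SD thresholds for |delta(SNP-index)| and ED^4, candidate regions
#' per statistic, and their intersection (the common candidate set).
#'
#' @param counts Pool-counts tibble.
#' @param min_depth See [compute_bsa_stats()].
#' @param min_snps,max_gap See [call_regions()].
#' @param per_chromosome Per-chromosome thresholds instead of genome-wide.
#' @return List of class `bsa_scan`: `stats`, `thresholds`, `regions_delta`,
#'   `regions_ed4`, `regions_common`.
#' @export
bsa_scan <- function(counts, min_depth = 4, min_snps = 3, max_gap = 2e5,
                     per_chromosome = FALSE) {
  stats <- compute_bsa_stats(counts, min_depth)
  ths <- bsa_thresholds(stats, per_chromosome)
  call_one <- function(statistic, values) {
    th <- ths[ths$statistic == statistic, , drop = FALSE]
    if (!per_chromosome) {
      call_regions(tibble(chrom = stats$chrom, pos = stats$pos,
                          value = values),
                   th$cutoff[[1]], min_snps, max_gap)
    } else {
      parts <- lapply(unique(stats$chrom), function(ch) {
        sel <- stats$chrom == ch
        call_regions(tibble(chrom = stats$chrom[sel], pos = stats$pos[sel],
                            value = values[sel]),
                     th$cutoff[th$chrom == ch], min_snps, max_gap)
      })
      do.call(rbind, parts)
    }
  }
  rd <- call_one("abs_delta_snp_index", abs(stats$delta_snp_index))
  re <- call_one("ed4", stats$ed4)
  structure(list(stats = stats, thresholds = ths,
                 regions_delta = rd, regions_ed4 = re,
                 regions_common = intersect_region_sets(rd, re)),
            class = "bsa_scan")
}
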