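# Per-SNP bulk-segregant statistics and the median+3SD genome-scan threshold.
#
# Notation: at a SNP, M is the pooled sequencing depth of the maternal
# (JF914-type) allele and P that of the paternal (JF173-type) allele, per
# pool. SNP-index(high) = M_high / (M_high + P_high), likewise for the low
# pool, and delta(SNP-index) = SNP-index(low) - SNP-index(high). The
# Euclidean distance is taken between the two pools' four-base frequency
# vectors and raised to the fourth power (ED^4) to suppress background.

#' SNP-index of one pool
#'
#' `M / (M + P)`, the fraction of parental-allele reads supporting the
#' maternal allele; missing when the informative depth `M + P` is below
#' `min_depth`.
#'
#' @param M,P Non-negative allele depths (vectors).
#' @param min_depth Minimum informative depth, default 4.
#' @return Values in `[0, 1]`, `NA` below `min_depth`.
#' @export
#' @examples
#' snp_index(7, 3)        # 0.7
#' snp_index(0, 12)       # 0
#' snp_index(1, 2)        # NA: depth 3 < 4
snp_index <- function(M, P, min_depth = 4) {
  if (any(M < 0, na.rm = TRUE) || any(P < 0, na.rm = TRUE)) {
    stop("negative allele depth", call. = FALSE)
  }
  tot <- M + P
  ifelse(!is.na(tot) & tot >= min_depth, M / tot, NA_real_)
}

#' Delta SNP-index
#'
#' `SNP-index(low) - SNP-index(high)`, exactly in that orientation; missing
#' if either index is.
#'
#' @param idx_low,idx_high SNP-index values of the low and high pools.
#' @return Values in `[-1, 1]`.
#' @export
delta_snp_index <- function(idx_low, idx_high) {
  idx_low - idx_high
}

#' Four-base Euclidean distance between two pools
#'
#' \deqn{ED = \sqrt{(A_h-A_l)^2 + (T_h-T_l)^2 + (C_h-C_l)^2 + (G_h-G_l)^2}}
#' over the base frequency vectors of the high and low pools; bounded by
#' \eqn{\sqrt 2}.
#'
#' @param freq_high,freq_low Numeric length-4 vectors (or n x 4 matrices) of
#'   base frequencies summing to 1 per pool.
#' @return ED in `[0, sqrt(2)]`.
#' @export
#' @examples
#' euclidean_distance(c(1, 0, 0, 0), c(0, 1, 0, 0))  # sqrt(2)
euclidean_distance <- function(freq_high, freq_low) {
  if (is.null(dim(freq_high))) freq_high <- matrix(freq_high, nrow = 1)
  if (is.null(dim(freq_low))) freq_low <- matrix(freq_low, nrow = 1)
  stopifnot(ncol(freq_high) == 4, ncol(freq_low) == 4,
            nrow(freq_high) == nrow(freq_low))
  ed <- sqrt(rowSums((freq_high - freq_low)^2))
  if (length(ed) == 1) ed[[1]] else ed
}

#' Fourth power of the Euclidean distance
#'
#' Monotone sharpening that suppresses background noise while preserving the
#' ranking of SNPs; bounded by 4.
#'
#' @param ed Non-negative ED values.
#' @return `ed^4`.
#' @export
ed_power <- function(ed) {
  if (any(ed < 0, na.rm = TRUE)) stop("ED must be non-negative", call. = FALSE)
  ed^4
}

#' Median + 3 SD threshold of a genome-scan statistic
#'
#' The scan cutoff is the genome-wide median plus three standard deviations
#' of the non-missing per-SNP values; SD is the sample (n-1) standard
#' deviation by default.
#'
#' @param values Numeric vector of per-SNP statistic values (NA = missing).
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return List of class `scan_threshold`: `median`, `sd`, `cutoff`, `n`.
#' @export
#' @examples
#' median_3sd_threshold(c(0, 0, 0, 0, 10))$cutoff  # about 13.416
median_3sd_threshold <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- values[!is.na(values)]
  if (length(x) < 2) {
    stop("need at least 2 non-missing values for a threshold", call. = FALSE)
  }
  s <- sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  structure(list(median = median(x), sd = s,
                 cutoff = median(x) + 3 * s, n = length(x)),
            class = "scan_threshold")
}

#' Compute all per-SNP BSA statistics from pool allele counts
#'
#' Adds to each SNP: per-pool total depths, SNP-index of both pools (from the
#' ref/alt = maternal/paternal allele depths), delta SNP-index, ED over the
#' four-base frequency vectors, and ED^4. A pool's frequencies are its base
#' depths divided by its total depth; statistics are missing below
#' `min_depth` (SNP-index on the informative depth M+P, ED on the total
#' depth).
#'
#' @param counts Pool-counts tibble (see [simulate_pool_counts()] /
#'   [read_pool_counts()]).
#' @param min_depth Minimum depth per pool, default 4.
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `dp_high`, `dp_low`,
#'   `snp_index_high`, `snp_index_low`, `delta_snp_index`, `ed`, `ed4`.
#' @export
compute_bsa_stats <- function(counts, min_depth = 4) {
  .check_counts(counts)
  bases <- c("A", "C", "G", "T")
  n <- nrow(counts)
  hm <- as.matrix(counts[, paste0("high_", bases)])
  lm_ <- as.matrix(counts[, paste0("low_", bases)])
  ri <- match(counts$ref, bases)
  ai <- match(counts$alt, bases)
  sel <- cbind(seq_len(n), ri)
  sel_a <- cbind(seq_len(n), ai)

  dp_h <- rowSums(hm)
  dp_l <- rowSums(lm_)
  idx_h <- snp_index(hm[sel], hm[sel_a], min_depth)
  idx_l <- snp_index(lm_[sel], lm_[sel_a], min_depth)

  fh <- hm / dp_h
  fl <- lm_ / dp_l
  ed <- sqrt(rowSums((fh - fl)^2))
  ed[dp_h < min_depth | dp_l < min_depth] <- NA_real_

  tibble(chrom = counts$chrom, pos = counts$pos,
         ref = counts$ref, alt = counts$alt,
         dp_high = dp_h, dp_low = dp_l,
         snp_index_high = idx_h, snp_index_low = idx_l,
         delta_snp_index = delta_snp_index(idx_l, idx_h),
         ed = ed, ed4 = ed^4)
}

#' Median+3SD thresholds for the delta and ED^4 tracks
#'
#' The delta track is thresholded on `|delta(SNP-index)|` so enrichment in
#' either direction is detected; the ED^4 track on its raw values. Genome
#' wide by default, optionally per chromosome.
#'
#' @param stats Output of [compute_bsa_stats()].
#' @param per_chromosome Compute separate thresholds per chromosome.
#' @param sd_type See [median_3sd_threshold()].
#' @return Tibble: `chrom` (`"*"` for genome-wide), `statistic`
#'   (`"abs_delta_snp_index"`, `"ed4"`), `median`, `sd`, `cutoff`, `n`.
#' @export
bsa_thresholds <- function(stats, per_chromosome = FALSE,
                           sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  groups <- if (per_chromosome) split(stats, stats$chrom) else list("*" = stats)
  rows <- lapply(names(groups), function(g) {
    s <- groups[[g]]
    th_d <- median_3sd_threshold(abs(s$delta_snp_index), sd_type)
    th_e <- median_3sd_threshold(s$ed4, sd_type)
    tibble(chrom = g,
           statistic = c("abs_delta_snp_index", "ed4"),
           median = c(th_d$median, th_e$median),
           sd = c(th_d$sd, th_e$sd),
           cutoff = c(th_d$cutoff, th_e$cutoff),
           n = c(th_d$n, th_e$n))
  })
  do.call(rbind, rows)
}
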