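#' Configuration of a synthetic bi-parental cross
#'
#' Bundles the full specification of a simulated cross: genome layout, map
#' length, marker density, population design, causal-locus effects, the
#' phenotype model, tail-bulk sizes and the pooled sequencing depth model.
#' Defaults mirror the JF914 x JF173 NFFB mapping design: a BC1F2 population
#' of 561 plants, 30-plant high/low tail bulks, and ~32x pooled depth per
#' SNP per pool.
#'
#' The phenotype model is linear:
#' \deqn{y = \mu + \sum_l a_l (d_l - 1) + \delta_l [d_l = 1] + \epsilon,
#'   \quad \epsilon \sim N(0, \sigma^2)}
#' where \eqn{d_l \in \{0,1,2\}} is the dosage of the maternal (JF914-type)
#' allele at causal locus \eqn{l}, \eqn{a_l} its additive effect and
#' \eqn{\delta_l} its dominance effect, both in trait units (nodes for NFFB).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Physical length of every chromosome, bp.
#' @param chrom_length_cM Map length of every chromosome, centimorgans.
#' @param n_markers_per_chrom Number of evenly spaced SNP markers per
#'   chromosome (causal positions are added as markers if absent).
#' @param population_type `"BC1F2"` or `"F2"`. BC1 founders are modeled as
#'   fully heterozygous at all segregating markers, so both designs segregate
#'   1:2:1 at unselected markers; see `segregating_regions`.
#' @param n_plants Plants in the segregating population.
#' @param causal_loci Data frame with columns `chrom`, `pos`, `additive`,
#'   `dominance` (trait units), or `NULL` for a null genome.
#' @param trait_baseline Trait value of the dosage-1 genotype at all loci.
#' @param residual_sd Residual (environmental) standard deviation, trait units.
#' @param bulk_size Plants per tail bulk.
#' @param mean_depth Mean pooled sequencing depth per SNP per pool
#'   (Poisson model).
#' @param base_error_rate Per-read probability that a read reports a uniformly
#'   random other base.
#' @param segregating_regions Optional data frame `chrom`, `start`, `end`
#'   restricting which markers segregate (markers outside are fixed for the
#'   maternal allele in every plant, emulating a BC1 founder homozygous
#'   elsewhere). `NULL` (default) means all markers segregate.
#' @param seed Integer seed; `simulate_population()` seeds the RNG with it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [reference_sim_config()], [simulate_population()]
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, n_markers_per_chrom = 50,
#'                   n_plants = 100, bulk_size = 10, seed = 1)
#' cfg$population_type
sim_config <- function(n_chromosomes = 3,
                       chrom_length_bp = 1e8,
                       chrom_length_cM = 160,
                       n_markers_per_chrom = 2000,
                       population_type = c("BC1F2", "F2"),
                       n_plants = 561,
                       causal_loci = data.frame(chrom = "chr1", pos = 9e7,
                                                additive = 1, dominance = 0),
                       trait_baseline = 6.5,
                       residual_sd = 0.5,
                       bulk_size = 30,
                       mean_depth = 32,
                       base_error_rate = 0.001,
                       segregating_regions = NULL,
                       seed = NULL) {
  population_type <- match.arg(population_type)
  if (is.null(causal_loci) || nrow(causal_loci) == 0) {
    causal_loci <- data.frame(chrom = character(), pos = numeric(),
                              additive = numeric(), dominance = numeric())
  }
  stopifnot(
    n_chromosomes >= 1, chrom_length_bp >= 1, chrom_length_cM > 0,
    n_markers_per_chrom >= 1, n_plants >= 2,
    is.data.frame(causal_loci),
    all(c("chrom", "pos", "additive", "dominance") %in% names(causal_loci)),
    residual_sd >= 0, mean_depth > 0,
    base_error_rate >= 0, base_error_rate < 1,
    bulk_size >= 1
  )
  if (n_plants < 2 * bulk_size) {
    stop("n_plants must be at least 2 * bulk_size", call. = FALSE)
  }
  chroms <- paste0("chr", seq_len(n_chromosomes))
  if (nrow(causal_loci)) {
    if (!all(causal_loci$chrom %in% chroms)) {
      stop("causal locus on unknown chromosome (use chr1..chrN)", call. = FALSE)
    }
    if (any(causal_loci$pos < 1 | causal_loci$pos > chrom_length_bp)) {
      stop("causal locus position outside chromosome", call. = FALSE)
    }
  }
  if (!is.null(segregating_regions)) {
    stopifnot(is.data.frame(segregating_regions),
              all(c("chrom", "start", "end") %in% names(segregating_regions)))
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    chrom_length_cM = chrom_length_cM,
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    population_type = population_type,
    n_plants = as.integer(n_plants),
    causal_loci = causal_loci,
    trait_baseline = trait_baseline,
    residual_sd = residual_sd,
    bulk_size = as.integer(bulk_size),
    mean_depth = mean_depth,
    base_error_rate = base_error_rate,
    segregating_regions = segregating_regions,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' Reference simulation settings for calibration and recovery studies
#'
#' The package's fixed calibration conditions: a BC1F2 of 561 plants with
#' 30/30 tail bulks, pooled depth 30x, three 100 Mb / 160 cM chromosomes with
#' 2000 markers each, and (unless `causal = FALSE`) one telomere-proximal
#' major locus at chr1:90,000,000 with additive effect 1.0 node and no
#' dominance (1.15 trait SD). These are the settings at which the end-to-end
#' parameter-recovery property is assessed.
#'
#' @param seed Integer seed.
#' @param causal If `FALSE`, no causal locus (null genome).
#' @return A [sim_config()] object.
#' @export
reference_sim_config <- function(seed = NULL, causal = TRUE) {
  sim_config(
    n_chromosomes = 3, chrom_length_bp = 1e8, chrom_length_cM = 160,
    n_markers_per_chrom = 2000, population_type = "BC1F2", n_plants = 561,
    causal_loci = if (causal) {
      data.frame(chrom = "chr1", pos = 9e7, additive = 1, dominance = 0)
    } else NULL,
    trait_baseline = 6.5, residual_sd = 0.5, bulk_size = 30,
    mean_depth = 30, base_error_rate = 0.001, seed = seed
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s: %d plants, %d chrom x %d markers, bulks %d/%d, depth %.3gx\n",
              x$population_type, x$n_plants, x$n_chromosomes,
              x$n_markers_per_chrom, x$bulk_size, x$bulk_size, x$mean_depth))
  if (nrow(x$causal_loci)) {
    cat(sprintf("  causal: %s\n", paste(
      sprintf("%s:%d (a=%.3g, d=%.3g)", x$causal_loci$chrom,
              as.integer(x$causal_loci$pos), x$causal_loci$additive,
              x$causal_loci$dominance), collapse = ", ")))
  } else cat("  causal: none (null genome)\n")
  invisible(x)
}
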