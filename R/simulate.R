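# Cross simulation: meiosis under a Haldane map (no interference), tail-bulk
# selection, and pooled read-count emission.

#' Simulate a segregating bi-parental population
#'
#' Generates per-plant genotypes at every marker and the resulting phenotypes.
#' Meiosis follows a Haldane map function: along each chromosome a gamete's
#' parental origin switches between adjacent markers with probability
#' \eqn{r = (1 - e^{-2d})/2}, where \eqn{d} is the inter-marker distance in
#' Morgans. F2 plants receive two independent gametes from a fully
#' heterozygous F1; BC1F2 plants likewise from fully heterozygous selfed BC1
#' founders, so unselected markers segregate 1:2:1 in both designs. Genotypes
#' are stored as dosage of the maternal (JF914-type) allele: 2 = AA, 1 = Aa,
#' 0 = aa.
#'
#' @param config A [sim_config()]. If `config$seed` is set, the RNG is seeded
#'   so that all downstream draws are reproducible.
#' @return An object of class `bsa_population`: a list with `config`,
#'   `markers` (tibble: `id`, `chrom`, `pos`, `cM`, `ref`, `alt`,
#'   `segregating`, `causal`), `genotypes` (integer dosage matrix, plants x
#'   markers), and `phenotypes` (tibble: `plant_id`, `nffb`).
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_chromosomes = 1,
#'   n_markers_per_chrom = 20, n_plants = 50, bulk_size = 5,
#'   causal_loci = NULL, seed = 7))
#' dim(pop$genotypes)
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  bases <- c("A", "C", "G", "T")
  mk <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    L <- config$chrom_length_bp
    n <- config$n_markers_per_chrom
    spacing <- L / n
    pos <- round(spacing * (seq_len(n) - 0.5))
    pos <- pmin(pmax(pos, 1), L)
    causal_here <- config$causal_loci$pos[config$causal_loci$chrom == chroms[ci]]
    pos <- sort(unique(c(pos, round(causal_here))))
    mk[[ci]] <- tibble(
      chrom = chroms[ci],
      pos = as.integer(pos),
      causal = pos %in% round(causal_here)
    )
  }
  markers <- do.call(rbind, mk)
  markers$cM <- markers$pos / config$chrom_length_bp * config$chrom_length_cM
  markers$id <- paste0(markers$chrom, "_", markers$pos)
  ref_idx <- sample.int(4L, nrow(markers), replace = TRUE)
  alt_idx <- ((ref_idx - 1L + sample.int(3L, nrow(markers), replace = TRUE)) %% 4L) + 1L
  markers$ref <- bases[ref_idx]
  markers$alt <- bases[alt_idx]

  markers$segregating <- TRUE
  sr <- config$segregating_regions
  if (!is.null(sr)) {
    seg <- rep(FALSE, nrow(markers))
    for (i in seq_len(nrow(sr))) {
      seg <- seg | (markers$chrom == sr$chrom[i] &
                      markers$pos >= sr$start[i] & markers$pos <= sr$end[i])
    }
    markers$segregating <- seg
  }

  n_pl <- config$n_plants
  geno <- matrix(2L, nrow = n_pl, ncol = nrow(markers))
  for (ci in seq_along(chroms)) {
    on_chr <- which(markers$chrom == chroms[ci])
    seg <- on_chr[markers$segregating[on_chr]]
    if (!length(seg)) next
    cm <- markers$cM[seg]
    geno[, seg] <- .sim_gametes(n_pl, cm) + .sim_gametes(n_pl, cm)
  }
  dimnames(geno) <- list(sprintf("P%04d", seq_len(n_pl)), markers$id)

  eff <- rep(0, n_pl)
  cl <- config$causal_loci
  for (i in seq_len(nrow(cl))) {
    j <- which(markers$chrom == cl$chrom[i] & markers$pos == round(cl$pos[i]))
    d <- geno[, j[1]]
    eff <- eff + cl$additive[i] * (d - 1) + cl$dominance[i] * (d == 1L)
  }
  nffb <- config$trait_baseline + eff + rnorm(n_pl, 0, config$residual_sd)

  structure(list(
    config = config,
    markers = markers[, c("id", "chrom", "pos", "cM", "ref", "alt",
                          "segregating", "causal")],
    genotypes = geno,
    phenotypes = tibble(plant_id = rownames(geno), nffb = nffb)
  ), class = "bsa_population")
}

# One gamete per row from a fully heterozygous parent; two-state Markov chain
# equivalent to a Poisson crossover process (Haldane, no interference).
# Returns 0/1 matrix: 1 = maternal allele carried at that marker.
.sim_gametes <- function(n, cM) {
  m <- length(cM)
  g <- matrix(0L, nrow = n, ncol = m)
  g[, 1] <- rbinom(n, 1L, 0.5)
  if (m == 1L) return(g)
  r <- 0.5 * (1 - exp(-2 * diff(cM) / 100))
  for (j in 2:m) {
    sw <- runif(n) < r[j - 1L]
    g[, j] <- as.integer((g[, j - 1L] + sw) %% 2L)
  }
  g
}

#' Select high and low phenotype tail bulks
#'
#' Plants are stable-sorted by (phenotype, plant id); the low bulk takes the
#' first `bulk_size` plants, the high bulk the last `bulk_size`, so the two
#' bulks are disjoint even under complete ties.
#'
#' @param pop A `bsa_population`.
#' @param bulk_size Plants per tail (defaults to the config's).
#' @return An object of class `bulk_assignment`: list with `high_ids`,
#'   `low_ids`, `bulk_size`.
#' @export
select_bulks <- function(pop, bulk_size = pop$config$bulk_size) {
  stopifnot(inherits(pop, "bsa_population"))
  n <- nrow(pop$phenotypes)
  if (2 * bulk_size > n) {
    stop("2 * bulk_size exceeds the number of plants", call. = FALSE)
  }
  ord <- order(pop$phenotypes$nffb)  # stable: ties broken by plant order
  ids <- pop$phenotypes$plant_id
  structure(list(
    high_ids = ids[ord[(n - bulk_size + 1):n]],
    low_ids = ids[ord[seq_len(bulk_size)]],
    bulk_size = as.integer(bulk_size)
  ), class = "bulk_assignment")
}

#' Simulate pooled sequencing counts for the two bulks
#'
#' For each SNP and pool, total depth is Poisson with the configured mean;
#' reads supporting the maternal (ref) allele are binomial in the bulk's true
#' allele frequency (mean dosage / 2 over the bulk's plants); each read then
#' reports a uniformly random other base with probability `base_error_rate`.
#' Zero-depth SNPs are legal and become missing downstream.
#'
#' @param pop A `bsa_population`.
#' @param bulks A `bulk_assignment` from [select_bulks()].
#' @param config Simulation config (defaults to the population's).
#' @return A tibble of per-SNP pool allele counts: `chrom`, `pos`, `ref`,
#'   `alt`, and four-base depths `high_A` ... `high_T`, `low_A` ... `low_T`.
#'   The maternal-allele depth M is the `ref` base's count, the paternal P
#'   the `alt` base's count.
#' @export
simulate_pool_counts <- function(pop, bulks, config = pop$config) {
  stopifnot(inherits(pop, "bsa_population"), inherits(bulks, "bulk_assignment"))
  bases <- c("A", "C", "G", "T")
  mk <- pop$markers
  m <- nrow(mk)
  ref_idx <- match(mk$ref, bases)
  alt_idx <- match(mk$alt, bases)
  out <- tibble(chrom = mk$chrom, pos = mk$pos, ref = mk$ref, alt = mk$alt)
  for (pool in c("high", "low")) {
    ids <- if (pool == "high") bulks$high_ids else bulks$low_ids
    freq <- colSums(pop$genotypes[ids, , drop = FALSE]) / (2 * length(ids))
    depth <- rpois(m, config$mean_depth)
    m_reads <- rbinom(m, depth, freq)
    p_reads <- depth - m_reads
    e <- config$base_error_rate
    cnt <- matrix(0L, nrow = m, ncol = 4L)
    if (e > 0) {
      err_m <- rbinom(m, m_reads, e)
      err_p <- rbinom(m, p_reads, e)
      m_reads <- m_reads - err_m
      p_reads <- p_reads - err_p
      for (i in which(err_m + err_p > 0L)) {
        if (err_m[i] > 0L) {
          to <- setdiff(1:4, ref_idx[i])
          cnt[i, to] <- cnt[i, to] + as.integer(rmultinom(1, err_m[i], rep(1, 3)))
        }
        if (err_p[i] > 0L) {
          to <- setdiff(1:4, alt_idx[i])
          cnt[i, to] <- cnt[i, to] + as.integer(rmultinom(1, err_p[i], rep(1, 3)))
        }
      }
    }
    cnt[cbind(seq_len(m), ref_idx)] <- cnt[cbind(seq_len(m), ref_idx)] + m_reads
    cnt[cbind(seq_len(m), alt_idx)] <- cnt[cbind(seq_len(m), alt_idx)] + p_reads
    colnames(cnt) <- paste0(pool, "_", bases)
    out <- cbind(out, as_tibble(cnt))
  }
  as_tibble(out)
}

#' Simulate a full cross end-to-end
#'
#' Convenience wrapper: population, tail bulks and pooled counts from one
#' seeded config. Bit-reproducible given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `population`, `bulks`, `counts`.
#' @export
simulate_cross <- function(config) {
  pop <- simulate_population(config)
  bulks <- select_bulks(pop)
  counts <- simulate_pool_counts(pop, bulks)
  list(population = pop, bulks = bulks, counts = counts)
}
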