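# Cross simulator: segregation ratios, phenotype model, bulk selection,
# pooled counts, determinism.

small_cfg <- function(..., causal_loci = data.frame(
                        chrom = "chr1", pos = 5e6, additive = 1,
                        dominance = 0)) {
  sim_config(n_chromosomes = 1, chrom_length_bp = 1e7, chrom_length_cM = 50,
             n_markers_per_chrom = 11, bulk_size = 5,
             causal_loci = causal_loci, ...)
}

test_that("noise-free null genome gives constant phenotypes at baseline", {
  pop <- simulate_population(small_cfg(n_plants = 40, causal_loci = NULL,
                                       residual_sd = 0, seed = 3))
  expect_equal(pop$phenotypes$nffb, rep(6.5, 40))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_plants = 50, bulk_size = 30), "bulk_size")
  expect_error(sim_config(causal_loci = data.frame(
    chrom = "chr9", pos = 1e6, additive = 1, dominance = 0)), "chromosome")
  expect_error(sim_config(causal_loci = data.frame(
    chrom = "chr1", pos = 2e9, additive = 1, dominance = 0)), "outside")
  expect_error(sim_config(mean_depth = 0))
  expect_error(sim_config(residual_sd = -1))
  expect_error(sim_config(population_type = "RIL"))
})

test_that("F2 and BC1F2 genotype frequencies converge to 1:2:1", {
  # Oracle: exact multinomial expectation (0.25, 0.5, 0.25) for a selfed
  # heterozygote; check the central marker at n = 10000 within 3 SE.
  for (ptype in c("F2", "BC1F2")) {
    pop <- simulate_population(small_cfg(
      population_type = ptype, n_plants = 10000, causal_loci = NULL,
      seed = if (ptype == "F2") 11 else 12))
    d <- pop$genotypes[, 6]
    p_hat <- c(mean(d == 0), mean(d == 1), mean(d == 2))
    expected <- c(0.25, 0.5, 0.25)
    se <- sqrt(expected * (1 - expected) / 10000)
    expect_true(all(abs(p_hat - expected) < 3 * se),
                info = paste(ptype, paste(round(p_hat, 4), collapse = "/")))
  }
})

test_that("adjacent-marker recombination fraction matches the Haldane map", {
  # 11 markers over 50 cM: adjacent spacing 5 cM -> r = (1 - exp(-0.1))/2.
  pop <- simulate_population(small_cfg(n_plants = 10000, causal_loci = NULL,
                                       seed = 5))
  g <- pop$genotypes
  # Dosage changes between adjacent markers track gametic switches; compare
  # the dosage correlation with its expectation (1-2r) for two independent
  # gametes per plant.
  r <- 0.5 * (1 - exp(-2 * 0.05))
  rho <- cor(g[, 5], g[, 6])
  expect_lt(abs(rho - (1 - 2 * r)), 0.03)
})

test_that("simulation is reproducible given the seed", {
  cfg <- small_cfg(n_plants = 60, seed = 99)
  a <- simulate_cross(cfg)
  b <- simulate_cross(cfg)
  expect_identical(a$population$genotypes, b$population$genotypes)
  expect_identical(a$population$phenotypes, b$population$phenotypes)
  expect_identical(a$counts, b$counts)
})

test_that("bulk selection takes the phenotype tails, deterministically", {
  pop <- make_population(matrix(1L, 10, 3), nffb = as.numeric(1:10))
  bk <- select_bulks(pop, bulk_size = 3)
  expect_setequal(bk$high_ids, sprintf("P%04d", 8:10))
  expect_setequal(bk$low_ids, sprintf("P%04d", 1:3))

  # complete ties: still disjoint and deterministic
  pop2 <- make_population(matrix(1L, 10, 3), nffb = rep(4, 10))
  bk2 <- select_bulks(pop2, bulk_size = 3)
  expect_length(intersect(bk2$high_ids, bk2$low_ids), 0)
  expect_identical(select_bulks(pop2, 3)$high_ids, bk2$high_ids)

  expect_error(select_bulks(pop, bulk_size = 6), "bulk_size")
})

test_that("bulks are enriched for the causal allele in the expected direction", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e7,
                    chrom_length_cM = 50, n_markers_per_chrom = 21,
                    n_plants = 561, bulk_size = 30,
                    causal_loci = data.frame(chrom = "chr1", pos = 5e6,
                                             additive = 1, dominance = 0),
                    residual_sd = 0.5, seed = 21)
  pop <- simulate_population(cfg)
  bk <- select_bulks(pop)
  j <- which(pop$markers$causal)
  # Oracle: recompute dosage means directly from the stored genotypes.
  high_mean <- mean(pop$genotypes[bk$high_ids, j])
  low_mean <- mean(pop$genotypes[bk$low_ids, j])
  expect_gt(high_mean, low_mean + 1)
})

test_that("a bulk fixed for the maternal allele yields SNP-index 1", {
  pop <- make_population(matrix(2L, 4, 5), base_error_rate = 0)
  bk <- make_bulks(sprintf("P%04d", 1:2), sprintf("P%04d", 3:4))
  set.seed(8)
  counts <- simulate_pool_counts(pop, bk)
  stats <- compute_bsa_stats(counts)
  ok <- !is.na(stats$snp_index_high)
  expect_true(any(ok))
  expect_true(all(stats$snp_index_high[ok] == 1))
  # all reads carry the maternal base: no paternal or error bases anywhere
  expect_true(all(counts$high_T == 0 & counts$high_C == 0 & counts$high_G == 0))
})

test_that("observed pooled frequency matches binomial expectation at high depth", {
  # all plants heterozygous -> true allele frequency exactly 0.5
  pop <- make_population(matrix(1L, 4, 1), mean_depth = 1e6,
                         base_error_rate = 0)
  bk <- make_bulks(sprintf("P%04d", 1:2), sprintf("P%04d", 3:4))
  set.seed(13)
  counts <- simulate_pool_counts(pop, bk)
  f <- counts$high_A / (counts$high_A + counts$high_T)
  se <- sqrt(0.25 / (counts$high_A + counts$high_T))
  expect_lt(abs(f - 0.5), 3 * se)
})

test_that("empirical mean depth matches the Poisson model", {
  pop <- make_population(matrix(1L, 4, 1e5), mean_depth = 31.99)
  bk <- make_bulks(sprintf("P%04d", 1:2), sprintf("P%04d", 3:4))
  set.seed(14)
  counts <- simulate_pool_counts(pop, bk)
  dp <- rowSums(counts[, paste0("high_", c("A", "C", "G", "T"))])
  expect_lt(abs(mean(dp) - 31.99) / 31.99, 0.02)
})

test_that("null genome: genome-wide mean delta(SNP-index) is centred on zero", {
  means <- vapply(1:8, function(s) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 2e7,
                      chrom_length_cM = 80, n_markers_per_chrom = 400,
                      n_plants = 200, bulk_size = 20, causal_loci = NULL,
                      residual_sd = 1, seed = 300 + s)
    sim <- simulate_cross(cfg)
    stats <- compute_bsa_stats(sim$counts)
    mean(stats$delta_snp_index, na.rm = TRUE)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-3)
})

test_that("segregating_regions fixes outside markers for the maternal allele", {
  cfg <- small_cfg(n_plants = 50, causal_loci = NULL, seed = 31,
                   segregating_regions = data.frame(chrom = "chr1",
                                                    start = 1, end = 4e6))
  pop <- simulate_population(cfg)
  fixed <- !pop$markers$segregating
  expect_true(any(fixed))
  expect_true(all(pop$genotypes[, fixed] == 2L))
  expect_true(any(pop$genotypes[, !fixed] != 2L))
})
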