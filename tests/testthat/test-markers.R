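# Marker engine: CP segregation-pattern classification, distortion and
# integrity filters, fragment deduplication, collinearity.

test_that("pattern classification matches the CP convention on key cases", {
  expect_equal(classify_marker_patterns("A/A", "T/T"), "aaxbb")
  expect_equal(classify_marker_patterns("A/A", "A/A"), "uninformative")
  expect_equal(classify_marker_patterns("A/T", "A/A"), "lmxll")
  expect_equal(classify_marker_patterns("A/A", "A/T"), "nnxnp")
  expect_equal(classify_marker_patterns("A/T", "A/T"), "hkxhk")
  expect_equal(classify_marker_patterns("T/A", "A/T"), "hkxhk")  # unordered
  expect_equal(classify_marker_patterns("A/T", "A/G"), "efxeg")
  expect_equal(classify_marker_patterns("A/T", "C/G"), "abxcd")
  expect_equal(classify_marker_patterns("A/T", "C/C"), "abxcc")
  expect_equal(classify_marker_patterns("C/C", "A/T"), "ccxab")
  expect_equal(classify_marker_patterns(NA, "A/T"), "uninformative")
  expect_equal(classify_marker_patterns("./.", "A/T"), "uninformative")
  expect_error(classify_marker_patterns("A/X", "A/T"), "allele symbol")
})

test_that("classification is exhaustive and mutually exclusive by enumeration", {
  # Independent oracle: set logic over all 100 ordered pairs of the 10
  # unordered genotypes on 4 alleles.
  bases <- c("A", "C", "G", "T")
  gts <- apply(expand.grid(bases, bases), 1, function(x)
    paste(sort(x), collapse = "/"))
  gts <- unique(gts)  # 10 genotypes
  pairs <- expand.grid(p1 = gts, p2 = gts, stringsAsFactors = FALSE)
  oracle <- function(p1, p2) {
    A <- sort(strsplit(p1, "/")[[1]]); B <- sort(strsplit(p2, "/")[[1]])
    h1 <- A[1] != A[2]; h2 <- B[1] != B[2]
    sh <- length(intersect(A, B))
    if (!h1 && !h2) return(if (identical(A, B)) "uninformative" else "aaxbb")
    if (!h1 && h2) return(if (A[1] %in% B) "nnxnp" else "ccxab")
    if (h1 && !h2) return(if (B[1] %in% A) "lmxll" else "abxcc")
    if (identical(A, B)) return("hkxhk")
    if (sh == 1) return("efxeg")
    "abxcd"
  }
  got <- classify_marker_patterns(pairs$p1, pairs$p2)
  want <- mapply(oracle, pairs$p1, pairs$p2)
  expect_equal(got, unname(want))
  expect_equal(length(got), 100L)
  # every code observed
  expect_setequal(unique(got),
                  c("aaxbb", "abxcc", "abxcd", "ccxab", "efxeg", "hkxhk",
                    "lmxll", "nnxnp", "uninformative"))
})

test_that("segregation distortion chi-square matches hand and base-R values", {
  r <- test_segregation_distortion(c(50, 100, 50))
  expect_equal(r$chisq, 0)
  expect_equal(r$p_value, 1)

  r2 <- test_segregation_distortion(c(120, 60, 20))
  expect_equal(r2$chisq, 70^2 / 50 + 40^2 / 100 + 30^2 / 50)  # 132
  expect_lt(r2$p_value, 1e-10)

  r3 <- test_segregation_distortion(c(40, 110, 50))
  expect_equal(r3$chisq, 3.0)
  expect_equal(r3$p_value, pchisq(3, 2, lower.tail = FALSE), tolerance = 1e-12)

  # cross-check against stats::chisq.test on several random count triples
  set.seed(55)
  for (i in 1:10) {
    cnt <- as.vector(rmultinom(1, 200, c(0.25, 0.5, 0.25)))
    mine <- test_segregation_distortion(cnt)
    ref <- suppressWarnings(chisq.test(cnt, p = c(1, 2, 1) / 4))
    expect_equal(mine$chisq, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }

  expect_true(is.na(test_segregation_distortion(c(0, 0, 0))$p_value))
})

test_that("integrity filter keeps exactly 40% and above", {
  expect_true(filter_integrity(80, 200))
  expect_false(filter_integrity(79, 200))
  expect_true(filter_integrity(200, 200))
  expect_equal(filter_integrity(c(0, 79, 80, 200), 200),
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("same-fragment dedupe keeps one representative per cluster", {
  mk <- function(pos, chrom = "c1") data.frame(chrom = chrom, pos = pos)
  expect_equal(dedupe_same_fragment(mk(c(1000, 1050))), c(TRUE, FALSE))
  expect_equal(dedupe_same_fragment(mk(c(1000, 1500))), c(TRUE, TRUE))
  expect_equal(dedupe_same_fragment(mk(5000)), TRUE)
  # invariants: surviving markers > L apart; every dropped marker within L
  # of the kept representative before it
  set.seed(66)
  for (i in 1:20) {
    pos <- sort(sample.int(5000, 40))
    keep <- dedupe_same_fragment(mk(pos), fragment_length = 150)
    kept <- pos[keep]
    expect_true(all(diff(kept) > 150))
    for (p in pos[!keep]) {
      rep_ <- max(kept[kept <= p])
      expect_lte(p - rep_, 150)
    }
  }
  # clusters are independent across chromosomes
  two <- rbind(mk(c(100, 150)), mk(120, chrom = "c2"))
  expect_equal(dedupe_same_fragment(two), c(TRUE, FALSE, TRUE))
})

test_that("collinearity is the Spearman rank correlation", {
  pos <- c(10, 50, 200, 400, 900, 1500, 2200, 3000, 4100, 5000)
  expect_equal(map_collinearity(1:10, pos), 1)
  expect_equal(map_collinearity(10:1, pos), -1)
  rk <- c(1, 2, 4, 3, 5, 6, 7, 8, 9, 10)  # one adjacent transposition
  expect_equal(map_collinearity(rk, pos), cor(rank(rk), rank(pos)))
  expect_true(is.na(map_collinearity(1, 100)))
})

test_that("abnormal-base calls are blanked and high-abnormality markers dropped", {
  markers <- tibble::tibble(id = c("m1", "m2"), chrom = "c1",
                            pos = c(1000, 2000),
                            p1 = c("A/A", "A/A"), p2 = c("T/T", "T/T"))
  prog <- rbind(c("A/A", "A/T", "G/G", "T/T"),   # one abnormal of 4 (25%)
                c("A/A", "A/T", "T/T", "A/T"))   # none
  gm <- genotype_matrix(markers, prog, "F2")
  fa <- flag_abnormal_calls(gm, max_abnormal_fraction = 0.05)
  expect_equal(fa$n_abnormal, c(1L, 0L))
  expect_true(is.na(fa$gm$progeny[1, 3]))
  expect_equal(fa$keep, c(FALSE, TRUE))
})

test_that("filter battery reports consistently and per-marker rules commute", {
  set.seed(67)
  n_mark <- 30; n_pl <- 100
  p1 <- rep("A/A", n_mark); p2 <- rep("T/T", n_mark)
  prog <- matrix(NA_character_, n_mark, n_pl)
  for (i in seq_len(n_mark)) {
    g <- sample(c("A/A", "A/T", "T/T"), n_pl, replace = TRUE,
                prob = c(0.25, 0.5, 0.25))
    miss <- runif(n_pl) < runif(1, 0, 0.8)
    g[miss] <- NA
    prog[i, ] <- g
  }
  # marker 1 heavily distorted, marker 2 monomorphic parents
  prog[1, ] <- sample(c("A/A", "A/T", "T/T"), n_pl, replace = TRUE,
                      prob = c(0.9, 0.05, 0.05))
  p2[2] <- "A/A"
  markers <- tibble::tibble(id = paste0("m", 1:n_mark), chrom = "c1",
                            pos = sort(sample.int(1e6, n_mark)),
                            p1 = p1, p2 = p2)
  gm <- genotype_matrix(markers, prog, "F2")
  fl <- filter_markers(gm)
  expect_false("m1" %in% fl$surviving_ids)
  expect_false("m2" %in% fl$surviving_ids)
  expect_equal(fl$report$n_removed[fl$report$filter == "not_aaxbb"], 1L)
  # bookkeeping: survivors + per-stage removals account for all markers
  expect_equal(length(fl$surviving_ids) + sum(fl$report$n_removed), n_mark)

  # the three per-marker predicates commute: intersecting them in any order
  # gives the same surviving set
  fa <- flag_abnormal_calls(gm)
  keep_int <- filter_integrity(rowSums(!is.na(fa$gm$progeny)), n_pl)
  seg <- test_segregation_distortion(bsaqtl:::.genotype_class_counts(fa$gm))
  keep_dist <- is.na(seg$p_value) | seg$p_value >= 0.001
  ab <- classify_marker_patterns(markers$p1, markers$p2) == "aaxbb"
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    preds <- list(fa$keep, keep_int, keep_dist)[perm]
    expect_equal(ab & preds[[1]] & preds[[2]] & preds[[3]],
                 ab & fa$keep & keep_int & keep_dist)
  }
})

test_that("distortion filter removes about 0.1% of undistorted markers", {
  set.seed(68)
  counts <- t(rmultinom(20000, 200, c(0.25, 0.5, 0.25)))
  p <- test_segregation_distortion(counts)$p_value
  rate <- mean(p < 0.001)
  se <- sqrt(0.001 * 0.999 / 20000)
  expect_lt(abs(rate - 0.001), 4 * se + 5e-4)
})
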