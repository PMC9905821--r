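# Marker engine: segregation-pattern classification of parental genotype
# pairs (JoinMap CP codes), progeny-based marker filters, fragment
# deduplication, and map/physical collinearity.

PATTERN_LEVELS <- c("aaxbb", "abxcc", "abxcd", "ccxab", "efxeg",
                    "hkxhk", "lmxll", "nnxnp", "uninformative")

#' Classify a parental genotype pair into a segregation pattern
#'
#' Implements the standard CP-convention mapping of the eight codes:
#' * `aaxbb`: both parents homozygous for different alleles;
#' * `lmxll`: parent 1 heterozygous, parent 2 homozygous for an allele
#'   parent 1 carries; `nnxnp` is the mirror (parent 1 homozygous);
#' * `abxcc` / `ccxab`: one parent heterozygous, the other homozygous for an
#'   allele absent from the heterozygote;
#' * `hkxhk`: both heterozygous with identical allele pairs;
#' * `efxeg`: both heterozygous sharing exactly one allele;
#' * `abxcd`: both heterozygous, four distinct alleles;
#' * `uninformative`: both parents homozygous identical, or a missing call.
#'
#' The mapping is exhaustive and mutually exclusive over all ordered pairs of
#' parental genotypes.
#'
#' @param p1,p2 Character vectors of genotype calls `"X/Y"` with alleles in
#'   A/C/G/T; `NA` or `"./."` is missing.
#' @return Character vector of pattern codes (one of
#'   `r paste(PATTERN_LEVELS, collapse = ", ")`).
#' @export
#' @examples
#' classify_marker_patterns("A/A", "T/T")  # "aaxbb"
#' classify_marker_patterns("A/T", "A/A")  # "lmxll"
classify_marker_patterns <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  a <- .parse_calls(p1)
  b <- .parse_calls(p2)
  out <- character(length(p1))
  miss <- is.na(a[, 1]) | is.na(b[, 1])
  hom1 <- a[, 1] == a[, 2]
  hom2 <- b[, 1] == b[, 2]
  for (i in seq_along(out)) {
    if (miss[i]) { out[i] <- "uninformative"; next }
    A <- a[i, ]; B <- b[i, ]
    shared <- length(intersect(unique(A), unique(B)))
    out[i] <- if (hom1[i] && hom2[i]) {
      if (A[1] == B[1]) "uninformative" else "aaxbb"
    } else if (hom1[i]) {            # p1 hom, p2 het
      if (A[1] %in% B) "nnxnp" else "ccxab"
    } else if (hom2[i]) {            # p1 het, p2 hom
      if (B[1] %in% A) "lmxll" else "abxcc"
    } else {                          # both het
      if (setequal(A, B)) "hkxhk"
      else if (shared == 1) "efxeg"
      else "abxcd"
    }
  }
  out
}

.parse_calls <- function(x) {
  x[x %in% c("./.", ".", "")] <- NA_character_
  parts <- strsplit(ifelse(is.na(x), "NA/NA", x), "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed genotype call: ", x[which(bad)[1]],
                     call. = FALSE)
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  m[m == "NA"] <- NA_character_
  ok <- is.na(m) | m %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("allele symbol outside A/C/G/T", call. = FALSE)
  t(apply(m, 1, sort, na.last = TRUE))
}

#' Chi-square test for segregation distortion at an aa x bb marker
#'
#' Goodness-of-fit of progeny genotype class counts (AA, Aa, BB) against the
#' Mendelian 1:2:1 expectation of an F2 (and of a BC1F2 selfed from fully
#' heterozygous BC1 plants), without continuity correction; df = 2. Markers
#' with p below the distortion threshold (0.001 in the standard filter) are
#' flagged for removal by [filter_markers()].
#'
#' @param counts Length-3 vector `(AA, Aa, BB)` or an n x 3 matrix of such
#'   counts (missing calls excluded beforehand).
#' @param population_type `"F2"` or `"BC1F2"` (same expectation under the
#'   heterozygous-founder model).
#' @return Tibble with `chisq` and `p_value` (NA when a row has zero
#'   informative progeny; such markers fall to the integrity rule instead).
#' @export
#' @examples
#' test_segregation_distortion(c(50, 100, 50))$p_value  # 1
test_segregation_distortion <- function(counts,
                                        population_type = c("F2", "BC1F2")) {
  population_type <- match.arg(population_type)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  stopifnot(ncol(counts) == 3, all(counts >= 0, na.rm = TRUE))
  n <- rowSums(counts)
  expected <- outer(n, c(0.25, 0.5, 0.25))
  chisq <- rowSums((counts - expected)^2 / expected)
  chisq[n == 0] <- NA_real_
  tibble(chisq = chisq,
         p_value = pchisq(chisq, df = 2, lower.tail = FALSE))
}

#' Marker integrity (call-rate) filter
#'
#' A marker is kept iff the fraction of plants with a non-missing call is at
#' least `min_integrity` (removal is strict: integrity < 40% by default, so
#' exactly 40% survives).
#'
#' @param n_called Non-missing progeny calls per marker (vector).
#' @param n_plants Population size.
#' @param min_integrity Minimum call-rate, default 0.40.
#' @return Logical vector: `TRUE` = keep.
#' @export
filter_integrity <- function(n_called, n_plants, min_integrity = 0.40) {
  stopifnot(n_plants > 0, all(n_called >= 0), all(n_called <= n_plants))
  n_called / n_plants >= min_integrity
}

#' Deduplicate markers on the same sequencing fragment
#'
#' Markers are scanned in position order per chromosome; a marker within
#' `fragment_length` bp of the current cluster's representative (the first
#' marker of the cluster) is dropped, otherwise it starts a new cluster and
#' is kept. Consequently any two surviving markers on a chromosome are more
#' than `fragment_length` bp apart, and every dropped marker lies within
#' `fragment_length` bp of a kept one.
#'
#' @param markers Tibble with `chrom` and `pos` (sorted by position within
#'   chromosome).
#' @param fragment_length Fragment span in bp (default 150).
#' @return Logical vector: `TRUE` = keep.
#' @export
dedupe_same_fragment <- function(markers, fragment_length = 150) {
  stopifnot(all(c("chrom", "pos") %in% names(markers)))
  keep <- logical(nrow(markers))
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    pos <- markers$pos[idx]
    if (is.unsorted(pos)) stop("markers must be position-sorted", call. = FALSE)
    rep_pos <- -Inf
    for (k in seq_along(idx)) {
      if (pos[k] - rep_pos > fragment_length) {
        keep[idx[k]] <- TRUE
        rep_pos <- pos[k]
      }
    }
  }
  keep
}

#' Collinearity between genetic map order and physical position
#'
#' Spearman rank correlation between a linkage group's genetic order and the
#' markers' physical coordinates; +1 for identical order, -1 for exactly
#' reversed order.
#'
#' @param genetic_rank Genetic map order (rank or map position) per marker.
#' @param physical_pos Physical position (bp) per marker.
#' @return Correlation in `[-1, 1]`, or `NA` with fewer than 2 markers.
#' @export
map_collinearity <- function(genetic_rank, physical_pos) {
  stopifnot(length(genetic_rank) == length(physical_pos))
  if (length(genetic_rank) < 2) return(NA_real_)
  cor(genetic_rank, physical_pos, method = "spearman")
}

#' Construct a genotype matrix container
#'
#' @param markers Tibble with `id`, `chrom`, `pos`, `p1`, `p2` (parental
#'   calls `"X/Y"`).
#' @param progeny Character matrix (markers x plants) of progeny calls,
#'   `NA`/`"./."` missing.
#' @param population_type `"F2"` or `"BC1F2"`.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(markers, progeny,
                            population_type = c("F2", "BC1F2")) {
  population_type <- match.arg(population_type)
  stopifnot(all(c("id", "chrom", "pos", "p1", "p2") %in% names(markers)),
            nrow(progeny) == nrow(markers))
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("marker positions must be strictly increasing within chromosome",
           call. = FALSE)
    }
  }
  progeny[progeny %in% c("./.", ".", "")] <- NA_character_
  structure(list(markers = as_tibble(markers), progeny = progeny,
                 population_type = population_type),
            class = "genotype_matrix")
}

#' Flag progeny calls carrying alleles absent from both parents
#'
#' "Abnormal base" calls -- progeny genotypes containing an allele that
#' neither parent carries -- are genotyping artifacts; they are set missing,
#' and markers whose abnormal-call fraction exceeds `max_abnormal_fraction`
#' are flagged for removal.
#'
#' @param gm A [genotype_matrix()].
#' @param max_abnormal_fraction Strict removal threshold (default 0.05).
#' @return List: `gm` (with abnormal calls set missing), `n_abnormal` per
#'   marker, `keep` logical per marker.
#' @export
flag_abnormal_calls <- function(gm, max_abnormal_fraction = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  prog <- gm$progeny
  n_ab <- integer(nrow(prog))
  for (i in seq_len(nrow(prog))) {
    par_alleles <- unique(unlist(strsplit(
      c(gm$markers$p1[i], gm$markers$p2[i]), "/", fixed = TRUE)))
    calls <- prog[i, ]
    ok <- is.na(calls)
    al <- strsplit(ifelse(ok, "A/A", calls), "/", fixed = TRUE)
    abnormal <- !ok & !vapply(al, function(x) all(x %in% par_alleles),
                              logical(1))
    n_ab[i] <- sum(abnormal)
    prog[i, abnormal] <- NA_character_
  }
  gm$progeny <- prog
  list(gm = gm, n_abnormal = n_ab,
       keep = n_ab / ncol(prog) <= max_abnormal_fraction)
}

#' Apply the full marker filter battery
#'
#' Classifies each marker's parental pattern, then on the `aaxbb` markers
#' applies, in order: the abnormal-base rule (abnormal calls set missing,
#' high-abnormality markers removed), the integrity (call-rate) rule, the
#' chi-square segregation-distortion rule, and last the same-fragment
#' deduplication (the only order-sensitive step, documented as applied
#' last). The first three are per-marker predicates whose surviving set is
#' order-independent.
#'
#' @param gm A [genotype_matrix()].
#' @param distortion_p Removal threshold on the distortion p-value
#'   (default 0.001, strict `<`).
#' @param min_integrity See [filter_integrity()].
#' @param max_abnormal_fraction See [flag_abnormal_calls()].
#' @param fragment_length See [dedupe_same_fragment()].
#' @return List of class `marker_filter`: `patterns` (per input marker),
#'   `surviving_ids`, and `report` tibble of per-filter removal counts.
#' @export
filter_markers <- function(gm, distortion_p = 0.001, min_integrity = 0.40,
                           max_abnormal_fraction = 0.05,
                           fragment_length = 150) {
  stopifnot(inherits(gm, "genotype_matrix"))
  patterns <- classify_marker_patterns(gm$markers$p1, gm$markers$p2)
  is_ab <- patterns == "aaxbb"
  n_plants <- ncol(gm$progeny)

  fa <- flag_abnormal_calls(gm, max_abnormal_fraction)
  gm2 <- fa$gm
  keep_abn <- fa$keep

  n_called <- rowSums(!is.na(gm2$progeny))
  keep_int <- filter_integrity(n_called, n_plants, min_integrity)

  counts <- .genotype_class_counts(gm2)
  seg <- test_segregation_distortion(counts, gm$population_type)
  keep_dist <- is.na(seg$p_value) | seg$p_value >= distortion_p

  keep <- is_ab & keep_abn & keep_int & keep_dist
  keep_dedup <- rep(FALSE, nrow(gm$markers))
  if (any(keep)) {
    sub <- gm$markers[keep, c("chrom", "pos")]
    keep_dedup[which(keep)[dedupe_same_fragment(sub, fragment_length)]] <- TRUE
  }

  structure(list(
    patterns = patterns,
    distortion = seg,
    surviving_ids = gm$markers$id[keep_dedup],
    report = tibble(
      filter = c("not_aaxbb", "abnormal_bases", "integrity",
                 "segregation_distortion", "same_fragment"),
      n_removed = c(sum(!is_ab),
                    sum(is_ab & !keep_abn),
                    sum(is_ab & !keep_int),
                    sum(is_ab & !keep_dist),
                    sum(keep) - sum(keep_dedup))
    )
  ), class = "marker_filter")
}

# Counts of (p1-homozygote, heterozygote, p2-homozygote) progeny classes.
.genotype_class_counts <- function(gm) {
  m <- nrow(gm$markers)
  out <- matrix(0L, nrow = m, ncol = 3L)
  norm <- function(x) {
    vapply(strsplit(x, "/", fixed = TRUE),
           function(a) paste(sort(a), collapse = "/"), character(1))
  }
  p1 <- norm(gm$markers$p1)
  p2 <- norm(gm$markers$p2)
  for (i in seq_len(m)) {
    calls <- gm$progeny[i, ]
    calls <- calls[!is.na(calls)]
    if (!length(calls)) next
    calls <- norm(calls)
    het <- paste(sort(c(sub("/.*", "", p1[i]), sub("/.*", "", p2[i]))),
                 collapse = "/")
    out[i, ] <- c(sum(calls == p1[i]), sum(calls == het), sum(calls == p2[i]))
  }
  out
}
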