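# Shared in-code fixtures for the test suite.

# Pool-counts tibble from explicit per-pool M/P depths on a ref/alt pair.
make_counts <- function(M_high, P_high, M_low, P_low,
                        ref = "A", alt = "T", chrom = "chr1",
                        pos = seq_along(M_high) * 1000L) {
  bases <- c("A", "C", "G", "T")
  n <- length(M_high)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  out <- tibble::tibble(chrom = rep_len(chrom, n), pos = pos,
                        ref = ref, alt = alt)
  for (pool in c("high", "low")) {
    cnt <- matrix(0L, n, 4, dimnames = list(NULL, bases))
    m <- if (pool == "high") M_high else M_low
    p <- if (pool == "high") P_high else P_low
    cnt[cbind(seq_len(n), match(ref, bases))] <- as.integer(m)
    cnt[cbind(seq_len(n), match(alt, bases))] <- as.integer(p)
    colnames(cnt) <- paste0(pool, "_", bases)
    out <- cbind(out, tibble::as_tibble(cnt))
  }
  tibble::as_tibble(out)
}

# Random biallelic counts with depth >= min_depth in both pools.
rand_biallelic_counts <- function(n, min_depth = 5, max_depth = 100) {
  dp_h <- sample(min_depth:max_depth, n, replace = TRUE)
  dp_l <- sample(min_depth:max_depth, n, replace = TRUE)
  m_h <- rbinom(n, dp_h, runif(n))
  m_l <- rbinom(n, dp_l, runif(n))
  make_counts(m_h, dp_h - m_h, m_l, dp_l - m_l)
}

# A minimal hand-built population object (bypasses meiosis simulation) for
# targeted pool-count tests: one chromosome, given dosage matrix.
make_population <- function(dosage, ref = "A", alt = "T",
                            mean_depth = 30, base_error_rate = 0,
                            residual_sd = 0, nffb = NULL) {
  n_pl <- nrow(dosage); m <- ncol(dosage)
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = m * 1000 + 1000,
                    n_markers_per_chrom = m, n_plants = max(n_pl, 2),
                    causal_loci = NULL, bulk_size = 1,
                    mean_depth = mean_depth,
                    base_error_rate = base_error_rate,
                    residual_sd = residual_sd)
  markers <- tibble::tibble(
    id = paste0("chr1_", seq_len(m) * 1000L), chrom = "chr1",
    pos = seq_len(m) * 1000L, cM = seq_len(m) * 0.01,
    ref = rep_len(ref, m), alt = rep_len(alt, m),
    segregating = TRUE, causal = FALSE)
  rownames(dosage) <- sprintf("P%04d", seq_len(n_pl))
  colnames(dosage) <- markers$id
  if (is.null(nffb)) nffb <- rep(5, n_pl)
  structure(list(config = cfg, markers = markers, genotypes = dosage,
                 phenotypes = tibble::tibble(plant_id = rownames(dosage),
                                             nffb = nffb)),
            class = "bsa_population")
}

make_bulks <- function(high_ids, low_ids) {
  structure(list(high_ids = high_ids, low_ids = low_ids,
                 bulk_size = length(high_ids)), class = "bulk_assignment")
}

# Random reads for QC property tests.
random_reads <- function(n, len = 100, n_rate = 0.02, qmin = 2, qmax = 40) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                 prob = c(rep((1 - n_rate) / 4, 4), n_rate)), collapse = "")
  }, character(1))
  quals <- vapply(seq_len(n), function(i) {
    intToUtf8(sample(qmin:qmax, len, replace = TRUE) + 33L)
  }, character(1))
  tibble::tibble(id = paste0("read", seq_len(n)), seq = seqs, qual = quals)
}

# Independent naive region-calling oracle: per-SNP scan with explicit
# run-growing, used to validate call_regions.
oracle_call_regions <- function(track, cutoff, min_snps, max_gap) {
  res <- list()
  for (ch in unique(track$chrom)) {
    pos <- track$pos[track$chrom == ch]
    val <- track$value[track$chrom == ch]
    cur <- integer(0)
    flush <- function(cur) {
      if (length(cur) >= min_snps) {
        res[[length(res) + 1]] <<- data.frame(
          chrom = ch, start = min(cur), end = max(cur),
          length = max(cur) - min(cur) + 1, n_snps = length(cur))
      }
    }
    for (k in seq_along(pos)) {
      if (!is.na(val[k]) && val[k] > cutoff) {
        if (length(cur) && pos[k] - cur[length(cur)] > max_gap) {
          flush(cur); cur <- integer(0)
        }
        cur <- c(cur, pos[k])
      }
    }
    flush(cur)
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      n_snps = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Independent per-base interval-intersection oracle on a small span.
oracle_intersect <- function(a, b, span) {
  res <- list()
  for (ch in union(a$chrom, b$chrom)) {
    cover <- function(rs) {
      v <- logical(span)
      rs <- rs[rs$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(rs))) v[rs$start[i]:rs$end[i]] <- TRUE
      v
    }
    v <- cover(a) & cover(b)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep)) {
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = starts[keep], end = ends[keep],
        length = ends[keep] - starts[keep] + 1)
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Random disjoint sorted region set on [1, span]; odd coordinates only so
# intervals are separated by at least one base (never merely adjacent).
random_region_set <- function(span, max_regions = 5) {
  k <- sample.int(max_regions, 1)
  cuts <- sort(sample(seq(1, span, by = 2), 2 * k))
  data.frame(chrom = "c1",
             start = cuts[seq(1, 2 * k, 2)],
             end = cuts[seq(2, 2 * k, 2)])
}
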