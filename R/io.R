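# File emission and ingestion for the simulator's fixtures: a VCF 4.2 with
# per-pool allele depths, phenotype and truth TSVs, and a TSV form of the
# pool counts.

#' Write simulated fixtures to standard files
#'
#' Emits a VCF 4.2 with four samples (JF914, JF173, HIGH, LOW): parents carry
#' GT calls (0/0 and 1/1, REF being the maternal allele), pools carry
#' ref/alt allele depths in AD and the four-base depths A,C,G,T in a BC
#' FORMAT field (needed by the Euclidean-distance statistic). Also writes a
#' phenotype TSV (`plant_id`, `nffb`) and a truth TSV of causal loci.
#'
#' @param pop A `bsa_population`.
#' @param counts Pool counts from [simulate_pool_counts()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the written paths
#'   (`vcf`, `phenotypes`, `truth`).
#' @export
write_fixtures <- function(pop, counts, dir) {
  stopifnot(inherits(pop, "bsa_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "pools.vcf"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_pool_vcf(counts, paths[["vcf"]],
                 contigs = setNames(rep(pop$config$chrom_length_bp,
                                        pop$config$n_chromosomes),
                                    paste0("chr", seq_len(pop$config$n_chromosomes))))
  write.table(pop$phenotypes, paths[["phenotypes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(pop$config$causal_loci, paths[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write pool allele counts as a VCF
#'
#' @param counts Pool-counts tibble (see [simulate_pool_counts()]).
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return Invisibly, `path`.
#' @export
write_pool_vcf <- function(counts, path, contigs = NULL) {
  .check_counts(counts)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bsaqtl",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt allele depths\">",
    "##FORMAT=<ID=BC,Number=4,Type=Integer,Description=\"Base depths A,C,G,T\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "JF914", "JF173", "HIGH", "LOW"), collapse = "\t")
  )
  body <- character(0)
  if (nrow(counts)) {
    bases <- c("A", "C", "G", "T")
    ri <- match(counts$ref, bases)
    ai <- match(counts$alt, bases)
    hm <- as.matrix(counts[, paste0("high_", bases)])
    lm_ <- as.matrix(counts[, paste0("low_", bases)])
    n <- nrow(counts)
    high_fmt <- sprintf("./.:%d,%d:%s",
                        hm[cbind(seq_len(n), ri)], hm[cbind(seq_len(n), ai)],
                        apply(hm, 1, paste, collapse = ","))
    low_fmt <- sprintf("./.:%d,%d:%s",
                       lm_[cbind(seq_len(n), ri)], lm_[cbind(seq_len(n), ai)],
                       apply(lm_, 1, paste, collapse = ","))
    body <- paste(counts$chrom, counts$pos,
                  paste0(counts$chrom, "_", counts$pos),
                  counts$ref, counts$alt, ".", "PASS", ".",
                  "GT:AD:BC", "0/0:.:.", "1/1:.:.", high_fmt, low_fmt,
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read pool allele counts back from a VCF
#'
#' Parses a VCF written by [write_pool_vcf()] (or any VCF carrying a BC
#' FORMAT field with four-base depths for samples HIGH and LOW) via vcfR.
#'
#' @param path VCF path.
#' @return A pool-counts tibble with the same columns as
#'   [simulate_pool_counts()].
#' @export
read_pool_counts <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bases <- c("A", "C", "G", "T")
  empty <- tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character())
  for (pool in c("high", "low")) for (b in bases) {
    empty[[paste0(pool, "_", b)]] <- integer()
  }
  if (nrow(vcf@fix) == 0) return(empty)
  bc <- vcfR::extract.gt(vcf, element = "BC")
  parse_bc <- function(x) {
    mat <- matrix(as.integer(unlist(strsplit(x, ",", fixed = TRUE))),
                  ncol = 4L, byrow = TRUE)
    colnames(mat) <- bases
    mat
  }
  hm <- parse_bc(bc[, "HIGH"])
  lm_ <- parse_bc(bc[, "LOW"])
  out <- tibble(chrom = unname(vcf@fix[, "CHROM"]),
                pos = as.integer(vcf@fix[, "POS"]),
                ref = unname(vcf@fix[, "REF"]),
                alt = unname(vcf@fix[, "ALT"]))
  colnames(hm) <- paste0("high_", bases)
  colnames(lm_) <- paste0("low_", bases)
  as_tibble(cbind(out, as_tibble(hm), as_tibble(lm_)))
}

#' Write / read pool counts as TSV
#'
#' Plain-text alternative to the VCF round trip; columns exactly as in
#' [simulate_pool_counts()].
#'
#' @param counts Pool-counts tibble.
#' @param path File path.
#' @return `write_pool_counts_tsv()` returns `path` invisibly;
#'   `read_pool_counts_tsv()` returns the tibble.
#' @export
write_pool_counts_tsv <- function(counts, path) {
  .check_counts(counts)
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_counts_tsv
#' @export
read_pool_counts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", ref = "character",
                                  alt = "character"))
  .check_counts(df)
  as_tibble(df)
}

#' Read a phenotype table
#'
#' @param path TSV with columns `plant_id` and a trait column (default
#'   `nffb`).
#' @return Tibble.
#' @export
read_phenotypes <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

.check_counts <- function(counts) {
  need <- c("chrom", "pos", "ref", "alt",
            paste0("high_", c("A", "C", "G", "T")),
            paste0("low_", c("A", "C", "G", "T")))
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("pool counts missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cnt <- as.matrix(counts[, need[-(1:4)]])
  if (nrow(counts) && any(cnt < 0)) stop("negative allele depth", call. = FALSE)
  invisible(TRUE)
}
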