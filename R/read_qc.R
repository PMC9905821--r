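# Read-quality filtering for GBS and re-sequencing libraries.
#
# A read is removed iff it violates at least one enabled rule; the report
# counts every rule a read trips (so per-rule counts can sum to more than the
# number of removed reads).

#' Quality-filter rule sets
#'
#' Builds the rule set for one of the two library types:
#'
#' * `GBS`: remove reads with >= 10% unidentified nucleotides (N); remove
#'   reads with > 50% of bases below Phred 5; remove reads with any 10-nt
#'   stretch aligning to the adapter with <= 10% mismatches; remove reads
#'   containing a restriction recognition site (defaults HaeIII = GGCC,
#'   EcoRI = GAATTC).
#' * `RESEQ`: remove reads with > 10% N (strict) and reads with > 40% of
#'   bases at Q <= 20; no adapter or site rule by default (adapter removal in
#'   re-sequencing is a trimming step, out of scope here).
#'
#' Boundary semantics follow the printed rules exactly: the GBS N rule is
#' inclusive (>= 10%), the low-quality fractions are strict (> 50%, > 40%),
#' the GBS low-quality comparison is strict (Phred < 5) while the RESEQ one
#' is inclusive (Q <= 20).
#'
#' @param mode `"GBS"` or `"RESEQ"`.
#' @param max_n_fraction,n_inclusive N-content threshold and whether the
#'   comparison is inclusive.
#' @param low_qual_cutoff,low_qual_inclusive Phred cutoff defining a
#'   low-quality base, and whether a base *at* the cutoff counts as low.
#' @param max_low_qual_fraction Strict upper bound on the low-quality base
#'   fraction.
#' @param adapter Adapter sequence, or `NULL` to disable the adapter rule.
#' @param adapter_match_len Window length compared against the adapter.
#' @param adapter_max_mismatch_fraction Mismatch tolerance per window.
#' @param forbidden_sites Named character vector of recognition sequences,
#'   or `NULL`.
#' @return An object of class `qc_rules`.
#' @export
#' @examples
#' qc_rules("GBS")
#' qc_rules("RESEQ")
qc_rules <- function(mode = c("GBS", "RESEQ"),
                     max_n_fraction = NULL,
                     n_inclusive = NULL,
                     low_qual_cutoff = NULL,
                     low_qual_inclusive = NULL,
                     max_low_qual_fraction = NULL,
                     adapter = NULL,
                     adapter_match_len = 10L,
                     adapter_max_mismatch_fraction = 0.1,
                     forbidden_sites = NULL) {
  mode <- match.arg(mode)
  defaults <- if (mode == "GBS") {
    list(max_n_fraction = 0.10, n_inclusive = TRUE,
         low_qual_cutoff = 5L, low_qual_inclusive = FALSE,
         max_low_qual_fraction = 0.50,
         adapter = "AGATCGGAAGAGC",
         forbidden_sites = c(HaeIII = "GGCC", EcoRI = "GAATTC"))
  } else {
    list(max_n_fraction = 0.10, n_inclusive = FALSE,
         low_qual_cutoff = 20L, low_qual_inclusive = TRUE,
         max_low_qual_fraction = 0.40,
         adapter = NULL, forbidden_sites = NULL)
  }
  supplied <- list(max_n_fraction = max_n_fraction, n_inclusive = n_inclusive,
                   low_qual_cutoff = low_qual_cutoff,
                   low_qual_inclusive = low_qual_inclusive,
                   max_low_qual_fraction = max_low_qual_fraction,
                   adapter = adapter, forbidden_sites = forbidden_sites)
  for (nm in names(supplied)) {
    if (!is.null(supplied[[nm]])) defaults[[nm]] <- supplied[[nm]]
  }
  rules <- c(defaults, list(mode = mode,
                            adapter_match_len = as.integer(adapter_match_len),
                            adapter_max_mismatch_fraction = adapter_max_mismatch_fraction))
  stopifnot(rules$max_n_fraction >= 0, rules$max_n_fraction <= 1,
            rules$max_low_qual_fraction >= 0, rules$max_low_qual_fraction <= 1,
            rules$adapter_max_mismatch_fraction >= 0,
            rules$adapter_max_mismatch_fraction <= 1)
  if (!is.null(rules$adapter) &&
      rules$adapter_match_len > nchar(rules$adapter)) {
    stop("adapter_match_len exceeds adapter length", call. = FALSE)
  }
  structure(rules, class = "qc_rules")
}

#' Filter reads against a QC rule set
#'
#' @param reads Tibble with columns `id`, `seq` (A/C/G/T/N), `qual`
#'   (Sanger-encoded Phred string, offset 33), as returned by [read_fastq()].
#' @param rules A [qc_rules()] object.
#' @return List of class `qc_filter` with `kept` (the surviving reads),
#'   `removed_ids`, and `report`: a tibble of per-rule removal counts
#'   (`rule`, `n_removed`) plus `n_input`/`n_kept` attributes-free summary
#'   rows are not included -- a read tripping several rules is counted under
#'   each.
#' @export
filter_reads <- function(reads, rules) {
  stopifnot(inherits(rules, "qc_rules"),
            all(c("id", "seq", "qual") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0) {
    return(structure(list(
      kept = reads, removed_ids = character(0),
      report = tibble(rule = c("n_content", "low_quality", "adapter",
                               "forbidden_site"),
                      n_removed = 0L),
      n_input = 0L, n_kept = 0L), class = "qc_filter"))
  }
  dss <- Biostrings::DNAStringSet(reads$seq)
  len <- Biostrings::width(dss)

  nfrac <- as.vector(Biostrings::letterFrequency(dss, "N")) / len
  fail_n <- if (rules$n_inclusive) nfrac >= rules$max_n_fraction else
    nfrac > rules$max_n_fraction

  q <- methods::as(Biostrings::PhredQuality(reads$qual), "IntegerList")
  nlow <- if (rules$low_qual_inclusive) sum(q <= rules$low_qual_cutoff) else
    sum(q < rules$low_qual_cutoff)
  fail_q <- nlow / len > rules$max_low_qual_fraction

  fail_ad <- rep(FALSE, n)
  if (!is.null(rules$adapter)) {
    L <- rules$adapter_match_len
    mm <- floor(rules$adapter_max_mismatch_fraction * L)
    starts <- seq_len(nchar(rules$adapter) - L + 1L)
    for (s in starts) {
      w <- substr(rules$adapter, s, s + L - 1L)
      fail_ad <- fail_ad |
        Biostrings::vcountPattern(w, dss, max.mismatch = mm) > 0
    }
  }

  fail_site <- rep(FALSE, n)
  if (!is.null(rules$forbidden_sites)) {
    for (site in rules$forbidden_sites) {
      fail_site <- fail_site | Biostrings::vcountPattern(site, dss) > 0
    }
  }

  removed <- fail_n | fail_q | fail_ad | fail_site
  structure(list(
    kept = reads[!removed, , drop = FALSE],
    removed_ids = reads$id[removed],
    report = tibble(
      rule = c("n_content", "low_quality", "adapter", "forbidden_site"),
      n_removed = c(sum(fail_n), sum(fail_q), sum(fail_ad), sum(fail_site))
    ),
    n_input = n, n_kept = sum(!removed)
  ), class = "qc_filter")
}

#' Filter read pairs: drop the pair if either mate fails
#'
#' @param reads1,reads2 Mate tibbles of equal length (see [filter_reads()]).
#' @param rules A [qc_rules()] object.
#' @return List with `kept1`, `kept2`, and the two mates' reports.
#' @export
filter_read_pairs <- function(reads1, reads2, rules) {
  stopifnot(nrow(reads1) == nrow(reads2))
  f1 <- filter_reads(reads1, rules)
  f2 <- filter_reads(reads2, rules)
  bad <- reads1$id %in% f1$removed_ids | reads2$id %in% f2$removed_ids
  list(kept1 = reads1[!bad, , drop = FALSE],
       kept2 = reads2[!bad, , drop = FALSE],
       n_pairs_input = nrow(reads1), n_pairs_kept = sum(!bad),
       report1 = f1$report, report2 = f2$report)
}

#' Read a FASTQ file
#'
#' Minimal strict 4-line-record reader. Malformed records (bad header or
#' separator lines, sequence/quality length mismatch, characters outside
#' A/C/G/T/N, truncated final record) raise an error naming the offending
#' 1-based line number. Transparently reads gzip-compressed files.
#'
#' @param path FASTQ path.
#' @return Tibble with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  nl <- length(lines)
  if (nl %% 4L != 0L) {
    stop(sprintf("malformed FASTQ: truncated record at line %d", nl + 1L),
         call. = FALSE)
  }
  if (nl == 0L) return(tibble(id = character(), seq = character(),
                              qual = character()))
  i1 <- seq(1L, nl, by = 4L)
  bad <- which(!startsWith(lines[i1], "@"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ: expected '@' header at line %d",
                 i1[bad[1]]), call. = FALSE)
  }
  bad <- which(!startsWith(lines[i1 + 2L], "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ: expected '+' separator at line %d",
                 i1[bad[1]] + 2L), call. = FALSE)
  }
  seqs <- lines[i1 + 1L]
  quals <- lines[i1 + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ: sequence/quality length mismatch at line %d",
                 i1[bad[1]] + 3L), call. = FALSE)
  }
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ: non-ACGTN character at line %d",
                 i1[bad[1]] + 1L), call. = FALSE)
  }
  tibble(id = sub("^@", "", sub("\\s.*$", "", lines[i1])),
         seq = seqs, qual = quals)
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `id`, `seq`, `qual`.
#' @param path Output path (gzip if it ends in `.gz`).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq,
                               "+", reads$qual)), con)
  }
  invisible(path)
}
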