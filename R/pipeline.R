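# Pipeline driver: stages communicate via files in standard formats so each
# stage is independently testable; one seed drives all stochastic stages and
# the run manifest (parameter echo + output checksums) makes a run
# reproducible bit-for-bit.

#' Run the BSA pipeline end-to-end
#'
#' Executes the enabled stages in fixed order -- simulate, bsa, regions,
#' pheno -- from one configuration (a YAML file or an equivalent nested
#' list), writing every product and a manifest of md5 checksums into
#' `out_dir`. Identical configuration and seed give identical checksums.
#'
#' Configuration keys: `seed`; `stages` (logical toggles `simulate`, `bsa`,
#' `regions`, `pheno`); `simulate` ([sim_config()] arguments; `causal_loci`
#' as a list of `{chrom, pos, additive, dominance}` records); `bsa`
#' (`min_depth`, and `counts` -- path to a pool-counts TSV or VCF -- when the
#' simulate stage is off); `regions` (`min_snps`, `max_gap`,
#' `per_chromosome`, optional `qtl` path to a TSV with `chrom`, `start`,
#' `end`); `pheno` (optional `phenotypes` path when simulate is off).
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `manifest` (tibble: `stage`, `file`,
#'   `md5`), `paths`, and the echoed `config`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- config$stages
  paths <- character(0)
  stage_of <- character(0)
  emit <- function(stage, name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    stage_of[[name]] <<- stage
    p
  }

  sim <- NULL
  counts <- NULL
  phenotypes <- NULL

  if (isTRUE(stages$simulate)) {
    sc_args <- config$simulate
    if (!is.null(sc_args$causal_loci)) {
      sc_args$causal_loci <- do.call(rbind, lapply(sc_args$causal_loci,
                                                   as.data.frame))
    }
    sc_args$seed <- config$seed
    cfg <- do.call(sim_config, sc_args)
    sim <- simulate_cross(cfg)
    counts <- sim$counts
    phenotypes <- sim$population$phenotypes
    fx <- write_fixtures(sim$population, counts, out_dir)
    for (nm in names(fx)) {
      paths[[basename(fx[[nm]])]] <- fx[[nm]]
      stage_of[[basename(fx[[nm]])]] <- "simulate"
    }
    emit("simulate", "pool_counts.tsv",
         function(p) write_pool_counts_tsv(counts, p))
  }

  scan <- NULL
  if (isTRUE(stages$bsa)) {
    if (is.null(counts)) {
      p <- config$bsa$counts
      counts <- if (grepl("\\.vcf$", p)) read_pool_counts(p) else
        read_pool_counts_tsv(p)
    }
    scan <- bsa_scan(counts,
                     min_depth = config$bsa$min_depth %||% 4,
                     min_snps = config$regions$min_snps %||% 3,
                     max_gap = config$regions$max_gap %||% 2e5,
                     per_chromosome = isTRUE(config$regions$per_chromosome))
    emit("bsa", "bsa_stats.tsv", function(p)
      write.table(scan$stats, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("bsa", "thresholds.tsv", function(p)
      write.table(scan$thresholds, p, sep = "\t", quote = FALSE,
                  row.names = FALSE))
  }

  if (isTRUE(stages$regions)) {
    if (is.null(scan)) stop("regions stage requires the bsa stage",
                            call. = FALSE)
    wr <- function(df) function(p) write.table(df, p, sep = "\t",
                                               quote = FALSE,
                                               row.names = FALSE)
    emit("regions", "regions_delta.tsv", wr(scan$regions_delta))
    emit("regions", "regions_ed4.tsv", wr(scan$regions_ed4))
    emit("regions", "regions_common.tsv", wr(scan$regions_common))
    emit("regions", "regions_common.bed",
         function(p) regions_to_bed(scan$regions_common, p))
    if (!is.null(config$regions$qtl)) {
      qtl <- read.delim(config$regions$qtl, stringsAsFactors = FALSE)
      ov <- overlap_with_qtl(scan$regions_common, qtl[1, , drop = FALSE])
      emit("regions", "qtl_overlap.tsv", wr(ov$overlaps))
    }
  }

  if (isTRUE(stages$pheno)) {
    if (is.null(phenotypes)) {
      if (is.null(config$pheno$phenotypes)) {
        stop("pheno stage needs a phenotype table when simulate is off",
             call. = FALSE)
      }
      phenotypes <- read_phenotypes(config$pheno$phenotypes)
    }
    value_col <- setdiff(names(phenotypes), "plant_id")[1]
    summ <- pheno_summarize(phenotypes[[value_col]])
    emit("pheno", "pheno_summary.tsv", function(p)
      write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  emit("manifest", "run_config.yaml",
       function(p) yaml::write_yaml(config, p))
  manifest <- tibble(stage = unname(stage_of[names(paths)]),
                     file = names(paths),
                     md5 = unname(tools::md5sum(unlist(paths))))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, paths = paths, config = config))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Validates toggles and input paths before any work is done.
.validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(simulate = TRUE, bsa = TRUE, regions = TRUE, pheno = TRUE)
  config$stages <- utils::modifyList(defaults, config$stages %||% list())
  if (isTRUE(config$stages$bsa) && !isTRUE(config$stages$simulate)) {
    p <- config$bsa$counts
    if (is.null(p)) {
      stop("bsa stage enabled without simulate: config$bsa$counts is required",
           call. = FALSE)
    }
    if (!file.exists(p)) stop("counts input not found: ", p, call. = FALSE)
  }
  if (!is.null(config$regions$qtl) && !file.exists(config$regions$qtl)) {
    stop("QTL interval file not found: ", config$regions$qtl, call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1L
  config
}

#' Bundled genetic-map summary of the JF914 x JF173 cross
#'
#' Per-linkage-group marker counts, map lengths, mean marker intervals,
#' largest gaps and map/physical collinearity coefficients of the
#' high-density GBS linkage map of the JF914 x JF173 NFFB mapping cross,
#' with the published At/Dt subgenome and total rows.
#'
#' @param include_totals Keep the `At`, `Dt` and `total` rows (default TRUE).
#' @return Tibble: `chrom`, `n_markers`, `length_cm`, `mean_interval_cm`,
#'   `largest_gap_cm`, `collinearity`.
#' @export
genetic_map_summary <- function(include_totals = TRUE) {
  path <- system.file("extdata", "jf_map_summary.tsv", package = "bsaqtl")
  df <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  if (!include_totals) df <- df[!df$chrom %in% c("At", "Dt", "total"), ]
  df
}

#' Arithmetic cross-checks of the bundled map summary
#'
#' Recomputes, from the per-chromosome rows alone, the At/Dt/total marker
#' and map-length subtotals and every per-chromosome mean marker interval
#' (map length / (markers - 1)), and compares them with the stated values.
#' The stated At/Dt "mean interval" cells do not follow the
#' length/(markers-1) convention of the per-chromosome cells and are
#' therefore not recomputed.
#'
#' Marker-count subtotals are compared exactly; map-length subtotals to
#' `sum_tolerance` (summing 13-26 values printed at 2 decimals accumulates
#' rounding drift of a few hundredths of a cM); mean-interval cells to
#' `tolerance` (half the printed resolution).
#'
#' @param tolerance Absolute tolerance for recomputed per-cell values
#'   (default 0.005).
#' @param sum_tolerance Absolute tolerance for sums of printed values
#'   (default 0.02).
#' @return Tibble: `check`, `computed`, `stated`, `pass`.
#' @export
map_summary_checks <- function(tolerance = 0.005, sum_tolerance = 0.02) {
  full <- genetic_map_summary(include_totals = TRUE)
  per <- genetic_map_summary(include_totals = FALSE)
  at <- per[grepl("^A", per$chrom), ]
  dt <- per[grepl("^D", per$chrom), ]
  stated <- function(ch, col) full[[col]][full$chrom == ch]
  rows <- tibble(
    check = c("At_n_markers", "At_length_cm", "Dt_n_markers", "Dt_length_cm",
              "total_n_markers", "total_length_cm"),
    computed = c(sum(at$n_markers), sum(at$length_cm),
                 sum(dt$n_markers), sum(dt$length_cm),
                 sum(per$n_markers), sum(per$length_cm)),
    stated = c(stated("At", "n_markers"), stated("At", "length_cm"),
               stated("Dt", "n_markers"), stated("Dt", "length_cm"),
               stated("total", "n_markers"), stated("total", "length_cm"))
  )
  iv <- tibble(
    check = paste0(per$chrom, "_mean_interval_cm"),
    computed = per$length_cm / (per$n_markers - 1),
    stated = per$mean_interval_cm
  )
  rows$tol <- ifelse(grepl("n_markers", rows$check), 0, sum_tolerance)
  iv$tol <- tolerance
  out <- rbind(rows, iv)
  out$pass <- abs(out$computed - out$stated) <= out$tol + 1e-9
  out$tol <- NULL
  out
}

#' Bundled D3 candidate intervals and their arithmetic
#'
#' The stable NFFB QTL interval on chromosome D3 and the two BSA-seq
#' candidate regions that narrow it, with 1-based inclusive lengths, the
#' per-region overlap with the QTL, and the summed candidate span.
#'
#' @return List: `intervals` (tibble with `length_bp`), `overlaps` (the two
#'   BSA regions against the QTL), `bsa_total_bp` (summed BSA region
#'   lengths), `qtl_length_bp`.
#' @export
candidate_interval_report <- function() {
  path <- system.file("extdata", "nffb_d3_intervals.tsv", package = "bsaqtl")
  iv <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  iv$length_bp <- interval_length(iv$start, iv$end)
  qtl <- iv[iv$source == "QTL", ][1, ]
  bsa <- iv[iv$source == "BSA", ]
  ov <- overlap_with_qtl(bsa[, c("chrom", "start", "end")],
                         qtl[, c("chrom", "start", "end")])
  list(intervals = iv,
       overlaps = ov$overlaps,
       bsa_total_bp = sum(bsa$length_bp),
       qtl_length_bp = qtl$length_bp)
}
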