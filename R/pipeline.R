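## End-to-end pipeline wiring and a small command-line front end:
## simulate -> trim -> align -> classify -> report (-> cleave panel),
## with a machine-readable run manifest.

#' @importFrom jsonlite write_json read_json
NULL

log_stage <- function(...) {
  message("[pirnapipe ", format(Sys.time(), "%H:%M:%S"), "] ", ...)
}

#' Run the full pipeline on simulated data
#'
#' Simulates a genome and a read library for one genotype, trims, aligns,
#' classifies (stringent mode), normalizes, and writes tables, a coverage
#' track and a JSON manifest into `outdir`.
#'
#' @param config a [simulation_config()], or a list/JSON file of
#'   `simulation_config` arguments plus optional `genotype` (preset name,
#'   default `"wild_type"`).
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = simulation_config(), outdir) {
  genotype <- "wild_type"
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("missing input: config file '", config, "'", call. = FALSE)
    }
    config <- read_json(config, simplifyVector = TRUE)
  }
  if (!inherits(config, "simulation_config")) {
    config <- as.list(config)
    if (!is.null(config$genotype)) {
      genotype <- config$genotype
      config$genotype <- NULL
    }
    config <- do.call(simulation_config, config)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(x) file.path(outdir, x)

  log_stage("simulate: genotype ", genotype, ", ", config$n_reads, " reads")
  sim <- simulate_genome(config)
  lib <- simulate_reads(config, sim$genome, sim$annotation, genotype)
  write_genome(sim$genome, path("genome.fa"))
  write_gtf(sim$annotation, path("annotation.gtf"))
  write_chrom_sizes(sim$annotation$chrom_sizes, path("chrom.sizes"))
  write_fastq(lib$reads, path("raw.fastq"))
  write.table(lib$truth, path("ground_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  log_stage("trim")
  stats <- preprocess_fastq(path("raw.fastq"), path("trimmed.fastq"))
  write_trim_stats(stats, path("trim_stats.tsv"))

  log_stage("align")
  index <- build_index(sim$genome)
  aligned <- align_fastq(path("trimmed.fastq"), index, path("aligned.sam"))

  log_stage("classify")
  excl <- exclude_ambiguous_loci(sim$annotation)
  ann <- excl$annotation
  windows <- derive_precursor_windows(ann)
  write_gtf(windows, path("precursor_windows.gtf"))
  assignments <- classify_reads(aligned, ann, windows, mode = "stringent")
  denom <- compute_denominator(aligned, ann)
  if (denom == 0L) {
    stop("normalization error: sample '", genotype,
         "' has zero non-structural reads", call. = FALSE)
  }
  mature <- normalize_rpm(count_by_locus(assignments, ann, windows,
                                         "mature_type1", genotype), denom)
  prec <- normalize_rpm(count_by_locus(assignments, ann, windows,
                                       "precursor_type1", genotype), denom)
  write_count_table(mature, path("counts_mature_type1.tsv"))
  write_count_table(prec, path("counts_precursor_type1.tsv"))

  log_stage("report")
  track <- coverage_track(aligned, ann, denom)
  write_bedgraph(track, path("coverage.bedGraph"))

  manifest <- list(
    tool = "pirnapipe", version = as.character(packageVersion("pirnapipe")),
    seed = config$seed, genotype = genotype,
    config = unclass(config),
    counts = list(raw_reads = stats$total, kept = stats$kept,
                  rejected = as.list(stats$rejected),
                  mapped = sum(aligned$mapped),
                  unmapped = sum(!aligned$mapped),
                  denominator = denom,
                  excluded_locus_fraction = excl$excluded_fraction,
                  total_mature_rpm = sum(mature$rpm),
                  total_precursor_rpm = sum(prec$rpm)))
  write_json(manifest, path("manifest.json"), auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  log_stage("done: ", outdir)
  invisible(manifest)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("usage error: unexpected argument '", a, "'", call. = FALSE)
    }
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

cli_usage <- function() {
  cat("usage: pirnapipe <command> [--flag value ...]\n",
      "commands:\n",
      "  run-all   --out DIR [--seed N] [--genotype NAME] [--n-reads N]\n",
      "  simulate  --out DIR [--seed N] [--genotype NAME] [--n-reads N]\n",
      "  trim      --in FASTQ --out FASTQ [--stats TSV]\n",
      "  align     --genome FASTA --in FASTQ --out SAM\n",
      "  classify  --sam SAM --gtf GTF --chrom-sizes TSV --out-prefix P\n",
      "            [--mode stringent|relaxed]\n",
      "  report    --sam SAM --gtf GTF --chrom-sizes TSV --out BEDGRAPH\n",
      "  cleave    --out TSV\n", sep = "")
}

require_flags <- function(flags, keys) {
  missing <- setdiff(keys, names(flags))
  if (length(missing)) {
    stop("usage error: missing --", gsub("_", "-", missing[1L]),
         call. = FALSE)
  }
}

sim_config_from_flags <- function(flags) {
  args <- list()
  for (key in c("seed", "n_reads", "n_type1_loci", "chrom_length",
                "n_structural_loci", "n_ambiguous_overlaps")) {
    if (!is.null(flags[[key]])) args[[key]] <- as.integer(flags[[key]])
  }
  for (key in c("sequencing_error_rate", "structural_fraction",
                "offset_noise_rate")) {
    if (!is.null(flags[[key]])) args[[key]] <- as.numeric(flags[[key]])
  }
  do.call(simulation_config, args)
}

load_annotation_cli <- function(flags) {
  ann <- load_annotation(flags$gtf, flags$chrom_sizes)
  exclude_ambiguous_loci(ann)$annotation
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `trim`, `align`, `classify`, `report`,
#' `cleave` and `run-all` subcommands. See `inst/cli/pirnapipe` for the
#' Rscript wrapper.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit status, invisibly: 0 ok, 1 usage error, 2 data error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("-h", "--help", "help")) {
    cli_usage()
    return(invisible(if (length(args)) 0L else 1L))
  }
  cmd <- args[1L]
  status <- tryCatch({
    flags <- parse_flags(args[-1L])
    switch(cmd,
      "run-all" = {
        require_flags(flags, "out")
        cfg <- unclass(sim_config_from_flags(flags))
        cfg$genotype <- if (is.null(flags$genotype)) "wild_type" else
          flags$genotype
        run_pipeline(cfg, flags$out)
      },
      "simulate" = {
        require_flags(flags, "out")
        cfg <- sim_config_from_flags(flags)
        dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
        sim <- simulate_genome(cfg)
        lib <- simulate_reads(cfg, sim$genome, sim$annotation,
                              if (is.null(flags$genotype)) "wild_type" else
                                flags$genotype)
        write_genome(sim$genome, file.path(flags$out, "genome.fa"))
        write_gtf(sim$annotation, file.path(flags$out, "annotation.gtf"))
        write_chrom_sizes(sim$annotation$chrom_sizes,
                          file.path(flags$out, "chrom.sizes"))
        write_fastq(lib$reads, file.path(flags$out, "raw.fastq"))
        write.table(lib$truth, file.path(flags$out, "ground_truth.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      },
      "trim" = {
        require_flags(flags, c("in", "out"))
        stats <- preprocess_fastq(flags[["in"]], flags$out)
        if (!is.null(flags$stats)) write_trim_stats(stats, flags$stats)
      },
      "align" = {
        require_flags(flags, c("genome", "in", "out"))
        index <- build_index(read_genome(flags$genome))
        align_fastq(flags[["in"]], index, flags$out)
      },
      "classify" = {
        require_flags(flags, c("sam", "gtf", "chrom_sizes", "out_prefix"))
        ann <- load_annotation_cli(flags)
        windows <- derive_precursor_windows(ann)
        aligned <- read_sam(flags$sam)
        mode <- if (is.null(flags$mode)) "stringent" else flags$mode
        assignments <- classify_reads(aligned, ann, windows, mode = mode)
        denom <- compute_denominator(aligned, ann)
        for (cat in c("mature_type1", "precursor_type1")) {
          tab <- count_by_locus(assignments, ann, windows, cat,
                                mode = mode)
          if (denom > 0L) tab <- normalize_rpm(tab, denom)
          write_count_table(tab, paste0(flags$out_prefix, cat, ".tsv"))
        }
      },
      "report" = {
        require_flags(flags, c("sam", "gtf", "chrom_sizes", "out"))
        ann <- load_annotation_cli(flags)
        aligned <- read_sam(flags$sam)
        denom <- compute_denominator(aligned, ann)
        write_bedgraph(coverage_track(aligned, ann, denom), flags$out)
      },
      "cleave" = {
        require_flags(flags, "out")
        panel <- reference_panel()
        tab <- do.call(rbind, lapply(panel, function(p) {
          truth_table(list(p$s), list(p$e), list(p$c))
        }))
        rownames(tab) <- NULL
        write_truth_table(tab, flags$out)
      },
      {
        cli_usage()
        stop("usage error: unknown command '", cmd, "'", call. = FALSE)
      })
    0L
  }, error = function(e) {
    message("pirnapipe: ", conditionMessage(e))
    if (grepl("^usage error", conditionMessage(e))) 1L else 2L
  })
  invisible(status)
}
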