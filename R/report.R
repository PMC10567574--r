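## Sample-level summaries: per-category RPM totals with replicate group
## means, per-locus mutant-vs-wild-type comparison tables, and normalized
## per-base coverage tracks (bedGraph).

#' Per-sample category totals
#'
#' Sums RPM over loci for each sample's count table and reports replicate
#' group means, mirroring total-abundance dot plots with group-mean lines.
#'
#' @param tables named list of normalized `count_table`s (one per sample).
#' @param groups optional character vector (same length) assigning samples to
#'   replicate groups; defaults to each sample being its own group.
#' @return list with `samples` (data.frame: sample, group, total_raw,
#'   total_rpm) and `group_means` (data.frame: group, mean_rpm, n).
#' @export
total_by_category <- function(tables, groups = NULL) {
  stopifnot(length(tables) >= 1L)
  ids <- lapply(tables, function(t) sort(t$locus_id))
  if (!all(vapply(ids, identical, logical(1), y = ids[[1L]]))) {
    stop("count tables do not share the same locus universe", call. = FALSE)
  }
  samples <- names(tables)
  if (is.null(samples)) samples <- paste0("sample", seq_along(tables))
  if (is.null(groups)) groups <- samples
  df <- data.frame(
    sample = samples, group = groups,
    total_raw = vapply(tables, function(t) sum(t$raw), numeric(1)),
    total_rpm = vapply(tables, function(t) sum(t$rpm), numeric(1)),
    stringsAsFactors = FALSE)
  gm <- aggregate(total_rpm ~ group, df, mean)
  names(gm)[2L] <- "mean_rpm"
  gm$n <- as.integer(table(df$group)[gm$group])
  list(samples = df, group_means = gm)
}

#' Per-locus two-sample comparison
#'
#' Pairs the RPM of each locus in two samples and adds log10 values with a
#' pseudocount, ready for mutant-versus-wild-type scatter plots.
#'
#' @param table_a,table_b normalized `count_table`s over the same loci.
#' @param pseudocount positive offset added before log10 (default 0.1 RPM).
#' @return data.frame: `locus_id`, `rpm_a`, `rpm_b`, `log10_a`, `log10_b`.
#' @export
compare_samples <- function(table_a, table_b, pseudocount = 0.1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      is.na(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  if (!identical(sort(table_a$locus_id), sort(table_b$locus_id))) {
    stop("count tables do not share the same locus universe", call. = FALSE)
  }
  b <- table_b[match(table_a$locus_id, table_b$locus_id), , drop = FALSE]
  data.frame(locus_id = table_a$locus_id,
             rpm_a = table_a$rpm, rpm_b = b$rpm,
             log10_a = log10(table_a$rpm + pseudocount),
             log10_b = log10(b$rpm + pseudocount),
             stringsAsFactors = FALSE)
}

#' Normalized coverage track over piRNA loci
#'
#' Per-base depth of mapped 18-35-nt reads that overlap a piRNA locus in
#' sense orientation, scaled by 1e6 / denominator, as non-overlapping sorted
#' half-open runs (bedGraph convention). Zero-depth runs are omitted.
#'
#' @param reads aligned-reads data.frame.
#' @param annotation a `genome_annotation`.
#' @param denominator positive non-structural read count.
#' @return data.frame: `chrom`, `start`, `end`, `value`.
#' @export
coverage_track <- function(reads, annotation, denominator) {
  if (!is.numeric(denominator) || length(denominator) != 1L ||
      is.na(denominator) || denominator <= 0) {
    stop("normalization error: denominator must be positive", call. = FALSE)
  }
  len <- read_len(reads)
  use <- reads$mapped & !is.na(len) & len >= READ_MIN_LEN & len <= READ_MAX_LEN
  reads <- reads[use, , drop = FALSE]
  keep <- logical(nrow(reads))
  if (nrow(reads) && nrow(annotation$pirna)) {
    hits <- findOverlaps(gr_of(reads), gr_of(annotation$pirna))
    keep[unique(queryHits(hits))] <- TRUE
  }
  reads <- reads[keep, , drop = FALSE]
  scale <- 1e6 / denominator
  out <- list()
  for (chrom in sort(unique(reads$chrom))) {
    r <- reads[reads$chrom == chrom, , drop = FALSE]
    cov <- coverage(IRanges(r$start + 1L, r$end),
                    width = annotation$chrom_sizes[[chrom]])
    ends <- cumsum(runLength(cov))
    starts <- ends - runLength(cov) + 1L
    vals <- runValue(cov)
    nz <- vals > 0
    if (any(nz)) {
      out[[chrom]] <- data.frame(chrom = chrom, start = starts[nz] - 1L,
                                 end = ends[nz], value = vals[nz] * scale,
                                 stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a coverage track as bedGraph
#' @param track data.frame from [coverage_track()].
#' @param path output file (4 columns, 0-based half-open).
#' @export
write_bedgraph <- function(track, path) {
  writeLines(paste(track$chrom, track$start, track$end,
                   format(track$value, trim = TRUE, scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}

#' @importFrom stats aggregate
NULL
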