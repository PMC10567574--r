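## Genome annotation handling for piRNA (21U RNA) analysis.
##
## All coordinates held in memory are 0-based half-open; GTF (1-based,
## inclusive) and BED (0-based, half-open) are converted at the I/O boundary
## and nowhere else.

STRUCTURAL_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")
TYPE1_LENGTH <- 21L
PRECURSOR_OFFSET <- 2L

#' @importFrom GenomicRanges GRanges findOverlaps strand seqnames
#' @importFrom IRanges IRanges coverage slice
#' @importFrom S4Vectors queryHits subjectHits Rle runValue runLength
NULL

## GRanges view of an interval data.frame (0-based half-open -> 1-based)
gr_of <- function(df) {
  if (nrow(df) == 0L) return(GRanges())
  GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand)
}

empty_interval_df <- function(extra = character(0)) {
  base <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     stringsAsFactors = FALSE)
  for (col in extra) base[[col]] <- character(0)
  base
}

validate_intervals <- function(df, chrom_sizes, what) {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(df$start < 0L | df$start >= df$end)
  if (length(bad)) {
    stop(what, ": invalid interval at row ", bad[1L],
         " (need 0 <= start < end)", call. = FALSE)
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(what, ": invalid strand '", df$strand[bad[1L]], "' at row ", bad[1L],
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop(what, ": chromosome '", unknown[1L], "' not in chromosome sizes",
         call. = FALSE)
  }
  bad <- which(df$end > chrom_sizes[df$chrom])
  if (length(bad)) {
    stop(what, ": interval ends beyond chromosome at row ", bad[1L],
         call. = FALSE)
  }
  invisible(df)
}

new_genome_annotation <- function(pirna, structural, other, chrom_sizes) {
  validate_intervals(pirna, chrom_sizes, "piRNA loci")
  validate_intervals(structural, chrom_sizes, "structural loci")
  validate_intervals(other, chrom_sizes, "other features")
  if (anyDuplicated(pirna$locus_id)) {
    stop("duplicate piRNA locus_id: ",
         pirna$locus_id[duplicated(pirna$locus_id)][1L], call. = FALSE)
  }
  t1 <- pirna[pirna$pirna_type == "type1", , drop = FALSE]
  bad <- which(t1$end - t1$start != TYPE1_LENGTH)
  if (length(bad)) {
    stop("type-1 piRNA locus '", t1$locus_id[bad[1L]], "' is not ",
         TYPE1_LENGTH, " nt long", call. = FALSE)
  }
  structure(list(pirna = pirna, structural = structural, other = other,
                 chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:",
      sum(x$pirna$pirna_type == "type1"), "type-1 +",
      sum(x$pirna$pirna_type == "type2"), "type-2 piRNA loci,",
      nrow(x$structural), "structural loci,",
      nrow(x$other), "other features on",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

parse_gtf_attributes <- function(attr) {
  ## 'key "value"; key "value";' -> named list of character vectors
  out <- lapply(strsplit(attr, ";"), function(fields) {
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    m <- regmatches(fields, regexec('^(\\S+)\\s+"?([^"]*)"?$', fields))
    keys <- vapply(m, function(x) if (length(x) == 3L) x[2L] else NA_character_,
                   character(1))
    vals <- vapply(m, function(x) if (length(x) == 3L) x[3L] else NA_character_,
                   character(1))
    setNames(vals, keys)
  })
  out
}

#' Load a GTF annotation
#'
#' Parses a GTF stream and partitions its features into piRNA loci (gene
#' biotype `piRNA`), structural RNA loci (rRNA/tRNA/snRNA/snoRNA) and all
#' remaining features. GTF's 1-based inclusive coordinates are converted to
#' the package-internal 0-based half-open convention.
#'
#' @param path GTF file. Lines starting with `#` are ignored.
#' @param chrom_sizes named integer vector of chromosome lengths, or the path
#'   of a two-column tab-separated file.
#' @return a `genome_annotation` object with elements `pirna`, `structural`,
#'   `other` (data.frames) and `chrom_sizes`.
#' @export
load_annotation <- function(path, chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L &&
      file.exists(chrom_sizes)) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GTF line ", keep[which(nf != 9L)[1L]], " in ", path,
         ": expected 9 tab-separated fields, got ", nf[nf != 9L][1L],
         call. = FALSE)
  }
  if (length(fields) == 0L) {
    return(new_genome_annotation(
      empty_interval_df(c("locus_id", "pirna_type")),
      empty_interval_df("rna_class"),
      empty_interval_df("biotype"), chrom_sizes))
  }
  mat <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.integer(mat[, 4L]))
  end1 <- suppressWarnings(as.integer(mat[, 5L]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) {
    stop("malformed GTF line ", keep[bad[1L]], " in ", path,
         ": non-numeric coordinates", call. = FALSE)
  }
  attrs <- parse_gtf_attributes(mat[, 9L])
  get_attr <- function(key) {
    vapply(attrs, function(a) if (key %in% names(a)) a[[key]] else NA_character_,
           character(1))
  }
  df <- data.frame(
    chrom = mat[, 1L], feature = mat[, 3L],
    start = start1 - 1L, end = end1, strand = mat[, 7L],
    gene_id = get_attr("gene_id"),
    gene_biotype = get_attr("gene_biotype"),
    pirna_type = get_attr("pirna_type"),
    stringsAsFactors = FALSE)
  df$gene_id[is.na(df$gene_id)] <- paste0("feature_", seq_len(nrow(df)))[is.na(df$gene_id)]

  is_pirna <- !is.na(df$gene_biotype) & df$gene_biotype == "piRNA"
  is_struct <- !is.na(df$gene_biotype) & df$gene_biotype %in% STRUCTURAL_CLASSES

  pirna <- df[is_pirna, , drop = FALSE]
  pirna <- data.frame(locus_id = pirna$gene_id, chrom = pirna$chrom,
                      start = pirna$start, end = pirna$end,
                      strand = pirna$strand,
                      pirna_type = ifelse(is.na(pirna$pirna_type), "type1",
                                          pirna$pirna_type),
                      stringsAsFactors = FALSE)
  struct <- df[is_struct, , drop = FALSE]
  struct <- data.frame(chrom = struct$chrom, start = struct$start,
                       end = struct$end, strand = struct$strand,
                       rna_class = struct$gene_biotype,
                       stringsAsFactors = FALSE)
  oth <- df[!is_pirna & !is_struct, , drop = FALSE]
  oth <- data.frame(chrom = oth$chrom, start = oth$start, end = oth$end,
                    strand = oth$strand,
                    biotype = ifelse(is.na(oth$gene_biotype), oth$feature,
                                     oth$gene_biotype),
                    stringsAsFactors = FALSE)
  new_genome_annotation(pirna, struct, oth, chrom_sizes)
}

#' Add type-2 piRNA loci from a BED file
#'
#' BED is 0-based half-open, matching the internal convention; no coordinate
#' conversion is applied. Column 4 supplies locus ids.
#'
#' @param annotation a `genome_annotation`.
#' @param path BED file with at least 6 columns (name in 4, strand in 6).
#' @return the annotation with the loci appended as `pirna_type == "type2"`.
#' @export
add_type2_loci <- function(annotation, path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("type-2 BED needs >= 6 columns", call. = FALSE)
  extra <- data.frame(locus_id = as.character(bed[[4L]]),
                      chrom = as.character(bed[[1L]]),
                      start = as.integer(bed[[2L]]),
                      end = as.integer(bed[[3L]]),
                      strand = as.character(bed[[6L]]),
                      pirna_type = "type2", stringsAsFactors = FALSE)
  new_genome_annotation(rbind(annotation$pirna, extra), annotation$structural,
                        annotation$other, annotation$chrom_sizes)
}

#' Exclude ambiguous piRNA loci
#'
#' Removes every type-1 locus that overlaps (>= 1 bp) a same-strand feature
#' whose biotype is in `ambiguous_biotypes` — by default miRNAs, snoRNAs and
#' exons of other genes, which would make read assignment ambiguous.
#'
#' @param annotation a `genome_annotation`.
#' @param ambiguous_biotypes character vector of disqualifying biotypes.
#' @return list with `annotation` (filtered) and `excluded_fraction` (the
#'   removed fraction of type-1 loci; 0 when there are none).
#' @export
exclude_ambiguous_loci <- function(annotation,
                                   ambiguous_biotypes = c("miRNA", "snoRNA",
                                                          "exon")) {
  pirna <- annotation$pirna
  t1 <- which(pirna$pirna_type == "type1")
  if (length(t1) == 0L) {
    return(list(annotation = annotation, excluded_fraction = 0))
  }
  amb <- annotation$other[annotation$other$biotype %in% ambiguous_biotypes, ,
                          drop = FALSE]
  drop <- integer(0)
  if (nrow(amb) > 0L) {
    ## strand-aware overlap: GRanges findOverlaps treats +/- as incompatible
    hits <- findOverlaps(gr_of(pirna[t1, ]), gr_of(amb))
    drop <- t1[unique(queryHits(hits))]
  }
  frac <- length(drop) / length(t1)
  if (length(drop)) pirna <- pirna[-drop, , drop = FALSE]
  list(annotation = new_genome_annotation(pirna, annotation$structural,
                                          annotation$other,
                                          annotation$chrom_sizes),
       excluded_fraction = frac)
}

#' Derive precursor-counting windows
#'
#' For each type-1 locus, returns the single genomic base 2 nt upstream of
#' the locus 5' end in the direction of transcription: `start - 2` on the
#' plus strand, `end + 1` (0-based) on the minus strand. piRNA precursor 5'
#' ends fall exactly on these positions. Loci whose window would fall outside
#' the chromosome are dropped with a warning (a clipped window cannot anchor
#' a 5' end).
#'
#' @param annotation a `genome_annotation`.
#' @param offset upstream distance in nt (default 2).
#' @param include_type2 also derive windows for type-2 loci (default FALSE).
#' @return data.frame with `locus_id`, `chrom`, `start`, `end` (start + 1),
#'   `strand`, `pirna_type`.
#' @export
derive_precursor_windows <- function(annotation, offset = PRECURSOR_OFFSET,
                                     include_type2 = FALSE) {
  keep_types <- if (include_type2) c("type1", "type2") else "type1"
  loci <- annotation$pirna[annotation$pirna$pirna_type %in% keep_types, ,
                           drop = FALSE]
  if (nrow(loci) == 0L) {
    w <- empty_interval_df(c("locus_id", "pirna_type"))
    w$start <- integer(0); w$end <- integer(0)
    return(w[, c("locus_id", "chrom", "start", "end", "strand", "pirna_type")])
  }
  pos <- ifelse(loci$strand == "+", loci$start - offset,
                loci$end + offset - 1L)
  sizes <- annotation$chrom_sizes[loci$chrom]
  ok <- pos >= 0L & pos + 1L <= sizes
  if (any(!ok)) {
    warning(sum(!ok), " locus/loci dropped: precursor window off chromosome (",
            paste(loci$locus_id[!ok], collapse = ", "), ")", call. = FALSE)
  }
  data.frame(locus_id = loci$locus_id[ok], chrom = loci$chrom[ok],
             start = as.integer(pos[ok]), end = as.integer(pos[ok] + 1L),
             strand = loci$strand[ok], pirna_type = loci$pirna_type[ok],
             stringsAsFactors = FALSE)
}

#' Write an annotation or window set as GTF
#'
#' Emits 1-based inclusive GTF. `load_annotation(write_gtf(x))` is an
#' identity on annotations (up to row order).
#'
#' @param x a `genome_annotation` or a precursor-window data.frame.
#' @param path output file.
#' @export
write_gtf <- function(x, path) {
  fmt <- function(chrom, feature, start0, end0, strand, attrs) {
    if (length(chrom) == 0L) return(character(0))
    paste(chrom, "pirnapipe", feature, start0 + 1L, end0, ".", strand, ".",
          attrs, sep = "\t")
  }
  lines <- character(0)
  if (inherits(x, "genome_annotation")) {
    p <- x$pirna
    lines <- c(lines, fmt(p$chrom, "gene", p$start, p$end, p$strand,
      paste0('gene_id "', p$locus_id, '"; gene_biotype "piRNA"; pirna_type "',
             p$pirna_type, '";')))
    s <- x$structural
    if (nrow(s)) {
      lines <- c(lines, fmt(s$chrom, "gene", s$start, s$end, s$strand,
        paste0('gene_id "structural_', seq_len(nrow(s)), '"; gene_biotype "',
               s$rna_class, '";')))
    }
    o <- x$other
    if (nrow(o)) {
      feature <- ifelse(o$biotype == "exon", "exon", "gene")
      attr <- paste0('gene_id "other_', seq_len(nrow(o)), '";',
                     ifelse(o$biotype == "exon", "",
                            paste0(' gene_biotype "', o$biotype, '";')))
      lines <- c(lines, fmt(o$chrom, feature, o$start, o$end, o$strand,
                            trimws(attr)))
    }
  } else {
    lines <- fmt(x$chrom, "precursor_window", x$start, x$end, x$strand,
                 paste0('gene_id "', x$locus_id, '";'))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write chromosome sizes
#' @param chrom_sizes named integer vector.
#' @param path output file (two-column TSV).
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(paste(names(chrom_sizes), chrom_sizes, sep = "\t"), path)
  invisible(path)
}
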