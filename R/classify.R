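## Partition aligned 18-35-nt reads into structural / mature piRNA /
## piRNA precursor / other, count per locus, and normalize to reads per
## million non-structural reads.
##
## Definitions (stringent mode):
##   structural — >= 1 bp sense overlap with an rRNA/tRNA/snRNA/snoRNA locus;
##     assigned first and excluded from everything downstream, including the
##     normalization denominator.
##   mature     — exactly 21 nt, 5' base (as sequenced) is T, read contained
##     within a piRNA locus, same strand.
##   precursor  — 23-35 nt, 5'-most genomic position exactly on the locus's
##     -2 upstream window, same strand.
## Relaxed mode replaces the mature/precursor tests by any >= 1 bp sense
## overlap with the locus (mature) or window (precursor).
##
## The 5' base test reads the sequenced base: plus-strand reads must start
## with T; minus-strand reads are stored as their forward-strand projection
## (SAM convention) and must therefore end in A.

READ_MIN_LEN <- 18L
READ_MAX_LEN <- 35L
MATURE_LEN <- 21L
PRECURSOR_MIN_LEN <- 23L
PRECURSOR_MAX_LEN <- 35L

READ_CATEGORIES <- c("structural", "mature_type1", "mature_type2",
                     "precursor_type1", "precursor_type2",
                     "other_nonstructural")

read_len <- function(reads) reads$end - reads$start

## strand-aware 5'-most genomic position (0-based)
five_prime_pos <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

## 5' base as sequenced, from the forward-projected stored sequence
five_prime_is_T <- function(reads) {
  ifelse(reads$strand == "+",
         substr(reads$seq, 1L, 1L) == "T",
         substring(reads$seq, nchar(reads$seq)) == "A")
}

#' Is a read structural?
#'
#' @param reads aligned-reads data.frame (mapped rows).
#' @param annotation a `genome_annotation`.
#' @return logical vector: >= 1 bp same-strand overlap with any structural
#'   (rRNA/tRNA/snRNA/snoRNA) locus.
#' @export
is_structural <- function(reads, annotation) {
  out <- logical(nrow(reads))
  if (nrow(reads) == 0L || nrow(annotation$structural) == 0L) return(out)
  hits <- findOverlaps(gr_of(reads), gr_of(annotation$structural))
  out[unique(queryHits(hits))] <- TRUE
  out
}

#' Mature-piRNA read/locus pairs
#'
#' @param reads aligned-reads data.frame.
#' @param loci piRNA locus data.frame (`annotation$pirna`).
#' @return data.frame of qualifying (read index, locus index) pairs.
#' @keywords internal
mature_pairs <- function(reads, loci) {
  if (nrow(reads) == 0L || nrow(loci) == 0L) {
    return(data.frame(read = integer(0), locus = integer(0)))
  }
  ok <- read_len(reads) == MATURE_LEN & five_prime_is_T(reads)
  cand <- which(ok)
  if (!length(cand)) return(data.frame(read = integer(0), locus = integer(0)))
  hits <- findOverlaps(gr_of(reads[cand, , drop = FALSE]), gr_of(loci),
                       type = "within")
  data.frame(read = cand[queryHits(hits)], locus = subjectHits(hits))
}

#' Precursor read/window pairs
#'
#' @param reads aligned-reads data.frame.
#' @param windows precursor windows from [derive_precursor_windows()].
#' @return data.frame of qualifying (read index, window index) pairs: 23-35
#'   nt and 5' end exactly on the window position, same strand.
#' @keywords internal
precursor_pairs <- function(reads, windows) {
  if (nrow(reads) == 0L || nrow(windows) == 0L) {
    return(data.frame(read = integer(0), window = integer(0)))
  }
  len <- read_len(reads)
  cand <- which(len >= PRECURSOR_MIN_LEN & len <= PRECURSOR_MAX_LEN)
  if (!length(cand)) return(data.frame(read = integer(0), window = integer(0)))
  key_r <- paste(reads$chrom[cand], five_prime_pos(reads[cand, , drop = FALSE]),
                 reads$strand[cand])
  key_w <- paste(windows$chrom, windows$start, windows$strand)
  ## multi-assignment across identical windows is allowed (featureCounts -M)
  idx <- split(seq_along(key_w), key_w)
  m <- idx[key_r]
  n_each <- lengths(m)
  data.frame(read = rep(cand, n_each), window = unlist(m, use.names = FALSE))
}

#' Classify aligned reads
#'
#' Applies the category rules with structural precedence: a structural read
#' receives only the structural label. Non-structural reads may receive
#' multiple mature/precursor assignments across overlapping loci
#' (multi-overlap counting); reads matching nothing are
#' `other_nonstructural`.
#'
#' @param reads aligned-reads data.frame; unmapped or out-of-size-range rows
#'   are ignored.
#' @param annotation a `genome_annotation`.
#' @param windows precursor windows from [derive_precursor_windows()].
#' @param mode `"stringent"` (default) or `"relaxed"`.
#' @return data.frame with `read_id`, `category`, `locus_id` (NA for
#'   structural/other); one row per assignment.
#' @export
classify_reads <- function(reads, annotation, windows,
                           mode = c("stringent", "relaxed")) {
  mode <- match.arg(mode)
  len <- read_len(reads)
  use <- reads$mapped & !is.na(len) & len >= READ_MIN_LEN & len <= READ_MAX_LEN
  reads <- reads[use, , drop = FALSE]
  rownames(reads) <- NULL
  n <- nrow(reads)
  if (n == 0L) {
    return(data.frame(read_id = character(0), category = character(0),
                      locus_id = character(0), stringsAsFactors = FALSE))
  }
  struct <- is_structural(reads, annotation)
  ns <- which(!struct)
  nsr <- reads[ns, , drop = FALSE]
  loci <- annotation$pirna
  if (mode == "stringent") {
    mp <- mature_pairs(nsr, loci)
    pp <- precursor_pairs(nsr, windows)
  } else {
    mh <- if (nrow(nsr) && nrow(loci)) {
      findOverlaps(gr_of(nsr), gr_of(loci))
    } else S4Vectors::Hits()
    mp <- data.frame(read = queryHits(mh), locus = subjectHits(mh))
    ph <- if (nrow(nsr) && nrow(windows)) {
      findOverlaps(gr_of(nsr), gr_of(windows))
    } else S4Vectors::Hits()
    pp <- data.frame(read = queryHits(ph), window = subjectHits(ph))
  }
  assignment_df <- function(ids, category, locus) {
    data.frame(read_id = ids, category = rep_len(category, length(ids)),
               locus_id = rep_len(locus, length(ids)),
               stringsAsFactors = FALSE)
  }
  out <- list(
    assignment_df(reads$read_id[struct], "structural", NA_character_),
    assignment_df(nsr$read_id[mp$read],
                  paste0("mature_", loci$pirna_type[mp$locus]),
                  loci$locus_id[mp$locus]),
    assignment_df(nsr$read_id[pp$read],
                  paste0("precursor_", windows$pirna_type[pp$window]),
                  windows$locus_id[pp$window]))
  assigned <- unique(c(mp$read, pp$read))
  other <- setdiff(seq_len(nrow(nsr)), assigned)
  out[[4L]] <- assignment_df(nsr$read_id[other], "other_nonstructural",
                             NA_character_)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count reads per locus for one category
#'
#' @param assignments output of [classify_reads()].
#' @param windows precursor windows (defines the locus universe together
#'   with `annotation`).
#' @param annotation a `genome_annotation`.
#' @param category one of `"mature_type1"`, `"mature_type2"`,
#'   `"precursor_type1"`, `"precursor_type2"`.
#' @param sample_id label stored on the table.
#' @param mode counting mode label (`"stringent"`/`"relaxed"`).
#' @return a `count_table`: data.frame(`locus_id`, `raw`, `rpm` = NA until
#'   [normalize_rpm()]), with attributes `sample_id`, `mode`, `category`,
#'   `denominator` (NA until normalized).
#' @export
count_by_locus <- function(assignments, annotation, windows,
                           category = "mature_type1",
                           sample_id = "sample", mode = "stringent") {
  stopifnot(category %in% setdiff(READ_CATEGORIES,
                                  c("structural", "other_nonstructural")))
  universe <- if (startsWith(category, "precursor")) {
    windows$locus_id[windows$pirna_type == sub("precursor_", "", category)]
  } else {
    annotation$pirna$locus_id[annotation$pirna$pirna_type ==
                                sub("mature_", "", category)]
  }
  sel <- assignments[assignments$category == category, , drop = FALSE]
  unknown <- setdiff(unique(sel$locus_id), universe)
  if (length(unknown)) {
    stop("assignment references unknown locus_id: ", unknown[1L],
         call. = FALSE)
  }
  counts <- table(factor(sel$locus_id, levels = universe))
  tab <- data.frame(locus_id = universe, raw = as.integer(counts),
                    rpm = NA_real_, stringsAsFactors = FALSE)
  structure(tab, class = c("count_table", "data.frame"),
            sample_id = sample_id, mode = mode, category = category,
            denominator = NA_integer_)
}

#' Non-structural read count (normalization denominator)
#'
#' @param reads aligned-reads data.frame.
#' @param annotation a `genome_annotation`.
#' @return integer: mapped reads of 18-35 nt that are not structural. Each
#'   read counts once regardless of how many category assignments it has.
#' @export
compute_denominator <- function(reads, annotation) {
  len <- read_len(reads)
  use <- reads$mapped & !is.na(len) & len >= READ_MIN_LEN & len <= READ_MAX_LEN
  reads <- reads[use, , drop = FALSE]
  sum(!is_structural(reads, annotation))
}

#' Normalize a count table to reads per million non-structural reads
#'
#' @param table a `count_table`.
#' @param denominator non-structural read count from
#'   [compute_denominator()]; must be positive.
#' @return the table with `rpm = raw / denominator * 1e6` and the denominator
#'   recorded as an attribute.
#' @export
normalize_rpm <- function(table, denominator) {
  if (!is.numeric(denominator) || length(denominator) != 1L ||
      is.na(denominator) || denominator <= 0) {
    stop("normalization error: denominator must be a positive count (got ",
         deparse(denominator), ")", call. = FALSE)
  }
  table$rpm <- table$raw / denominator * 1e6
  attr(table, "denominator") <- as.integer(denominator)
  table
}

#' Write a count table as TSV
#' @param table a `count_table`.
#' @param path output file.
#' @export
write_count_table <- function(table, path) {
  out <- data.frame(locus_id = table$locus_id,
                    type = attr(table, "category"),
                    raw = table$raw, rpm = table$rpm)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
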