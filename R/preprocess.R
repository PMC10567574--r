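## Adapter trimming and size selection for NEXTflex-style small-RNA
## libraries: each sequenced read is 4 random bases + insert + 4 random
## bases + 3' adapter. Reads are kept when the adapter-trimmed length falls
## in [26, 43], i.e. inserts of 18-35 nt plus the 8 random bases, and the
## random bases are then stripped from both ends.

NEXTFLEX_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Trimming configuration
#'
#' @param adapter 3' adapter sequence. Default is the NEXTflex small-RNA
#'   adapter.
#' @param min_len,max_len kept post-adapter-trim length range, in nt,
#'   including the random bases (defaults 26 and 43).
#' @param random_bases_each_side randomized bases flanking the insert on each
#'   side (default 4).
#' @param min_adapter_overlap minimum adapter-prefix match length accepted at
#'   the 3' read end when the full adapter is absent (default 3).
#' @return a `trim_config` list.
#' @export
trim_config <- function(adapter = NEXTFLEX_ADAPTER, min_len = 26L,
                        max_len = 43L, random_bases_each_side = 4L,
                        min_adapter_overlap = 3L) {
  stopifnot(nchar(adapter) >= min_adapter_overlap,
            min_len >= 2L * random_bases_each_side + 1L,
            max_len >= min_len)
  structure(list(adapter = toupper(adapter), min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 random_bases_each_side = as.integer(random_bases_each_side),
                 min_adapter_overlap = as.integer(min_adapter_overlap)),
            class = "trim_config")
}

## Vectorised adapter localisation: returns the 0-based cut position (length
## of the retained prefix), or the full read length when no adapter is found.
## Earliest full match wins; otherwise the longest (>= min overlap) adapter
## prefix anchored at the read's 3' end.
adapter_cut_positions <- function(seqs, cfg) {
  n <- length(seqs)
  len <- nchar(seqs)
  pos <- regexpr(cfg$adapter, seqs, fixed = TRUE)
  cut <- ifelse(pos > 0L, pos - 1L, len)
  alen <- nchar(cfg$adapter)
  open <- pos <= 0L
  for (k in seq(alen - 1L, cfg$min_adapter_overlap)) {
    if (!any(open)) break
    idx <- which(open & len >= k)
    if (!length(idx)) next
    hit <- substring(seqs[idx], len[idx] - k + 1L, len[idx]) ==
      substr(cfg$adapter, 1L, k)
    cut[idx[hit]] <- len[idx[hit]] - k
    open[idx[hit]] <- FALSE
  }
  as.integer(cut)
}

#' Trim a single read
#'
#' Locates the 3' adapter, removes it and everything after, rejects the read
#' when the trimmed length is outside `[min_len, max_len]`, then strips the
#' randomized bases from both ends.
#'
#' @param sequence read sequence (character scalar).
#' @param cfg a [trim_config()].
#' @return list with `kept` (logical), and when kept: `insert`,
#'   `left_random`, `right_random`; when rejected: `reason` (one of
#'   `"empty"`, `"too_short"`, `"too_long"`).
#' @export
trim_read <- function(sequence, cfg = trim_config()) {
  res <- trim_reads(sequence, cfg)
  if (!res$kept[1L]) return(list(kept = FALSE, reason = res$reason[1L]))
  list(kept = TRUE, insert = res$insert[1L], left_random = res$left_random[1L],
       right_random = res$right_random[1L])
}

## Vectorised core used by trim_read and preprocess_fastq.
trim_reads <- function(seqs, cfg = trim_config()) {
  seqs <- toupper(seqs)
  n <- length(seqs)
  kept <- logical(n)
  reason <- rep(NA_character_, n)
  insert <- left <- right <- rep(NA_character_, n)
  empty <- !nzchar(seqs)
  reason[empty] <- "empty"
  act <- which(!empty)
  if (length(act)) {
    cut <- adapter_cut_positions(seqs[act], cfg)
    short <- cut < cfg$min_len
    long <- cut > cfg$max_len
    reason[act[short]] <- "too_short"
    reason[act[long]] <- "too_long"
    ok <- act[!short & !long]
    cutok <- cut[!short & !long]
    rb <- cfg$random_bases_each_side
    kept[ok] <- TRUE
    left[ok] <- substr(seqs[ok], 1L, rb)
    right[ok] <- substring(seqs[ok], cutok - rb + 1L, cutok)
    insert[ok] <- substring(seqs[ok], rb + 1L, cutok - rb)
  }
  data.frame(kept = kept, reason = reason, insert = insert,
             left_random = left, right_random = right,
             stringsAsFactors = FALSE)
}

#' Trim a FASTQ file
#'
#' @param in_path input FASTQ (raw reads).
#' @param out_path output FASTQ of trimmed inserts; qualities are subset to
#'   the insert bases when present.
#' @param cfg a [trim_config()].
#' @return invisibly, a `trim_stats` list: `total`, `kept`, `rejected`
#'   (named vector by reason) and `insert_length_histogram` (table).
#' @export
preprocess_fastq <- function(in_path, out_path, cfg = trim_config()) {
  reads <- read_fastq(in_path)
  res <- trim_reads(reads$sequence, cfg)
  keep <- which(res$kept)
  rb <- cfg$random_bases_each_side
  out <- data.frame(read_id = reads$read_id[keep],
                    sequence = res$insert[keep],
                    qualities = substring(reads$qualities[keep], rb + 1L,
                                          rb + nchar(res$insert[keep])),
                    stringsAsFactors = FALSE)
  write_fastq(out, out_path)
  rej <- table(res$reason[!res$kept])
  stats <- structure(list(
    total = nrow(reads), kept = length(keep),
    rejected = setNames(as.integer(rej), names(rej)),
    insert_length_histogram = table(nchar(res$insert[keep]))),
    class = "trim_stats")
  invisible(stats)
}

#' Write trimming statistics as a key/value report
#' @param stats a `trim_stats` object.
#' @param path output TSV.
#' @export
write_trim_stats <- function(stats, path) {
  kv <- function(prefix, x) {
    if (length(x) == 0L) return(character(0))
    paste0(prefix, names(x), "\t", as.integer(x))
  }
  lines <- c(paste("total", stats$total, sep = "\t"),
             paste("kept", stats$kept, sep = "\t"),
             kv("rejected.", stats$rejected),
             kv("insert_length.", stats$insert_length_histogram))
  writeLines(lines, path)
  invisible(path)
}
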