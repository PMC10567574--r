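## One-mismatch best-hit alignment of short inserts against a small genome.
##
## A k-mer seed index (default k = 9) covers both possible error positions:
## with at most one substitution, at least one of the two terminal k-mers of
## a read is exact, so candidate positions come from seed lookups at the
## read's 5' and 3' ends and are then verified by direct comparison. Reads
## are placed with 0 mismatches when possible, else 1 (best-stratum
## semantics); ties are broken deterministically by chromosome name, start
## and + before -, replacing the random single-report choice of production
## mappers so runs are reproducible.

ALIGN_SEED_K <- 9L

#' Build a k-mer index over a genome
#'
#' @param genome named character vector of chromosome sequences (A/C/G/T/N).
#' @param k seed length; must be at most half the shortest query (default 9,
#'   adequate for 18-35-nt inserts).
#' @return a `genome_index` object.
#' @export
build_index <- function(genome, k = ALIGN_SEED_K) {
  if (length(genome) == 0L || all(nchar(genome) == 0L)) {
    stop("empty genome", call. = FALSE)
  }
  genome <- vapply(genome, toupper, character(1))
  idx <- lapply(genome, function(seq) {
    L <- nchar(seq)
    env <- new.env(hash = TRUE, parent = emptyenv())
    if (L < k) return(env)
    starts <- seq_len(L - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    list2env(split(starts, kmers), envir = env)
  })
  structure(list(genome = genome, k = k, kmer_positions = idx,
                 chrom_sizes = chrom_sizes_of(genome)),
            class = "genome_index")
}

## candidate 1-based start positions for query q on one chromosome
seed_candidates <- function(q, chrom, index) {
  k <- index$k
  L <- nchar(q)
  tab <- index$kmer_positions[[chrom]]
  s1 <- get0(substr(q, 1L, k), envir = tab, inherits = FALSE)
  s2 <- get0(substring(q, L - k + 1L, L), envir = tab, inherits = FALSE)
  cand <- c(s1, if (!is.null(s2)) s2 - (L - k))
  Lc <- nchar(index$genome[[chrom]])
  unique(cand[!is.na(cand) & cand >= 1L & cand <= Lc - L + 1L])
}

## core placement: returns a plain list so callers can assemble columns
## without per-read data.frame overhead
align_one <- function(insert, index, max_mismatches, rc) {
  L <- nchar(insert)
  h_chrom <- character(0); h_start <- integer(0)
  h_strand <- character(0); h_mm <- integer(0); h_seq <- character(0)
  queries <- c("+" = insert, "-" = rc)
  for (chrom in names(index$genome)) {
    gseq <- index$genome[[chrom]]
    for (st in c("+", "-")) {
      q <- queries[[st]]
      cand <- seed_candidates(q, chrom, index)
      if (!length(cand)) next
      ref <- substring(gseq, cand, cand + L - 1L)
      qi <- utf8ToInt(q)
      mm <- vapply(ref, function(r) sum(utf8ToInt(r) != qi), integer(1),
                   USE.NAMES = FALSE)
      ok <- which(mm <= max_mismatches)
      if (length(ok)) {
        h_chrom <- c(h_chrom, rep(chrom, length(ok)))
        h_start <- c(h_start, cand[ok] - 1L)
        h_strand <- c(h_strand, rep(st, length(ok)))
        h_mm <- c(h_mm, mm[ok])
        h_seq <- c(h_seq, rep(q, length(ok)))
      }
    }
  }
  if (!length(h_mm)) {
    return(list(chrom = NA_character_, start = NA_integer_,
                end = NA_integer_, strand = NA_character_, seq = insert,
                mismatches = NA_integer_, mapped = FALSE))
  }
  ## best stratum, then deterministic tie-break
  o <- order(h_mm, h_chrom, h_start, h_strand != "+")[1L]
  list(chrom = h_chrom[o], start = h_start[o], end = h_start[o] + L,
       strand = h_strand[o], seq = h_seq[o], mismatches = h_mm[o],
       mapped = TRUE)
}

#' Align one insert
#'
#' @param insert trimmed insert sequence (18-35 nt typical; any length >= 2k
#'   works).
#' @param index a [build_index()] result.
#' @param max_mismatches maximum substitutions (0 or 1; default 1).
#' @param rc optional precomputed reverse complement of `insert` (a batch
#'   caller can reverse-complement all reads in one vectorised call).
#' @return one-row data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `seq` (forward-strand projection of the read, SAM
#'   convention), `mismatches`, `mapped`. Unmapped inserts have `mapped =
#'   FALSE` and NA coordinates.
#' @export
align_read <- function(insert, index, max_mismatches = 1L, rc = NULL) {
  insert <- toupper(insert)
  if (!is_dna(insert)) {
    stop("insert contains non-IUPAC characters: ", insert, call. = FALSE)
  }
  if (is.null(rc)) rc <- revcomp(insert)
  h <- align_one(insert, index, max_mismatches, rc)
  data.frame(chrom = h$chrom, start = h$start, end = h$end,
             strand = h$strand, seq = h$seq, mismatches = h$mismatches,
             mapped = h$mapped, stringsAsFactors = FALSE)
}

#' Align a set of inserts
#'
#' Deduplicates identical inserts before alignment (small-RNA libraries are
#' highly redundant), then expands the placements back to all reads.
#'
#' @param reads data.frame with `read_id` and `sequence`.
#' @param index a [build_index()] result.
#' @param max_mismatches maximum substitutions per read (default 1).
#' @return data.frame of aligned reads (`read_id`, `chrom`, `start`, `end`,
#'   `strand`, `seq`, `mismatches`, `mapped`), one row per input read.
#' @export
align_reads <- function(reads, index, max_mismatches = 1L) {
  seqs <- toupper(reads$sequence)
  bad <- which(!is_dna(seqs))
  if (length(bad)) {
    stop("insert contains non-IUPAC characters: ", seqs[bad[1L]],
         call. = FALSE)
  }
  uniq <- unique(seqs)
  rcs <- revcomp(uniq)
  hits <- lapply(seq_along(uniq), function(i)
    align_one(uniq[i], index, max_mismatches, rcs[i]))
  col <- function(name, template) {
    vapply(hits, `[[`, template, name)
  }
  placed <- data.frame(chrom = col("chrom", character(1)),
                       start = col("start", integer(1)),
                       end = col("end", integer(1)),
                       strand = col("strand", character(1)),
                       seq = col("seq", character(1)),
                       mismatches = col("mismatches", integer(1)),
                       mapped = col("mapped", logical(1)),
                       stringsAsFactors = FALSE)
  out <- placed[match(seqs, uniq), , drop = FALSE]
  out <- cbind(read_id = reads$read_id, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Align a trimmed FASTQ and write SAM
#'
#' @param fastq_path trimmed FASTQ (inserts).
#' @param index a [build_index()] result.
#' @param sam_path output SAM, coordinate-sorted, with `@SQ` header lines, a
#'   simple `<len>M` CIGAR and an `NM` tag.
#' @return invisibly, the aligned-reads data.frame.
#' @export
align_fastq <- function(fastq_path, index, sam_path) {
  reads <- read_fastq(fastq_path)
  aligned <- align_reads(reads, index)
  write_sam(aligned, index$chrom_sizes, sam_path)
  invisible(aligned)
}

#' Write aligned reads as SAM
#'
#' @param aligned data.frame from [align_reads()].
#' @param chrom_sizes named integer vector for the `@SQ` header.
#' @param path output SAM file.
#' @export
write_sam <- function(aligned, chrom_sizes, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(chrom_sizes), "\tLN:", chrom_sizes))
  m <- aligned[aligned$mapped, , drop = FALSE]
  m <- m[order(m$chrom, m$start), , drop = FALSE]
  u <- aligned[!aligned$mapped, , drop = FALSE]
  recs <- character(0)
  if (nrow(m)) {
    recs <- paste(m$read_id, ifelse(m$strand == "+", 0L, 16L), m$chrom,
                  m$start + 1L, 255L, paste0(nchar(m$seq), "M"), "*", 0L, 0L,
                  m$seq, "*", paste0("NM:i:", m$mismatches), sep = "\t")
  }
  if (nrow(u)) {
    recs <- c(recs, paste(u$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                          u$seq, "*", sep = "\t"))
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a SAM file of ungapped short-read alignments
#'
#' Accepts externally produced SAM as long as mapped records use all-match
#' CIGARs (`<len>M`), which is what both this package's aligner and the
#' ungapped mode of production small-RNA mappers emit.
#'
#' @param path SAM file.
#' @return aligned-reads data.frame as produced by [align_reads()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0),
                      mismatches = integer(0), mapped = logical(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  mapped <- bitwAnd(flag, 4L) == 0L
  seq <- toupper(get(10))
  cigar <- get(6)
  bad <- which(mapped & cigar != paste0(nchar(seq), "M"))
  if (length(bad)) {
    stop("unsupported CIGAR '", cigar[bad[1L]], "' in ", path,
         " (only ungapped <len>M records are supported)", call. = FALSE)
  }
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
  }, integer(1))
  start <- as.integer(get(4)) - 1L
  data.frame(read_id = get(1),
             chrom = ifelse(mapped, get(3), NA_character_),
             start = ifelse(mapped, start, NA_integer_),
             end = ifelse(mapped, start + nchar(seq), NA_integer_),
             strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) == 16L,
                                            "-", "+"), NA_character_),
             seq = seq, mismatches = nm, mapped = mapped,
             stringsAsFactors = FALSE)
}
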