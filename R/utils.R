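#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement
#' @importFrom stats rbinom rlnorm runif setNames
#' @importFrom utils write.table read.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

## Hamming distance between two equal-length strings; NA lengths disallowed.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

is_dna <- function(x) {
  !grepl("[^ACGTN]", x)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector, one element per chromosome. Names are
#'   truncated at the first whitespace, following common aligner behaviour.
#' @export
read_genome <- function(path) {
  ss <- readDNAStringSet(path)
  g <- as.character(ss)
  names(g) <- sub("\\s.*$", "", names(ss))
  toupper(g)
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  ss <- DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  writeXStringSet(ss, path)
  invisible(path)
}

chrom_sizes_of <- function(genome) {
  vapply(genome, nchar, integer(1))
}

#' Read a two-column chromosome-sizes file
#'
#' @param path tab-separated file: chromosome name, length.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "size"),
                    colClasses = c("character", "integer"))
  setNames(tab$size, tab$chrom)
}

## ---- FASTQ ----------------------------------------------------------------
## Parsed by hand (4-line records) so that malformed records can be reported
## by record index, which the contract requires.

#' Read a FASTQ file
#'
#' @param path FASTQ file (plain or gzip).
#' @return data.frame with columns `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines, not a multiple of 4", call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      qualities = character(0), stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path, call. = FALSE)
  }
  data.frame(read_id = sub("\\s.*$", "", substring(hdr, 2L)),
             sequence = seq, qualities = qual, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with `read_id`, `sequence` and optionally
#'   `qualities` (defaults to "I" per base).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qualities
  if (is.null(qual)) qual <- strrep("I", nchar(reads$sequence))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      qual), con)
  }
  invisible(path)
}

## deterministic per-stage seed derived from one root seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 101L, reads = 211L, trim = 307L, align = 401L,
               misc = 503L)
  (as.integer(seed) %% 1000000000L) * 2L + offsets[[stage]]
}
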