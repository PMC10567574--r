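# Independent reference implementations used as oracles. These are written
# as direct, quadratic translations of the classification/alignment rules
# and deliberately share no code with the package internals (no GRanges, no
# k-mer index).

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

# all alignments of `insert` with <= max_mm mismatches, by full scan of
# every position on both strands
oracle_align_all <- function(insert, genome, max_mm = 1L) {
  L <- nchar(insert)
  hits <- list()
  for (chrom in names(genome)) {
    gseq <- genome[[chrom]]
    n <- nchar(gseq) - L + 1L
    if (n < 1L) next
    refs <- substring(gseq, seq_len(n), seq_len(n) + L - 1L)
    for (st in c("+", "-")) {
      q <- if (st == "+") insert else oracle_revcomp(insert)
      qi <- utf8ToInt(q)
      mm <- vapply(refs, function(r) sum(utf8ToInt(r) != qi), integer(1),
                   USE.NAMES = FALSE)
      ok <- which(mm <= max_mm)
      if (length(ok)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = ok - 1L, end = ok - 1L + L, strand = st,
          mismatches = mm[ok], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# best-stratum, deterministically tie-broken single placement
oracle_align_best <- function(insert, genome, max_mm = 1L) {
  hits <- oracle_align_all(insert, genome, max_mm)
  if (is.null(hits)) return(NULL)
  hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  hits <- hits[order(hits$chrom, hits$start, hits$strand != "+"), ,
               drop = FALSE]
  hits[1L, , drop = FALSE]
}

# quadratic-scan reference classifier; returns the same assignment shape as
# classify_reads(), unsorted. Columns are pulled into plain vectors up
# front; the scan itself is an explicit read x feature double loop.
oracle_classify <- function(reads, annotation, windows,
                            mode = "stringent") {
  len <- reads$end - reads$start
  use <- reads$mapped & !is.na(len) & len >= 18L & len <= 35L
  reads <- reads[use, , drop = FALSE]
  rc <- reads$chrom; rs <- reads$start; re <- reads$end
  rst <- reads$strand; rid <- reads$read_id; rseq <- reads$seq
  s <- annotation$structural
  p <- annotation$pirna
  w <- windows
  o_id <- character(0); o_cat <- character(0); o_loc <- character(0)
  emit <- function(read_id, category, locus_id) {
    o_id <<- c(o_id, read_id); o_cat <<- c(o_cat, category)
    o_loc <<- c(o_loc, locus_id)
  }
  for (i in seq_along(rid)) {
    rl <- re[i] - rs[i]
    structural <- FALSE
    for (j in seq_len(nrow(s))) {
      if (s$chrom[j] == rc[i] && s$strand[j] == rst[i] &&
          rs[i] < s$end[j] && re[i] > s$start[j]) {
        structural <- TRUE
        break
      }
    }
    if (structural) {
      emit(rid[i], "structural", NA_character_)
      next
    }
    five <- if (rst[i] == "+") rs[i] else re[i] - 1L
    first_t <- if (rst[i] == "+") substr(rseq[i], 1L, 1L) == "T" else
      substring(rseq[i], nchar(rseq[i])) == "A"
    hit <- FALSE
    for (j in seq_len(nrow(p))) {
      mature <- if (mode == "stringent") {
        rl == 21L && first_t && p$chrom[j] == rc[i] &&
          p$strand[j] == rst[i] && rs[i] >= p$start[j] && re[i] <= p$end[j]
      } else {
        p$chrom[j] == rc[i] && p$strand[j] == rst[i] &&
          rs[i] < p$end[j] && re[i] > p$start[j]
      }
      if (mature) {
        emit(rid[i], paste0("mature_", p$pirna_type[j]), p$locus_id[j])
        hit <- TRUE
      }
    }
    for (j in seq_len(nrow(w))) {
      prec <- if (mode == "stringent") {
        rl >= 23L && rl <= 35L && w$chrom[j] == rc[i] &&
          w$strand[j] == rst[i] && five == w$start[j]
      } else {
        w$chrom[j] == rc[i] && w$strand[j] == rst[i] &&
          rs[i] < w$end[j] && re[i] > w$start[j]
      }
      if (prec) {
        emit(rid[i], paste0("precursor_", w$pirna_type[j]), w$locus_id[j])
        hit <- TRUE
      }
    }
    if (!hit) emit(rid[i], "other_nonstructural", NA_character_)
  }
  data.frame(read_id = o_id, category = o_cat, locus_id = o_loc,
             stringsAsFactors = FALSE)
}

# canonical ordering so assignment multisets can be compared exactly
sort_assignments <- function(df) {
  df <- df[order(df$read_id, df$category,
                 ifelse(is.na(df$locus_id), "", df$locus_id)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# hand-built annotation around explicit intervals (0-based half-open)
make_annotation <- function(pirna = NULL, structural = NULL, other = NULL,
                            chrom_sizes = c(chrI = 10000L)) {
  blank <- function(extra) {
    df <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     stringsAsFactors = FALSE)
    for (e in extra) df[[e]] <- character(0)
    df
  }
  if (is.null(pirna)) pirna <- blank(c("locus_id", "pirna_type"))
  if (is.null(structural)) structural <- blank("rna_class")
  if (is.null(other)) other <- blank("biotype")
  pirnapipe:::new_genome_annotation(pirna, structural, other, chrom_sizes)
}

pirna_row <- function(locus_id, chrom, start, strand = "+",
                      pirna_type = "type1", len = 21L) {
  data.frame(locus_id = locus_id, chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), strand = strand,
             pirna_type = pirna_type, stringsAsFactors = FALSE)
}

# aligned-read row builder; seq defaults to T followed by G's so the
# sequenced 5' base is T on either strand
read_row <- function(read_id, chrom, start, len, strand = "+", seq = NULL,
                     mapped = TRUE, mismatches = 0L) {
  sense <- if (is.null(seq)) paste0("T", strrep("G", len - 1L)) else seq
  fwd <- if (strand == "+") sense else oracle_revcomp(sense)
  data.frame(read_id = read_id, chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), strand = strand, seq = fwd,
             mismatches = mismatches, mapped = mapped,
             stringsAsFactors = FALSE)
}

# one GTF line (1-based inclusive), for parser tests
gtf_line <- function(chrom, start1, end1, strand, gene_id, biotype,
                     feature = "gene") {
  paste(chrom, "test", feature, start1, end1, ".", strand, ".",
        paste0('gene_id "', gene_id, '"; gene_biotype "', biotype, '";'),
        sep = "\t")
}
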