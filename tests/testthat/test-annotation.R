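test_that("GTF loading converts coordinates and partitions by biotype", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chrI", 1000, 1020, "+", "21ur-1", "piRNA"),
    gtf_line("chrI", 2000, 2100, "-", "rrn-1", "rRNA"),
    gtf_line("chrI", 3000, 3060, "+", "mir-1", "miRNA")), gtf)
  ann <- load_annotation(gtf, c(chrI = 10000L))
  expect_equal(ann$pirna$start, 999L)
  expect_equal(ann$pirna$end, 1020L)
  expect_equal(ann$pirna$end - ann$pirna$start, 21L)
  expect_equal(ann$pirna$pirna_type, "type1")
  expect_equal(nrow(ann$structural), 1L)
  expect_equal(ann$structural$rna_class, "rRNA")
  expect_equal(ann$other$biotype, "miRNA")
})

test_that("malformed GTF and invalid intervals are rejected with context", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chrI", 100, 120, "+", "x", "piRNA"),
               "chrI\tonly\tthree"), gtf)
  expect_error(load_annotation(gtf, c(chrI = 1000L)), "line 2")

  gtf2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf_line("chrI", 990, 1010, "+", "x", "piRNA"), gtf2)
  expect_error(load_annotation(gtf2, c(chrI = 1000L)), "beyond chromosome")

  gtf3 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf_line("chrI", 10, 25, "+", "short", "piRNA"), gtf3)
  expect_error(load_annotation(gtf3, c(chrI = 1000L)), "not 21 nt")
})

test_that("write_gtf / load_annotation round-trips a synthetic annotation", {
  cfg <- simulation_config(seed = 5, n_type1_loci = 40,
                           n_ambiguous_overlaps = 2)
  sim <- simulate_genome(cfg)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$annotation, gtf)
  back <- load_annotation(gtf, sim$annotation$chrom_sizes)
  norm <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(norm(back$pirna), norm(sim$annotation$pirna))
  expect_equal(norm(back$structural), norm(sim$annotation$structural))
  expect_equal(norm(back$other), norm(sim$annotation$other))
  ## load∘write∘load is a fixpoint
  gtf2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(back, gtf2)
  expect_identical(readLines(gtf), readLines(gtf2))
})

test_that("ambiguous-locus exclusion is same-strand, >=1 bp, idempotent", {
  loc <- rbind(pirna_row("a", "chrI", 100), pirna_row("b", "chrI", 300),
               pirna_row("c", "chrI", 500))
  other <- data.frame(
    chrom = "chrI",
    start = c(120L, 320L),           # a: 1 bp overlap; b: opposite strand
    end = c(200L, 400L),
    strand = c("+", "-"),
    biotype = c("miRNA", "miRNA"), stringsAsFactors = FALSE)
  ann <- make_annotation(pirna = loc, other = other)
  res <- exclude_ambiguous_loci(ann)
  expect_setequal(res$annotation$pirna$locus_id, c("b", "c"))
  expect_equal(res$excluded_fraction, 1 / 3)
  again <- exclude_ambiguous_loci(res$annotation)
  expect_equal(again$excluded_fraction, 0)
  expect_equal(again$annotation$pirna, res$annotation$pirna)
  ## empty annotation: fraction 0
  expect_equal(exclude_ambiguous_loci(make_annotation())$excluded_fraction, 0)
})

test_that("simulator-planted exon overlaps are excluded exactly", {
  cfg <- simulation_config(seed = 3, n_type1_loci = 40,
                           n_ambiguous_overlaps = 3)
  sim <- simulate_genome(cfg)
  res <- exclude_ambiguous_loci(sim$annotation)
  expect_equal(res$excluded_fraction, 0.075)
  expect_false(any(sim$truth$ambiguous_locus_ids %in%
                     res$annotation$pirna$locus_id))
})

test_that("precursor windows sit 2 nt upstream, strand-aware", {
  loc <- rbind(pirna_row("plus", "chrI", 999, "+"),
               pirna_row("minus", "chrI", 999, "-"))
  ann <- make_annotation(pirna = loc)
  w <- derive_precursor_windows(ann)
  expect_equal(w$start[w$locus_id == "plus"], 997L)
  expect_equal(w$end[w$locus_id == "plus"], 998L)
  expect_equal(w$start[w$locus_id == "minus"], 1021L)
  expect_equal(w$end[w$locus_id == "minus"], 1022L)
})

test_that("windows land 2 nt upstream of the 5'-most base for random loci", {
  set.seed(42)
  for (i in 1:50) {
    strand <- sample(c("+", "-"), 1)
    start <- sample(100:5000, 1)
    ann <- make_annotation(pirna = pirna_row("L", "chrI", start, strand))
    w <- derive_precursor_windows(ann)
    five_prime <- if (strand == "+") start else start + 21L - 1L
    ## walk 2 nt downstream in transcription direction from the window
    landing <- if (strand == "+") w$start + 2L else w$start - 2L
    expect_equal(landing, five_prime)
  }
})

test_that("boundary loci are dropped with a warning; counts match", {
  loc <- rbind(pirna_row("edge", "chrI", 0, "+"),
               pirna_row("edge2", "chrI", 9979, "-"),  # window at 10000
               pirna_row("ok", "chrI", 500, "+"))
  ann <- make_annotation(pirna = loc)
  expect_warning(w <- derive_precursor_windows(ann), "off chromosome")
  expect_equal(w$locus_id, "ok")
  ## window count equals retained locus count when nothing is at a boundary
  cfg <- simulation_config(seed = 8, n_type1_loci = 25)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(derive_precursor_windows(sim$annotation)), 25L)
})

test_that("type-2 loci load from BED and get windows only on request", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrI\t4000\t4021\t21ur-t2-1\t0\t-", bed)
  ann <- make_annotation(pirna = pirna_row("a", "chrI", 100))
  ann2 <- add_type2_loci(ann, bed)
  expect_equal(sum(ann2$pirna$pirna_type == "type2"), 1L)
  expect_equal(ann2$pirna$start[ann2$pirna$pirna_type == "type2"], 4000L)
  expect_equal(nrow(derive_precursor_windows(ann2)), 1L)
  w2 <- derive_precursor_windows(ann2, include_type2 = TRUE)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$start[w2$pirna_type == "type2"], 4022L)
})
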