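# One locus on each strand, a tRNA, and hand-placed reads exercise the
# classification rules; larger random instances are checked against the
# quadratic-scan oracle in test-acceptance.R.

fixture_annotation <- function() {
  make_annotation(
    pirna = rbind(pirna_row("Lp", "chrI", 1000, "+"),
                  pirna_row("Lm", "chrI", 2000, "-")),
    structural = data.frame(chrom = "chrI", start = 3000L, end = 3072L,
                            strand = "+", rna_class = "tRNA",
                            stringsAsFactors = FALSE))
}

test_that("structural calls require sense overlap", {
  ann <- fixture_annotation()
  inside <- read_row("s1", "chrI", 3010, 22, "+")
  anti <- read_row("s2", "chrI", 3010, 22, "-")
  off <- read_row("s3", "chrI", 3100, 22, "+")
  reads <- rbind(inside, anti, off)
  expect_equal(is_structural(reads, ann), c(TRUE, FALSE, FALSE))
})

test_that("mature calls need 21 nt, 5' T as sequenced, containment, sense", {
  ann <- fixture_annotation()
  win <- derive_precursor_windows(ann)
  ok_p <- read_row("m1", "chrI", 1000, 21, "+")            # exact locus
  bad_base <- read_row("m2", "chrI", 1000, 21, "+",
                       seq = paste0("A", strrep("G", 20)))
  shifted <- read_row("m3", "chrI", 999, 21, "+")          # 1 nt out
  anti <- read_row("m4", "chrI", 1000, 21, "-")
  ok_m <- read_row("m5", "chrI", 2000, 21, "-")            # minus locus
  asg <- classify_reads(rbind(ok_p, bad_base, shifted, anti, ok_m), ann, win)
  mature <- asg[asg$category == "mature_type1", ]
  expect_setequal(mature$read_id, c("m1", "m5"))
  expect_equal(mature$locus_id[mature$read_id == "m1"], "Lp")
  expect_equal(mature$locus_id[mature$read_id == "m5"], "Lm")
  expect_true(all(asg$category[asg$read_id %in% c("m2", "m3", "m4")] ==
                    "other_nonstructural"))
})

test_that("the sequenced-base rule judges a read by its own bases", {
  ## a read whose single mismatch sits at base 1: reference has no T, the
  ## read does -> mature by the sequenced base
  ann <- fixture_annotation()
  win <- derive_precursor_windows(ann)
  r <- read_row("mm1", "chrI", 1000, 21, "+", mismatches = 1L)
  asg <- classify_reads(r, ann, win)
  expect_equal(asg$category, "mature_type1")
  ## and conversely a read sequenced as A at base 1 is rejected even if the
  ## reference locus starts with T
  r2 <- read_row("mm2", "chrI", 1000, 21, "+",
                 seq = paste0("A", strrep("G", 20)), mismatches = 1L)
  expect_equal(classify_reads(r2, ann, win)$category, "other_nonstructural")
})

test_that("precursor calls key on the -2 five-prime position and 23-35 nt", {
  ann <- fixture_annotation()
  win <- derive_precursor_windows(ann)
  ## 5' ends at offsets -5..+5 around the plus-strand locus 5' end (1000),
  ## length 28; only the -2 offset (the window at 998) may qualify
  reads <- do.call(rbind, lapply(-5:5, function(off)
    read_row(paste0("p", off), "chrI", 1000 + off, 28, "+")))
  asg <- classify_reads(reads, ann, win)
  prec <- asg[asg$category == "precursor_type1", ]
  expect_equal(prec$read_id, "p-2")
  expect_equal(prec$locus_id, "Lp")
  ## minus strand: 5' end (end - 1) must equal the window start 2022
  pm <- read_row("pm", "chrI", 2023 - 28, 28, "-")
  expect_equal(classify_reads(pm, ann, win)$category[1], "precursor_type1")
  ## 21-nt read at the -2 position is not a precursor
  p21 <- read_row("p21", "chrI", 998, 21, "+")
  expect_false(any(classify_reads(p21, ann, win)$category ==
                     "precursor_type1"))
})

test_that("structural precedence short-circuits piRNA labels", {
  ann <- make_annotation(
    pirna = pirna_row("L", "chrI", 1000, "+"),
    structural = data.frame(chrom = "chrI", start = 990L, end = 1030L,
                            strand = "+", rna_class = "snoRNA",
                            stringsAsFactors = FALSE))
  win <- derive_precursor_windows(ann)
  r <- read_row("x", "chrI", 1000, 21, "+")  # qualifies as mature, but...
  asg <- classify_reads(r, ann, win)
  expect_equal(asg$category, "structural")
  expect_equal(nrow(asg), 1L)
})

test_that("multi-assignment across overlapping loci is retained", {
  loc <- rbind(pirna_row("A", "chrI", 1000, "+"),
               pirna_row("B", "chrI", 1000, "+", len = 21L))
  ann <- make_annotation(pirna = loc)
  win <- derive_precursor_windows(ann)
  r <- read_row("x", "chrI", 1000, 21, "+")
  asg <- classify_reads(r, ann, win)
  mature <- asg[asg$category == "mature_type1", ]
  expect_setequal(mature$locus_id, c("A", "B"))
})

test_that("relaxed mode includes every stringent assignment and more", {
  ann <- fixture_annotation()
  win <- derive_precursor_windows(ann)
  set.seed(31)
  reads <- do.call(rbind, lapply(1:150, function(i) {
    read_row(paste0("r", i), "chrI", sample(900:2100, 1), sample(18:35, 1),
             sample(c("+", "-"), 1),
             seq = paste(sample(c("A", "C", "G", "T"),
                                sample(18:35, 1), replace = TRUE),
                         collapse = ""))
  }))
  reads$end <- reads$start + nchar(reads$seq)
  strict <- classify_reads(reads, ann, win, mode = "stringent")
  relax <- classify_reads(reads, ann, win, mode = "relaxed")
  key <- function(df, cats) {
    df <- df[df$category %in% cats, ]
    paste(df$read_id, df$category, df$locus_id)
  }
  cats <- c("mature_type1", "precursor_type1")
  expect_true(all(key(strict, cats) %in% key(relax, cats)))
  ## an 18-nt sense overlap is relaxed-mature but never stringent-mature
  r18 <- read_row("short", "chrI", 1001, 18, "+")
  expect_false(any(classify_reads(r18, ann, win)$category == "mature_type1"))
  expect_true(any(classify_reads(r18, ann, win, mode = "relaxed")$category ==
                    "mature_type1"))
})

test_that("count_by_locus tabulates per locus over the right universe", {
  ann <- fixture_annotation()
  win <- derive_precursor_windows(ann)
  reads <- do.call(rbind, lapply(1:5, function(i)
    read_row(paste0("r", i), "chrI", 1000, 21, "+")))
  asg <- classify_reads(reads, ann, win)
  tab <- count_by_locus(asg, ann, win, "mature_type1")
  expect_equal(tab$raw[tab$locus_id == "Lp"], 5L)
  expect_equal(tab$raw[tab$locus_id == "Lm"], 0L)
  empty <- classify_reads(reads[0, ], ann, win)
  tab0 <- count_by_locus(empty, ann, win, "mature_type1")
  expect_equal(sum(tab0$raw), 0L)
  expect_equal(nrow(tab0), 2L)
  bad <- data.frame(read_id = "r", category = "mature_type1",
                    locus_id = "nope", stringsAsFactors = FALSE)
  expect_error(count_by_locus(bad, ann, win, "mature_type1"),
               "unknown locus_id")
})

test_that("denominator counts non-structural 18-35-nt mapped reads once", {
  ann <- fixture_annotation()
  reads <- rbind(
    do.call(rbind, lapply(1:70, function(i)
      read_row(paste0("n", i), "chrI", 500, 25, "+"))),
    do.call(rbind, lapply(1:30, function(i)
      read_row(paste0("s", i), "chrI", 3010, 22, "+"))))
  expect_equal(compute_denominator(reads, ann), 70L)
  ## all structural -> 0; unmapped and out-of-range reads don't count
  expect_equal(compute_denominator(reads[71:100, ], ann), 0L)
  un <- read_row("u", "chrI", 500, 25, "+", mapped = FALSE)
  long <- read_row("l", "chrI", 500, 36, "+")
  expect_equal(compute_denominator(rbind(un, long), ann), 0L)
})

test_that("RPM normalization is exact, refuses zero, scales inversely", {
  ann <- fixture_annotation()
  win <- derive_precursor_windows(ann)
  asg <- data.frame(read_id = paste0("r", 1:70), category = "mature_type1",
                    locus_id = "Lp", stringsAsFactors = FALSE)
  tab <- count_by_locus(asg, ann, win, "mature_type1")
  norm <- normalize_rpm(tab, 1e6)
  expect_equal(norm$rpm[norm$locus_id == "Lp"], 70)
  expect_equal(norm$rpm[norm$locus_id == "Lm"], 0)
  expect_error(normalize_rpm(tab, 0), "denominator")
  k <- 4
  n1 <- normalize_rpm(tab, 1000)
  nk <- normalize_rpm(tab, 1000 * k)
  expect_equal(nk$rpm * k, n1$rpm)
})

test_that("stringent mature and precursor are length-disjoint by design", {
  ann <- fixture_annotation()
  win <- derive_precursor_windows(ann)
  set.seed(77)
  for (i in 1:100) {
    len <- sample(18:35, 1)
    r <- read_row("x", "chrI", sample(980:1030, 1), len,
                  sample(c("+", "-"), 1))
    asg <- classify_reads(r, ann, win)
    cats <- asg$category
    expect_false(any(cats == "mature_type1") &&
                   any(cats == "precursor_type1"))
  }
})
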