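## Synthetic data with ground truth: random genomes carrying 21-nt type-1
## piRNA loci (genomic T at the locus 5' base, A/G-biased base 2 nt
## upstream, i.e. precursor position 1), structural RNA loci of the four
## contaminant classes, and genotype-aware read sets in which each locus
## emits 21-nt mature reads and 27-29-nt capped-precursor reads whose 5'
## ends sit exactly 2 nt upstream of the locus, wrapped as NEXTflex-style
## raw reads (4 random bases + insert + 4 random bases + adapter).

#' Simulation configuration
#'
#' @param seed root seed; per-stage seeds are derived deterministically.
#' @param n_chromosomes,chrom_length genome shape (default 1 x 50 kb).
#' @param n_type1_loci number of 21-nt type-1 piRNA loci (default 40).
#' @param n_type2_loci number of type-2 loci (default 0).
#' @param n_structural_loci structural RNA loci, assigned round-robin to
#'   rRNA/tRNA/snRNA/snoRNA (default 8).
#' @param n_ambiguous_overlaps type-1 loci additionally covered by a
#'   same-strand exon feature, for exclusion testing (default 0).
#' @param expression_meanlog,expression_sdlog log-normal per-locus expression
#'   weights (defaults 0 and 1: median-1, moderately dispersed relative
#'   abundances; the real dispersion is not known and this is a documented
#'   modeling choice).
#' @param n_reads total reads per library (default 1e5).
#' @param sequencing_error_rate per-base substitution rate in the insert
#'   (default 0: error-free, the condition under which ground-truth recovery
#'   is exact).
#' @param structural_fraction expected fraction of reads from structural
#'   loci (default 0.1).
#' @param offset_noise_rate fraction of precursor reads whose 5' end is
#'   displaced by +/-1 nt (default 0).
#' @param base_precursor_fraction wild-type baseline precursor share of a
#'   locus's transcripts (default 0.1 = 1 - wild-type mature fraction);
#'   genotype precursor multipliers scale this baseline.
#' @param pirna_fraction wild-type share of non-structural reads that are
#'   piRNA-derived (mature + precursor); the remainder is a
#'   genotype-independent background of other small RNAs drawn from
#'   dedicated ncRNA regions (default 0.1, a realistic 21U share of a total
#'   small-RNA library). This background anchors the RPM denominator so that
#'   normalized abundances track absolute piRNA changes across genotypes.
#' @param n_background_loci ncRNA regions emitting the background reads
#'   (default 30).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_chromosomes = 1L,
                              chrom_length = 50000L, n_type1_loci = 40L,
                              n_type2_loci = 0L, n_structural_loci = 8L,
                              n_ambiguous_overlaps = 0L,
                              expression_meanlog = 0,
                              expression_sdlog = 1, n_reads = 100000L,
                              sequencing_error_rate = 0,
                              structural_fraction = 0.1,
                              offset_noise_rate = 0,
                              base_precursor_fraction = 0.1,
                              pirna_fraction = 0.1,
                              n_background_loci = 30L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_type1_loci = as.integer(n_type1_loci),
              n_type2_loci = as.integer(n_type2_loci),
              n_structural_loci = as.integer(n_structural_loci),
              n_ambiguous_overlaps = as.integer(n_ambiguous_overlaps),
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              n_reads = as.integer(n_reads),
              sequencing_error_rate = sequencing_error_rate,
              structural_fraction = structural_fraction,
              offset_noise_rate = offset_noise_rate,
              base_precursor_fraction = base_precursor_fraction,
              pirna_fraction = pirna_fraction,
              n_background_loci = as.integer(n_background_loci))
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chrom_length >= 200L,
            cfg$n_type1_loci >= 0L, cfg$n_type2_loci >= 0L,
            cfg$n_structural_loci >= 0L, cfg$n_background_loci >= 0L,
            cfg$n_ambiguous_overlaps <= cfg$n_type1_loci,
            cfg$n_reads >= 0L,
            cfg$sequencing_error_rate >= 0, cfg$sequencing_error_rate <= 1,
            cfg$structural_fraction >= 0, cfg$structural_fraction < 1,
            cfg$offset_noise_rate >= 0, cfg$offset_noise_rate <= 1,
            cfg$base_precursor_fraction > 0, cfg$base_precursor_fraction <= 1,
            cfg$pirna_fraction > 0, cfg$pirna_fraction <= 1)
  structure(cfg, class = "simulation_config")
}

#' Genotype presets
#'
#' Effect sizes are modeling choices encoding the experimentally observed directions:
#' loss of mature piRNAs with precursor accumulation for the catalytic-dead
#' nuclease and the double SLFL knockout; strong mature reduction with
#' unchanged precursors when the membrane anchor is removed; reduced (but
#' not restored-to-WT) precursor accumulation when the precursor-stabilizing
#' complex is additionally lost.
#'
#' @return data.frame: `name`, `mature_fraction`, `precursor_multiplier`,
#'   `description`.
#' @export
genotype_profiles <- function() {
  data.frame(
    name = c("wild_type", "tofu2_E216A", "slfl34_null", "slfl3_dTM_slfl4",
             "tofu2_pid1"),
    mature_fraction = c(0.9, 0, 0.01, 0.05, 0),
    precursor_multiplier = c(1, 5, 5, 1, 2),
    description = c(
      "baseline: 90% of a locus's reads are mature 21U RNAs",
      "catalytic-dead nuclease: no mature piRNAs, precursors accumulate",
      "double SLFL knockout: near-total piRNA loss, precursors accumulate",
      "membrane-anchor deletion: strong mature loss, precursors unchanged",
      "nuclease-dead without precursor stabilization: no mature piRNAs, reduced precursor accumulation"),
    stringsAsFactors = FALSE)
}

#' Look up one genotype preset
#' @param name preset name from [genotype_profiles()].
#' @return one-row data.frame.
#' @export
genotype_profile <- function(name = "wild_type") {
  gp <- genotype_profiles()
  row <- gp[gp$name == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown genotype profile '", name, "'; available: ",
         paste(gp$name, collapse = ", "), call. = FALSE)
  }
  row
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

## place n features of the given lengths without overlap, keeping `pad`
## bases clear on each side so reads and upstream windows cannot straddle
## neighbouring features or chromosome ends
place_features <- function(lengths, chrom_names, chrom_length, pad = 40L) {
  n <- length(lengths)
  occupied <- lapply(chrom_names, function(x) {
    data.frame(start = integer(0), end = integer(0))
  })
  names(occupied) <- chrom_names
  chrom <- character(n)
  start <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(2000L)) {
      ch <- sample(chrom_names, 1L)
      s <- sample.int(chrom_length - lengths[i] - 2L * pad, 1L) + pad
      occ <- occupied[[ch]]
      if (!any(s - pad < occ$end & s + lengths[i] + pad > occ$start)) {
        occupied[[ch]] <- rbind(occ, data.frame(start = s,
                                                end = s + lengths[i]))
        chrom[i] <- ch
        start[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("configuration error: could not place all features in the genome; ",
           "increase chrom_length or reduce locus counts", call. = FALSE)
    }
  }
  data.frame(chrom = chrom, start = start, end = start + lengths,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

## overwrite one genome base, honouring strand (base given in sense)
set_sense_base <- function(genome, chrom, pos0, strand, base) {
  b <- if (strand == "+") base else complement_base(base)
  substr(genome[[chrom]], pos0 + 1L, pos0 + 1L) <- b
  genome
}

#' Simulate a genome and its annotation
#'
#' @param cfg a [simulation_config()].
#' @return list with `genome` (named character vector), `annotation`
#'   (a `genome_annotation`) and `truth` (placement record).
#' @export
simulate_genome <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "genome"))
  chrom_names <- paste0("chr", utils::as.roman(seq_len(cfg$n_chromosomes)))
  genome <- setNames(vapply(chrom_names, function(x)
    random_dna(cfg$chrom_length), character(1)), chrom_names)

  n1 <- cfg$n_type1_loci
  n2 <- cfg$n_type2_loci
  ns <- cfg$n_structural_loci
  nb <- cfg$n_background_loci
  struct_len <- if (ns) sample(60:120, ns, replace = TRUE) else integer(0)
  bg_len <- if (nb) sample(100:200, nb, replace = TRUE) else integer(0)
  placed <- place_features(c(rep(TYPE1_LENGTH, n1 + n2), struct_len, bg_len),
                           chrom_names, cfg$chrom_length)
  pirna <- placed[seq_len(n1 + n2), , drop = FALSE]
  pirna$locus_id <- sprintf("21ur-sim-%03d", seq_len(n1 + n2))
  pirna$pirna_type <- rep(c("type1", "type2"), c(n1, n2))
  pirna <- pirna[, c("locus_id", "chrom", "start", "end", "strand",
                     "pirna_type")]

  ## plant the sequence signals: T at the locus 5' base (mature 5'-U bias,
  ## precursor position 3), A/G-biased base at the -2 precursor start
  p1_bases <- sample(DNA_BASES, n1 + n2, replace = TRUE,
                     prob = c(0.45, 0.10, 0.35, 0.10))
  for (i in seq_len(n1 + n2)) {
    plus <- pirna$strand[i] == "+"
    five <- if (plus) pirna$start[i] else pirna$end[i] - 1L
    up2 <- if (plus) pirna$start[i] - 2L else pirna$end[i] + 1L
    genome <- set_sense_base(genome, pirna$chrom[i], five, pirna$strand[i],
                             "T")
    genome <- set_sense_base(genome, pirna$chrom[i], up2, pirna$strand[i],
                             p1_bases[i])
  }

  structural <- placed[seq_len(ns) + n1 + n2, , drop = FALSE]
  structural$rna_class <- rep(STRUCTURAL_CLASSES, length.out = max(ns, 1L))[
    seq_len(ns)]
  structural <- structural[, c("chrom", "start", "end", "strand", "rna_class")]

  ## background ncRNA regions: genotype-independent non-structural reads
  background <- placed[seq_len(nb) + n1 + n2 + ns, , drop = FALSE]
  if (nb) background$biotype <- "ncRNA"
  other <- if (nb) background[, c("chrom", "start", "end", "strand",
                                  "biotype")] else
    empty_interval_df("biotype")
  amb <- integer(0)
  if (cfg$n_ambiguous_overlaps > 0L) {
    amb <- sample.int(n1, cfg$n_ambiguous_overlaps)
    other <- rbind(other,
                   data.frame(chrom = pirna$chrom[amb],
                              start = pmax(pirna$start[amb] - 10L, 0L),
                              end = pmin(pirna$end[amb] + 10L,
                                         cfg$chrom_length),
                              strand = pirna$strand[amb], biotype = "exon",
                              stringsAsFactors = FALSE))
  }
  ann <- new_genome_annotation(pirna, structural, other,
                               chrom_sizes_of(genome))
  list(genome = genome, annotation = ann,
       truth = list(config = cfg,
                    ambiguous_locus_ids = pirna$locus_id[amb]))
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1L]]
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## vectorised sense-strand sequence extraction
sense_seq <- function(genome, chrom, start, end, strand) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[i] <- substring(genome[[ch]], start[i] + 1L, end[i])
  }
  minus <- which(strand == "-")
  if (length(minus)) out[minus] <- revcomp(out[minus])
  out
}

#' Simulate a read library for one genotype
#'
#' Per-locus expression is drawn log-normal; each locus's reads split into
#' mature (21 nt, coinciding with the locus) and precursor (27-29 nt, 5' end
#' at the -2 position) according to the genotype's mature fraction and
#' precursor multiplier applied to the wild-type precursor baseline;
#' structural reads are drawn sense from structural loci. Reads are emitted
#' as raw FASTQ-style sequences: 4 random bases + insert + 4 random bases +
#' adapter.
#'
#' @param cfg a [simulation_config()].
#' @param genome,annotation from [simulate_genome()].
#' @param profile one-row data.frame from [genotype_profile()], or a preset
#'   name.
#' @param adapter 3' adapter appended to every read.
#' @return list with `reads` (data.frame `read_id`, `sequence`, `qualities`)
#'   and `truth` (data.frame `read_id`, `category`, `locus_id`, `chrom`,
#'   `start`, `end`, `strand`, `insert`, `displaced`).
#' @export
simulate_reads <- function(cfg, genome, annotation,
                           profile = "wild_type",
                           adapter = NEXTFLEX_ADAPTER) {
  if (is.character(profile)) profile <- genotype_profile(profile)
  set.seed(stage_seed(cfg$seed, "reads"))
  loci <- annotation$pirna
  nl <- nrow(loci)
  w <- if (nl) rlnorm(nl, cfg$expression_meanlog, cfg$expression_sdlog) else
    numeric(0)
  W <- sum(w)
  mature_w <- w * profile$mature_fraction
  prec_w <- w * cfg$base_precursor_fraction * profile$precursor_multiplier
  bg_regions <- annotation$other[annotation$other$biotype == "ncRNA", ,
                                 drop = FALSE]
  ## background and structural weights are wild-type-referenced constants,
  ## so genotype effects change absolute piRNA read numbers, not the anchor
  bg_w <- if (nrow(bg_regions) > 0L && cfg$pirna_fraction < 1) {
    (1 - cfg$pirna_fraction) / cfg$pirna_fraction * W
  } else 0
  struct_w <- if (cfg$structural_fraction > 0 &&
                  nrow(annotation$structural) > 0L) {
    cfg$structural_fraction / (1 - cfg$structural_fraction) * (W + bg_w)
  } else 0
  probs <- c(mature_w, prec_w, bg_w, struct_w)
  if (sum(probs) <= 0) stop("no read sources have positive weight",
                            call. = FALSE)
  draw <- as.integer(rmultinom(1L, cfg$n_reads, probs))
  n_mat <- draw[seq_len(nl)]
  n_pre <- draw[nl + seq_len(nl)]
  n_bg <- draw[2L * nl + 1L]
  n_str <- draw[2L * nl + 2L]

  rows <- list()
  ## mature reads: the locus itself, in sense
  mi <- rep(seq_len(nl), n_mat)
  if (length(mi)) {
    rows$mature <- data.frame(
      category = paste0("mature_", loci$pirna_type[mi]),
      locus_id = loci$locus_id[mi], chrom = loci$chrom[mi],
      start = loci$start[mi], end = loci$end[mi], strand = loci$strand[mi],
      displaced = FALSE, stringsAsFactors = FALSE)
  }
  ## precursor reads: 5' at -2, length 27-29, optional +/-1 displacement
  pi <- rep(seq_len(nl), n_pre)
  if (length(pi)) {
    len <- sample(27:29, length(pi), replace = TRUE)
    disp <- runif(length(pi)) < cfg$offset_noise_rate
    shift <- ifelse(disp, sample(c(-1L, 1L), length(pi), replace = TRUE), 0L)
    plus <- loci$strand[pi] == "+"
    five <- ifelse(plus, loci$start[pi] - 2L, loci$end[pi] + 1L) +
      ifelse(plus, shift, -shift)
    start <- ifelse(plus, five, five - len + 1L)
    rows$precursor <- data.frame(
      category = paste0("precursor_", loci$pirna_type[pi]),
      locus_id = loci$locus_id[pi], chrom = loci$chrom[pi],
      start = as.integer(start), end = as.integer(start + len),
      strand = loci$strand[pi], displaced = disp, stringsAsFactors = FALSE)
  }
  ## background and structural reads: sense fragments inside their regions
  region_reads <- function(regions, n, category) {
    si <- sample.int(nrow(regions), n, replace = TRUE)
    sl <- regions[si, , drop = FALSE]
    maxlen <- pmin(READ_MAX_LEN, sl$end - sl$start)
    len <- READ_MIN_LEN + floor(runif(n) * (maxlen - READ_MIN_LEN + 1L))
    off <- floor(runif(n) * (sl$end - sl$start - len + 1L))
    data.frame(category = category, locus_id = NA_character_,
               chrom = sl$chrom, start = as.integer(sl$start + off),
               end = as.integer(sl$start + off + len), strand = sl$strand,
               displaced = FALSE, stringsAsFactors = FALSE)
  }
  if (n_bg > 0L) {
    rows$background <- region_reads(bg_regions, n_bg, "other_nonstructural")
  }
  if (n_str > 0L) {
    rows$structural <- region_reads(annotation$structural, n_str,
                                    "structural")
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth)) {
    truth <- data.frame(category = character(0), locus_id = character(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        displaced = logical(0), stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  n <- nrow(truth)
  truth <- cbind(read_id = sprintf("simread%06d", seq_len(n)), truth,
                 stringsAsFactors = FALSE)
  insert <- if (n) sense_seq(genome, truth$chrom, truth$start, truth$end,
                             truth$strand) else character(0)
  insert <- apply_errors(insert, cfg$sequencing_error_rate)
  truth$insert <- insert
  rand4 <- function(m) {
    if (m == 0L) return(character(0))
    b <- matrix(sample(DNA_BASES, 4L * m, replace = TRUE), ncol = 4L)
    paste0(b[, 1L], b[, 2L], b[, 3L], b[, 4L])
  }
  raw <- paste0(rand4(n), insert, rand4(n), adapter)
  reads <- data.frame(read_id = truth$read_id,
                      sequence = if (n) raw else character(0),
                      qualities = strrep("I", nchar(if (n) raw else
                        character(0))), stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Ground-truth per-locus counts
#'
#' Tabulates the simulator's planted read categories over a locus universe,
#' in the same shape as [count_by_locus()] output, for exact comparison.
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param locus_ids locus universe (e.g. `annotation$pirna$locus_id`).
#' @param category category to tabulate.
#' @return data.frame `locus_id`, `raw`.
#' @export
ground_truth_counts <- function(truth, locus_ids, category) {
  sel <- truth[truth$category == category, , drop = FALSE]
  counts <- table(factor(sel$locus_id, levels = locus_ids))
  data.frame(locus_id = locus_ids, raw = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' @importFrom stats rmultinom
NULL
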