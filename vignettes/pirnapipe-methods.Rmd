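---
title: "Methods: classifying C. elegans piRNAs and modeling PUCH specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying C. elegans piRNAs and modeling PUCH specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis problem

In *Caenorhabditis elegans*, mature piRNAs (21U RNAs) are 21-nt small RNAs
with a strong 5′-uridine bias, transcribed individually from thousands of
short genomic loci (type 1) and, much more rarely, from capped short
transcripts of other genes (type 2). Each mature piRNA derives from a
capped precursor of roughly 27–29 nt whose 5′ end lies exactly 2 nt
upstream of the mature 5′ end. The PUCH endonuclease — a trimer of the
single-SLFN-domain proteins TOFU-1, TOFU-2 and SLFL-3 or SLFL-4 — removes
the cap together with the first two nucleotides, cleaving between
precursor positions 2 and 3 and leaving the 5′-monophosphate that defines
the mature 5′ end.

Quantifying this system from small-RNA sequencing requires separating four
read populations that differ only in subtle positional and sequence
features: structural-RNA contamination, mature piRNAs, piRNA precursors,
and everything else. `pirnapipe` implements this classification as a
reusable, tested pipeline, together with a rule model of PUCH substrate
specificity and a synthetic-data generator that makes every stage testable
without any external download.

## Read processing

**Trimming** (`trim_config()`, `preprocess_fastq()`). Libraries follow the
NEXTflex small-RNA design: 4 randomized bases, the insert, 4 randomized
bases, then the 3′ adapter `TGGAATTCTCGGGTGCCAAGG`. The adapter is located
by its earliest exact full-length occurrence; when absent, an adapter
prefix of at least 3 nt anchored at the 3′ read end is accepted. Reads are
kept when the adapter-trimmed length lies in [26, 43] nt — inserts of
18–35 nt plus the 8 randomized bases — and the randomized bases are then
stripped. Two deliberate choices: adapter matching tolerates no mismatches
by default (the error model of the original trimming tool is not part of
the pipeline definition; a configurable overlap length is provided
instead), and reads without any adapter are kept when their full length is
in range, mirroring standard 3′-adapter semantics for inserts that run
into the maximum read length. Base qualities are carried through but never
used for filtering.

**Alignment** (`build_index()`, `align_reads()`). Inserts are placed on
the genome with at most one substitution, best stratum first: a read with
any 0-mismatch placement is never reported at 1 mismatch. Candidate
positions come from exact 9-mer seeds at both read ends (with one
substitution and reads of ≥ 18 nt, at least one terminal 9-mer is exact),
verified by direct comparison. Production mappers report one of several
equal-best hits at random; `pirnapipe` instead breaks ties
deterministically — lowest chromosome name, then lowest start, then plus
before minus — so that every run of the pipeline is exactly reproducible.
Stored sequences follow SAM convention (forward-strand projection). The
aligner targets the small genomes the simulator produces; externally
produced SAM from a production mapper can be ingested instead
(`read_sam()`), as long as records are ungapped.

Randomized-base removal happens at trim time rather than by trimming 4 nt
from each read end at alignment time; the two are arithmetically
identical for these libraries.

## Classification rules

All coordinates are held 0-based, half-open internally; GTF (1-based,
inclusive) is converted only at the I/O boundary. Given an annotation with
piRNA loci, structural loci (rRNA, tRNA, snRNA, snoRNA) and other
features, mapped reads of 18–35 nt are labeled in strict precedence order:

1. **Structural**: ≥ 1 bp overlap with a structural locus on the same
   strand. Structural reads are excluded from every downstream count *and*
   from the normalization denominator.
2. **Mature** (stringent): exactly 21 nt, 5′ base *as sequenced* is T,
   read contained entirely within a piRNA locus, same strand. Reading the
   sequenced base (not the reference) means a read whose single mismatch
   sits at base 1 is judged by its own 5′ nucleotide.
3. **Precursor** (stringent): 23–35 nt, 5′-most genomic position exactly
   on the locus's −2 upstream window, same strand; the 3′ end is
   unconstrained beyond the length gate. Windows are derived per type-1
   locus as `start − 2` (plus strand) or `end + 1` in 0-based coordinates
   (minus strand) — "upstream" on the minus strand means larger
   coordinates. Loci whose window would fall off the chromosome are
   dropped with a warning rather than clipped, because a clipped window
   cannot anchor a 5′ end.
4. **Other non-structural**: everything else.

A relaxed mode replaces rules 2–3 by any ≥ 1 bp sense overlap with the
locus or window. Stringent assignments are a strict subset of relaxed
ones. Reads may be assigned to several overlapping loci (multi-overlap
counting); this breaks count conservation and is therefore surfaced in the
output rather than hidden.

Type-1 loci that overlap a same-strand miRNA, snoRNA or exon of another
gene are ambiguous and removed before counting
(`exclude_ambiguous_loci()`); any overlap length (≥ 1 bp) disqualifies.
The biotype list is configurable since "other RNA exons" has no exhaustive
definition. Precursor windows are derived for type-1 loci by default;
type-2 loci can be included explicitly.

**Normalization.** Per-locus counts are scaled to reads per million
non-structural reads: `rpm = raw / denominator × 1e6`, where the
denominator counts each mapped, non-structural 18–35-nt read once,
regardless of how many locus assignments it received. A zero denominator
is an explicit error, never a silent division.

## The PUCH rule engine

`assess_substrate()` encodes the experimentally determined substrate
requirements as a deterministic decision: cleavage occurs iff the enzyme
is wild type with TOFU-1, TOFU-2 and at least one of SLFL-3/SLFL-4
present; the substrate carries an m⁷G cap (TMG, 5′-monophosphate and
5′-hydroxyl ends are rejected); position 3 is uridine; no EDTA; and the
divalent cation supports catalysis — Mg²⁺ or Mn²⁺ at ≥ 1 mM, Ca²⁺ only at
high concentration, Zn²⁺ never. "High" calcium defaults to 11 mM, the top
of the tested concentration series; both thresholds are configurable
parameters of the rule engine, since only the qualitative contrast is
established. When cleavage occurs, the product starts at former position
3, carries a 5′-monophosphate, and is 2 nt shorter than the substrate;
the verdict is invariant to everything beyond position 3. Rate is a
two-level class, not a kinetic constant: C at position 1 is `slow`, A/G
`fast`; U at position 1 was not assayed and maps to `fast` with an
explicit `position1_untested` flag. Mixtures show no competitive
inhibition: each substrate's outcome equals its solo outcome.

## The synthetic world

`simulate_genome()` plants non-overlapping features on a random genome
(default one 50-kb chromosome): 40 type-1 loci of exactly 21 nt with a
genomic T at the 5′ base (the mature 5′-U / precursor position-3 U) and an
A/G-biased base at the −2 position (precursor position 1; sampled A 0.45,
G 0.35, C 0.10, T 0.10), structural loci of the four contaminant classes,
and background ncRNA regions. A 40-bp clearance around every feature
guarantees that no read from one feature can touch another.

`simulate_reads()` draws per-locus expression from a log-normal
distribution (meanlog 0, sdlog 1 — the real per-locus dispersion is not
established; this is a documented assumption, not a claim) and splits each
locus's reads into mature (21 nt, locus-coincident) and precursor
(27–29 nt, 5′ end at −2) according to the genotype: expected mature reads
∝ `mature_fraction`, expected precursor reads ∝ the wild-type baseline
precursor share (0.1) times the genotype's `precursor_multiplier`.

Two structural choices matter for interpreting normalized results:

* **A genotype-independent background anchors the denominator.** Real
  libraries are dominated by small RNAs outside the piRNA pathway
  (miRNAs, 22G/26G siRNAs); piRNA-derived reads default to 10% of
  non-structural reads at wild type (`pirna_fraction`), and background
  and structural read weights are wild-type-referenced constants. Without
  this anchor, losing mature piRNAs in a mutant would mechanically
  inflate every other RPM value, and statements like "precursor levels
  unaffected" could not be expressed in RPM at all. With the anchor,
  normalized abundances track absolute piRNA changes to within the
  residual denominator shift (< 10% at the default mixture), which the
  3-standard-error acceptance bound absorbs.
* **Cap chemistry is not represented in reads.** Sequencing erases the
  cap; the two cap-proximal precursor nucleotides are genome-templated.
  Cap logic lives exclusively in the rule engine.

Genotype presets encode the experimentally observed directions with free effect sizes:
wild type (mature fraction 0.9), catalytic-dead nuclease (0, precursors
×5), double SLFL knockout (0.01, ×5), membrane-anchor deletion (0.05,
×1 — precursors unchanged), and nuclease-dead without precursor
stabilization (0, ×2 — reduced relative to the nuclease-dead ×5).
Sequencing errors (uniform substitutions) and precursor 5′-end
displacement (±1 nt) default to zero: the error-free setting is the one
under which ground-truth recovery is exact, and both noise sources are
switched on explicitly where tests probe robustness.

One root seed drives everything; per-stage seeds are derived
deterministically, so a fixed configuration yields byte-identical FASTA,
GTF and FASTQ on every run.

### What a green test does and does not establish

The simulator produces uniquely placed, non-overlapping features on a
uniform-random genome. Green end-to-end tests establish that the
implementation applies the stated rules exactly and that the arithmetic
(offsets, strand reflection, normalization) is correct. They do not
establish robustness to multi-mapping reads from repetitive regions,
overlapping or spliced gene models, non-uniform sequencing error
profiles, or adapter variants — real-data properties the generator does
not emulate.

## Numerical and degenerate-input choices

* Pseudocount for log-scatter comparisons: 0.1 RPM (typical log-scatter figures
  use zero-inflated log axes without stating the offset); it must be
  strictly positive.
* Group summaries are arithmetic means of replicate totals.
* Coverage tracks cover the full interval of every 18–35-nt read that
  sense-overlaps a piRNA locus, scaled by 1e6/denominator; the track sum
  therefore equals the summed lengths of contributing reads times the
  scale factor, which the tests assert exactly.
* Empty annotations, empty read sets and empty streams yield empty (not
  erroneous) results; malformed GTF/FASTQ records fail with the line or
  record index; intervals outside their chromosome fail validation.
* Ambiguous-locus exclusion on an annotation with no type-1 loci reports
  a removed fraction of 0.

## Known limitations

The internal aligner is a reference implementation for small genomes
(≲ 10 Mb): correct, deterministic and oracle-checked, but not
performance-comparable to production mappers, and without indel support.
Multi-exon piRNA genes, assembly liftover, UMI-based deduplication and
differential-expression statistics are out of scope. The rule engine
deliberately models relative cleavage speed as a class, not a rate
constant, and does not model the precursor-stabilizing complex's effect
on kinetics.
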