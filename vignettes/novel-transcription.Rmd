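---
title: "Finding unannotated transcription and classifying splice junctions with novotx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding unannotated transcription and classifying splice junctions with novotx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novotx)
```

`novotx` implements two complementary analyses of bulk RNA-seq evidence
against a gene annotation: window-based discovery of transcription in
intronic and intergenic space ("high coverage peaks", HCPs), and a
hierarchical seven-category classification of splice junctions. This
vignette is the package's own account of the underlying models, their
assumptions, the tunable parameters, and the design and numerical
choices that were genuinely open.

## The coverage model

The discovery statistic treats background read placement in
non-exonic space as a homogeneous Poisson process. Per compartment
(intronic, intergenic) with rate λ (reads per bp), the number of read
starts in a window of width *w* is Poisson with mean μ = λ·w, and a
window with *k* observed reads gets the upper-tail p-value P(X ≥ k).
This is a single-λ analogue of model-based peak calling as used for
ChIP-seq: no local (sliding) background is estimated, because the
compartments searched are precisely the regions where no annotation
exists to anchor a local model, and the background-eligible subset
(below) is deliberately far from everything annotated.

Assumptions worth stating explicitly:

* **Uniform background within a compartment.** Mappability variation,
  repeats and pre-mRNA gradients are not modelled; in real data they
  inflate the intronic rate near expressed genes and make the test
  conservative far from them. The intronic and intergenic rates are
  estimated independently for exactly this reason — intronic
  background (pre-mRNA) is systematically higher.
* **Each read counts once.** A read falls in the unique window
  containing its start coordinate (its 5′-most genomic base). For
  50 bp reads and ≥ 200 bp windows this is practically
  indistinguishable from fractional overlap assignment and guarantees
  exact count conservation; a config switch
  (`count_method = "overlap"`) counts a read in every window it
  touches instead. Strand is ignored, matching unstranded coverage.
* **Independence across windows.** BH-FDR assumes the usual positive
  dependence at worst; reads never span two windows' starts, so counts
  in disjoint windows are independent under the Poisson model.

### Background estimation

λ is the maximum-likelihood estimate of a homogeneous per-bp rate:
reads starting in the background regions divided by their total
length. Background-eligible regions are, by default:

| compartment | minimum untrimmed length | trim per end |
|-------------|--------------------------|--------------|
| intergenic  | > 1 Mb                   | 10 kb        |
| intronic    | > 300 kb                 | 1 kb         |

The length thresholds are strict and applied *before* trimming — the
natural reading of "long intervals, kept away from annotation edges";
measuring after trimming would only reclassify intervals within 2–20 kb
of the threshold and makes no practical difference at these scales.
The trims keep gene-boundary run-through (unannotated UTRs, pre-mRNA
edges) out of the estimate.

Two degeneracies are handled explicitly:

* **No eligible region** (common on small genomes): with
  `background_fallback = TRUE` the rate is estimated from the whole
  compartment minus a configurable edge buffer (1 kb per interval end
  by default), with a warning. The thresholds themselves are also
  configurable, so desk-scale analyses can lower them instead.
* **Zero background reads**: a pseudocount of one read over the
  background span is applied, with a warning, so p-values stay
  defined; the alternative (λ = 0) makes every non-empty window
  infinitely significant, which is never the wanted answer.

### Testing, correction, merging

Per window, μ = λ × *true* width: the final tile of a region may be
shorter than nominal, and scaling its expectation by true width lets
partial tiles be tested instead of discarded (discarding would blind
the caller within one window of every region edge). BH correction is
applied separately within the intronic and intergenic families — the
two families have independently estimated rates and different window
sizes, so their p-value distributions differ; `pool_fdr = TRUE` merges
them into one family if desired. The significance threshold defaults
to q ≤ 0.05 and is configurable.

Significant windows merge into an HCP while the gap between
consecutive ones is at most the nominal window size; this tolerates a
single interior window dipping below threshold without splitting a
peak, while two peaks separated by more than one window of background
stay distinct. Each HCP records its span, member-window count, total
reads and minimum q.

A numerical note on calibration: Poisson p-values are discrete. At
background means of order μ ≤ 1 the attainable significance levels are
far apart (for μ = 0.2 they are 0.181, 0.0175, 0.00115, ...), so the
fraction of null windows with p ≤ α equals the largest attainable
level ≤ α, which can sit well below α. The test is therefore
conservative, never anti-conservative; empirical type-I checks in the
test suite compare against the exact discrete null level rather than
against α itself.

### Flank scan

Transcription running past annotated transcript boundaries (extended
UTRs, upstream transcripts) is assessed with a ladder of windows —
50, 100, 200, 500 and 1000 bp by default — placed immediately upstream
of each TSS and downstream of each transcript end, strand-aware
(upstream of a minus-strand transcript extends toward larger
coordinates). The ladder is a fixed set of nested widths; nothing in
the method requires adaptivity, and a fixed ladder keeps the report
comparable across transcripts. Windows are scored against the
intergenic rate. The scan is reported *without* multiple-testing
correction by default: it is a coverage assessment keyed by transcript
and width, not a discovery family — a window overlapping another
gene's exon is flagged rather than removed, and windows truncated at a
chromosome edge are rescaled to their true width and flagged.

## The junction model

A junction's two anchor blocks are `[S, S + MOL)` and `[E − MOR, E)`,
with MOL/MOR the maximal overhangs over its supporting reads — exactly
the two blocks of a TopHat-dialect BED12 record, whose score carries
the read support. S < E always holds in genomic coordinates; on the
minus strand the 5′/3′ designations swap but nothing in the
classification depends on that. Records with other than two blocks, or
overlapping blocks, are rejected with a warning; duplicate junctions
(same chromosome, S, E, strand) are merged with supports summed before
filtering, so concatenated inputs are safe. The support filter
defaults to ≥ 3 reads, the usual high-confidence cutoff for de novo
junctions.

"Maps to an exon" means overlap of at least one base, half-open
(`intersectBed` semantics), strand-blind: a junction whose strand
contradicts the matched transcript is flagged in the output
(`strand_mismatch`), not vetoed, since antisense junctions are
themselves interesting. "Consecutive exons" means adjacent in genomic
order within one transcript — equivalent to transcription-order
adjacency on either strand, and strand-proof.

The hierarchy (annotated → exon skipping → only one side →
intra-exonic → different transcripts → trans-splicing →
intronic/intergenic) is evaluated strictly in order and the first
satisfied category wins, so a junction that is annotated in one
isoform but skipping in another is *annotated*. Three edge decisions:

* Both blocks in the same exon cannot satisfy categories 1–2 (those
  require two distinct exons with a positive rank gap), so the
  hierarchy reaches intra-exonic naturally.
* Category 5 requires that no single transcript contains both anchor
  exons; this is implied by the hierarchy (categories 1, 2 and 4 fire
  first otherwise) rather than tested separately.
* Category 6 does not require the two genes to be adjacent; adjacency
  in descriptions of trans-splicing between neighbouring genes is
  treated as descriptive, not definitional. The gene pair is recorded
  in the evidence so adjacency can be assessed downstream.

Exhaustiveness is structural: if both blocks hit exons they share a
transcript, share only a gene, or span two genes (categories 1/2/4, 5,
6); if one or neither hits, categories 3 or 7 apply. Every junction
receives exactly one category.

## What the simulator emulates — and what it does not

`simulation_config()` describes a desk-scale study that still
exercises the production constants: a 10 Mb chromosome with 8
non-overlapping genes on alternating strands, multi-exon transcripts
(4–8 exons of 120–300 bp, introns of 2–8 kb), two genes carrying a
400 kb intron and two intergenic gaps beyond 1 Mb — so the default
background-eligibility rules (1 Mb/10 kb, 300 kb/1 kb) select
non-empty region sets without any special-casing. Two genes get a
second isoform that skips one internal exon and adds an alternative
exon inside a different intron, which is the minimal structure that
makes every junction category constructible.

Reads are drawn as a homogeneous Poisson process at 0.01 reads/bp,
with planted regions (20 by default, placed in intronic and intergenic
space, 3–10 windows long, one window clear of compartment edges and
two windows clear of each other) receiving 10-fold that rate. The
background depth is a deliberate choice: a per-window power
calculation shows that at much shallower coverage (say 0.002 reads/bp,
i.e. μ = 0.4 per 200 bp window) a 10-fold enrichment yields ~4 reads
per window, which cannot reach significance after BH across tens of
thousands of windows — no method could recover such regions
window-wise. At 0.01 reads/bp (μ = 2 intronic, μ = 5 intergenic) a
10-fold signal is unambiguous, which is what a recovery benchmark
needs; calibration checks, by contrast, run at shallow depth on pure
background, where discreteness is the dominant effect (see above).
Fixed 50 bp read lengths are cosmetic — counting is by read start.

The simulator does **not** emulate: mappability structure or repeats,
sequencing error or alignment artifacts, fragment-length effects,
expression gradients along genes (pre-mRNA decay), overlapping genes,
or strand-specific coverage. Passing the closed-loop tests therefore
demonstrates correctness of the statistics and interval logic under
the stated model, not robustness to alignment pathology; on real data
the visual-inspection and external-evidence steps that normally follow
peak calling remain necessary.

Determinism: each generator call re-seeds from the configuration
(`seed`, `seed + 1`, `seed + 2` for annotation, reads and junctions),
so identical configurations give byte-identical output files, and the
three generators can be called independently.

## Problem sizes and runtime choices

The test suite and the acceptance script run everything at the sizes
above: ~10 Mb genomes (~10⁵ reads, ~2×10⁴ windows) for discovery,
1 Mb / 10,000-window compartments for calibration (20 replicates),
50 random ≤ 10 kb genomes for per-base brute-force comparisons, and
ten simulated genomes for junction closed loops. These sizes keep a
full run in minutes on one core while leaving every statistic in the
regime it is designed for; nothing in the implementation is
size-limited, and the interval machinery is the same
GenomicRanges-backed code at any scale.

## Known limitations

* A single λ per compartment cannot model locally elevated background;
  HCPs near highly expressed genes should be screened against
  pre-mRNA run-through (the flank scan helps).
* Window-based discovery quantises peak boundaries to the window grid;
  boundary accuracy is at best one window.
* The classifier trusts the annotation's exon coordinates exactly;
  off-by-a-few-bp splice sites in either input shift categories (a
  strict splice-site mode would trade sensitivity for precision and is
  not currently implemented).
* Junction support is taken from the input score; the package does not
  re-derive overhangs from alignments.
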