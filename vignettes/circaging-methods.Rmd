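---
title: "Models and methods behind circaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind circaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`circaging` implements a complete circRNA discovery, quantification and
aging differential-accumulation analysis, together with a synthetic-data
generator that produces studies with known ground truth. This vignette
explains the models, the tunable parameters and their defaults, the
numerical decisions, and what the synthetic studies do and do not
demonstrate about real data.

## The measurement problem

A circRNA is defined by its back-spliced junction: a downstream donor
joined to an upstream acceptor, out of order relative to the genome. Reads
internal to the circle are indistinguishable from host-mRNA reads, so all
identification and quantification rests on the small minority of reads
(well under 0.1 % of a ribo-depleted total RNA-seq library) that cross the
junction. The package therefore treats the junction as the unit of
annotation (`chrom`, `start`, `end`, `strand`; 0-based half-open, with
`start` the acceptor-exon start and `end` the donor-exon end) and every
quantity downstream is a junction-read count.

## De novo detection

Mates that align end-to-end nowhere on the genome or the spliced
transcriptome (substitution-only matcher, budget 2 mismatches) are split
into 20 nt terminal anchors. When both anchors place **uniquely** on one
chromosome with the tail anchor upstream of the head anchor, every split
position of the read is scored: the breakpoint must produce flanking
splice signals (genomic GT just 3' of `end` and AG just 5' of `start` for
plus-strand circles; CT/AC for minus-strand) and at most 2 total extension
mismatches. Exactly one best-scoring valid breakpoint is required — ties
are counted as ambiguous and the read is discarded rather than assigned
arbitrarily. Junctions are aggregated across libraries on the exact
coordinate key; support counts distinct junction reads (identical
sequences at one junction collapse, so PCR duplicates do not inflate
support) and the default threshold is 6 reads, one per library of a
two-age triplicate tissue.

Parameter defaults — anchor length 20 nt, unique anchors, 2 extension
mismatches, GT/AG (CT/AC) signals, 1 Mb maximum junction span — are the
published defaults of the split-anchor detection algorithm family this
module re-implements; the span cap bounds the breakpoint search and
excludes inter-locus artifacts.

The linear filter is a k-mer–seeded, substitution-only end-to-end matcher
(Rcpp): `max_mismatches + 1` disjoint segments per read guarantee by
pigeonhole that any qualifying placement has an exact seed. It is
deliberately indel-free: the simulator emits no indels, anchors are not
indel-tolerant, and with mismatch penalty 6, gap-open 5 and gap-extend 3 an
ungapped placement dominates any gapped alternative on indel-free data.
The same matcher serves anchor lookup and scaffold alignment, so one
compiled primitive backs all three alignment steps.

## Scaffold quantification

Each annotated junction gets a 200 nt scaffold: the last 100 **genomic** nt
before `end` concatenated with the first 100 genomic nt after `start`,
reverse-complemented for minus-strand circles so the scaffold reads 5'→3'
in transcript orientation. Flanks are genomic rather than spliced on
purpose — this reproduces the standard sequence-extraction approach — and
can therefore include intronic sequence when a terminal exon is shorter
than 100 nt; scaffolds of circles narrower than 200 nt carry an explicit
`short_overlap` flag. With 125 nt reads on 200 nt scaffolds, an end-to-end
placement necessarily crosses the junction with at least 25 nt on each
side, so the configurable `min_overhang` (default 10 nt, for shorter read
lengths) never binds in the default geometry.

Mates align end-to-end, both orientations, scored at −6 per mismatch with
a floor of −15 (so at most 2 mismatches); a mate tied between two
scaffolds is discarded as ambiguous, matching unique-read counting.
Duplicate removal collapses alignments on (scaffold, start, strand) within
a library — the single-end analogue of start-coordinate duplicate marking,
chosen because mates are mapped individually; the highest-scoring
alignment is kept with ties broken by read id, which makes the operation
idempotent and deterministic. Counting excludes fragments whose two mates
hit different scaffolds (no-chimera rule). The per-library total `N` is
linearly aligned mates plus retained junction mates — a depth-invariant
TPM denominator.

Two filters follow: the per-tissue expression filter retains a circRNA
when its summed count across the tissue's 6 libraries is at least 6 (no
per-library requirement; tissues with other library counts either error or,
optionally, scale the threshold proportionally), and the multi-gene filter
removes junctions whose two boundaries fall in exons of two different
genes with no common gene — the signature of near-identical paralog pairs,
which validation shows to be linearly spliced rather than back-spliced.
Intergenic junctions are kept and labelled `intergenic`.

## Expression analysis

* **TPM**: `count * 1e6 / N`. **FPKM**: unique-pair exon-union counting,
  `assigned * 1e9 / (union_len * total_assigned)` — a deliberately simple
  quantifier, not an isoform deconvolution engine.
* **Differential test**: two-sided Welch t-test per feature on the
  normalized values (raw scale by default, log optional), fold change
  `(mean_old + eps)/(mean_young + eps)` with `eps` the normalized
  equivalent of half a read, preventing infinite fold changes at zero
  means while leaving well-measured features essentially untouched. Welch
  rather than pooled-variance because n = 3 per group makes the equal
  variance assumption untestable. The 1.5-fold cutoff is inclusive.
  circRNA results are uncorrected (each tissue's circRNA set is small and
  the original analysis made the same choice, stated openly); linear-RNA
  results use Benjamini–Hochberg and the adjusted p drives status calls.
  Degenerate inputs are flagged: both groups constant and equal gives
  p = 1, constant and unequal gives p = 0.
* **Global shift**: Mann–Whitney U on pooled old vs pooled young values,
  normal approximation with tie correction and continuity correction,
  reporting U, z and the two-sided P. For small untied groups (both sizes
  at most 50) the exact U distribution is used instead, which is the
  conventional switch and is what the test-suite's enumeration oracle
  checks; the pooled whole-set comparison always uses the approximation.
* **Independence analysis**: joint status counts (how many up circRNAs
  have up host mRNAs), per-circle ratio tests on `TPM/(FPKM + eps)`, and a
  density table of (log2 linear FC, log2 circ FC) pairs whose
  circ-axis-only shift is the signature of host-independent accumulation.
  Intergenic circles are excluded from ratio and density computations and
  counted separately.
* **PCA**: `log10(x + 1)`, feature-centered, unscaled SVD. A pseudocount
  of 1 keeps zero counts finite; variance fractions sum to 1 except for a
  constant matrix, which returns all-zero scores and fractions by
  convention.

## The synthetic-data generator

The generator emulates the target study design: three tissues (cortex,
hippocampus, heart) x two ages x three replicates, paired-end 125 nt
reads, biological-triplicate groups. Defaults were chosen once, as the
study conditions, and are not tuned per analysis:

* Toy genome: 3 chromosomes x 1 Mb, 150 genes, 3–8 exons of 120–400 nt,
  introns 200–800 nt, uniform random sequence with planted strand-aware
  splice dinucleotides. Exons of at least 120 nt keep 100 nt scaffold
  flanks fully exonic, so the scaffold oracle is exact; real genomes have
  shorter terminal exons, which is why the `short_overlap`/intronic-flank
  caveat exists at all.
* circRNAs: 40 host genes (5 with a second circle), acceptor exon drawn
  with mode at exon 2 and probability 0 at exon 1 (a first exon has no
  upstream acceptor site, so no back-splice can land there); the donor
  avoids the terminal exon for the symmetric reason. Members are the
  contiguous acceptor..donor exon block.
* Abundances: log-normal across transcripts and circles (meanlog 0,
  sdlog 1); the age effect multiplies designated circles (20 % up x2, 5 %
  down x2 by default) in the brain tissues at the old age only, leaving
  host linear abundances untouched — circular/linear independence holds by
  construction, which is exactly what the independence oracle needs.
* Reads: fragments Gaussian (300 ± 50 nt, truncated to
  [read length, 2x read length + 200]), inner-facing FR pairs, sense mate
  randomized for unstranded-equivalent data (a `stranded` flag exists
  because strandedness handling in the original mapping step is not
  documented); circular fragments are drawn from the circular permutation
  of the mature circle sequence, fragments longer than the circle are
  rejected (no rolling-circle multi-lap reads), and circles shorter than
  the read length are skipped with a warning. Substitution errors at
  1e-3 per base by default (no indels, no instrument error profiles);
  PCR duplicates re-emit both mates verbatim with probability 0.05 —
  exactly what start-coordinate deduplication can detect. Qualities are
  constant because nothing downstream reads them.
* Calibration: circle sampling weights are scaled once, at baseline
  multipliers, so that the expected fraction of junction-crossing
  fragments matches `circ_fraction_of_reads` (default 5e-4, the sub-0.1 %
  regime); calibrating per library would silently cancel the very age
  effect being studied.
* Ground truth records every junction-crossing mate with donor- and
  acceptor-side overhangs, so true counts can be recomputed at any
  overhang threshold: 20 nt (anchor length) for the detection oracle and
  25 nt (read length minus flank) for the end-to-end quantification
  oracle. Because start-coordinate deduplication can also collapse two
  genuine fragments that happen to share a start, the truth tables make
  those natural collisions computable and the test suite asserts exact
  set equality of removed reads (injected duplicates plus predicted
  collisions) rather than a weakened count comparison.
* Determinism: every random draw descends from the single study seed via
  named substreams (per stage and per library), so stages are individually
  reproducible and identical configurations give byte-identical FASTQ and
  truth output.

A count-level companion (`simulate_count_study()`) draws deduplicated
junction counts directly as Poisson variates for the statistical
calibration studies (type-I error at 3 vs 3, power and fold-change
recovery at mean 50 with fold 2, global-shift behavior), where thousands
of circles are needed and per-read detail adds nothing.

What passing these oracles does **not** show: performance on real genomes
with repeats and paralogs (the toy genome is uniform random, so anchor
uniqueness is almost free), indel and quality-dependent errors, rRNA
contamination, pre-mRNA/intronic reads (mature transcripts only by
design), isoform-resolved circles (alternative internal splicing within
one junction is collapsed), or rolling-circle reads.

## microRNA seed sites

Canonical site types against a family seed `s` (microRNA bases 2–8):
7mer-m8 is an exact match to `rc(s)`; 7mer-A1 is `rc(s[1:6])` followed by
an A in the target; an 8mer is both. Every position reports its best type
only — an 8mer is not double-counted as its component 7mers — and
overlapping sites are all reported. Sites are scanned on the locus
sequence in transcript orientation, converted to genomic intervals, and
restricted to sites fully inside annotated exons (circles have their
introns spliced out, so intronic or boundary-straddling sites are not real
target sequence). Conservation requires a same-family site (any canonical
type by default; a strict-type flag exists because the original analysis
does not state which rule it used) in the aligned columns of every other
species, with per-species gap removal so a site shifted by an alignment
gap still counts. The shipped 20-family mouse seed table is a small
editable stand-in for a full broadly-conserved family list, which is an
external database artifact. 6mer sites are excluded: the canonical
7–8 nt types are the defensible default when no type breakdown is stated.

## Pipeline and reproducibility

`run_all()` chains detection → annotation merge → multi-gene filter →
scaffolds → quantification → expression filter → TPM/FPKM → per-tissue
differential, shift and independence analyses → features/overlap/PCA →
optional seed-site scan, writing each stage's table into the results
directory plus a `summary.json`. Re-running over an existing
`summary.json` with `overwrite = FALSE` is a no-op (file-presence caching,
not content-addressed). `run_simulate()`/`load_study()` round-trip a study
through standard formats (FASTA, GTF with gene/transcript/exon/CDS
features, paired FASTQ, TSV truth tables). The `cli` surface of the
package is these R functions; no shell wrapper is shipped because the
intended users drive analyses from R.

Problem sizes used in the shipped tests and acceptance script — a ~3 Mb /
150-gene / ~200k-pair study for the detection and quantification oracles,
2000-circle count studies for calibration, a 600 kb / 12k-fragment
single-tissue study for the independence analysis — were chosen as the
smallest designs at which each property is statistically identifiable;
they run on one CPU in minutes.

## Known limitations

* The multi-gene filter removes every flagged locus; reported counts of
  flagged loci are the filter's own, and no attempt is made to rescue
  genuinely multi-genic read-through circles.
* FPKM is exon-union and unique-pair only; genes with heavy isoform
  switching would need a real quantifier.
* The independence ratio test inherits the noise of both TPM and FPKM;
  with triplicates it is descriptive rather than decisive.
* Detection sensitivity is bounded by anchor length: junction reads with
  less than 20 nt on either side are invisible to the detector (they are
  still counted by scaffold quantification down to 25 nt overhangs).
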