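---
title: "Methods: genome-wide discovery of bacterial small RNAs from strand-specific read data"
author: "srnascout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide discovery of bacterial small RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnascout)
```

# The discovery problem

Bacterial small RNAs (sRNAs, roughly 50--350 nt) are found by sequencing the
small-RNA fraction of total RNA and mapping the reads back to the genome.
Two obstacles dominate the analysis. First, read pileups alone do not
distinguish genuine transcription units from degradation products of mRNAs,
so candidate calling must impose explicit coverage thresholds. Second, a
mapped 5' read end does not reveal whether it is a transcription start site
(TSS) or a processing site. The dRNA-seq design this package models resolves
the second problem with two libraries from the same RNA pool: sample 1
(`s1_primary`) is enzymatically enriched for primary transcripts, which
retain their 5'-triphosphate, while sample 2 (`s2_processed`) favors
processed, 5'-monophosphorylated RNA. A 5'-end supported by sample 1 is
evidence of a TSS; an end seen only in sample 2 is a processing product.

`srnascout` implements the full downstream analysis: coverage-based
transcription-unit ("contig") calling, distinct 5'/3'-end detection with
primary/processed labeling, positional classification against the
annotation, promoter scanning, structure well-definedness scoring,
small-ORF/RBS screening, and two hybridization-based candidate filters. A
first-class synthetic-data module generates genomes, annotations and reads
with known ground truth so that every stage is testable end to end.

# Contig calling

Coverage is accumulated per replicon, strand and library: `depth[i]` counts
reads whose alignment contains position `i`; `starts5`/`ends3` count
biological read ends (on the minus strand the 5'-end is the higher
coordinate). A contig is called by a seed-and-extend rule with parameters
$(L_{\min}, L_{\max}, C, c)$:

* a *seed* is a maximal run of positions with depth $\ge C$ of length at
  least $L_{\min}$;
* the surrounding contig is the maximal run of depth $\ge c$ containing the
  seed.

"Covered by at least $C$ reads" is interpreted as per-position depth, not as
$C$ distinct reads spanning the whole seed; positional depth is the standard
reading and is what makes extension by the lower threshold $c$ well defined.
Seed runs never merge across positions below $c$ (runs are maximal
intervals). Defaults follow the long-read preset $(50, 350, 10, 5)$
(`contig_params_454()`); the short-read preset $(50, 5, 2)$ is
`contig_params_illumina()`. Contigs that extend beyond $L_{\max}$ are
retained but flagged `over_length` rather than truncated: with a sequencing
protocol that size-selects RNA below ~350 nt, longer calls indicate a
misconfigured simulation or contamination, not observable biology. Both
libraries are pooled for depth by default; unstranded (total-RNA) libraries
are excluded from strand-specific calling unless explicitly enabled, since
their strand cannot be recovered.

# Distinct ends and primary/processed labels

Within a called contig, a position $p$ is a *distinct 5'-end* when

* $p$ lies within the first two bases of the contig (strand-aware) and more
  than 5 reads share it as their 5'-end ("more than 5" is read strictly:
  at least 6), or
* $p$ lies elsewhere, more than 5 reads share it, *and* the shared count is
  at least 10% of the contig's mean depth (mean depth = total depth over the
  contig divided by its length, pooled over the libraries being
  interrogated).

Symmetric rules apply to 3'-ends. Counts of distinct ends are summarized as
categories 0, 1, 2 or m (more than two). Ends one or two nucleotides apart
are reported separately by default because closely spaced alternative ends
are a real phenomenon; a `merge_radius` is available for reporting.

A 5'-end is labeled *primary* exactly when it is a distinct 5'-end of the
s1 library; presence in s1 is treated as sufficient even when the s2 count
is much larger, because the enrichment step, not the count ratio, carries
the evidence. Ends found only in s2 are processed.

# Positional classification

Each gene $g$ defines a *minimal transcription unit* (MTU): its CDS extended
by an assumed 5'-UTR of 60 nt and 3'-UTR of 20 nt. The same two constants
drive both the trans-exclusion rule and the UTR-overlap subtypes, which is
the only way the geometry stays self-consistent. The decision order per
overlapping gene, evaluated strand-aware in the gene's own frame, is:

1. **orf_cover** -- same strand, contig covers the entire CDS;
2. **leader** -- same strand, contig 5'-end within the 40 nt upstream of the
   start codon (or 1 nt into it) and 3'-end strictly inside the CDS;
3. **sense** -- same strand, any other MTU overlap. Subtype 1: 5'-end in the
   remaining 5'-UTR band (-60..-41) with the 3'-end in the CDS; subtype 2:
   fully inside the CDS; subtype 3: overlapping the CDS and reaching into
   the 3'-UTR; subtype 4: starting inside the 3'-UTR. The -60..-41 band for
   subtype 1 is this package's resolution of the boundary between a leader
   (a 5'-UTR long enough to support translation initiation) and a sense
   sRNA whose leader would be too short; it makes the leader and sense
   classes disjoint. A contig lying wholly inside one UTR, which the
   subtype list does not anticipate, falls back to the subtype of the
   region it overlaps.
4. **antisense** -- opposite strand, MTU overlap; subtypes 1/2/3 for the
   5'-UTR, CDS and 3'-UTR, joined (e.g. `"1/2"`) when several regions are
   touched;
5. **trans** -- no MTU overlap on either strand; type 1 when the nearest
   flanking gene on each side (either strand) runs antisense to the contig,
   else type 2.

Same-strand relations take precedence over antisense, and the class order
above (most to least gene-coupled) resolves multi-gene ambiguity
deterministically; multiple genes of the winning class yield joined
subtypes. Contigs overlapping annotated rRNA, tRNA or repeat features are
excluded before classification; contigs overlapping transposase genes are
classified but flagged `te_associated` for separate reporting. A leader may
not extend past the CDS 3'-end -- such a contig covers the CDS and is
orf_cover. Candidate clusters are single-linkage chains of candidates
separated by strictly less than 200 nt, reported at size two and larger.

# Promoter model

The $\sigma^{70}$ promoter is modeled as two width-6 position-specific
scoring matrices (-35 box, -10 box) separated by a variable spacer of 15--19
nt (the printed consensus spacer of 17 plus or minus 2), with the -10 box
required to end within 10 nt upstream of the TSS. Column probabilities are
pseudocount-smoothed counts, $P(b) = (n_b + q)/(n + 4q)$ with $q = 0.01$,
scored as $\log_2 P(b)/\pi(b)$ against a 0-order background $\pi$; the
genome's own base composition is the least-assuming background and is the
default for genome scans. Exact score P-values -- the probability that a
background word scores at least $s$ -- are computed by convolving the
per-column score distributions on a lattice of $10^{-4}$ bits per bin; the
test suite asserts lattice P-values equal full word enumeration for widths
up to 6 (the per-column key rounding is absorbed by a slack of one bin per
column, far below any real score gap).

A placement is reported when the product of the two box P-values falls at
or below the cutoff. The default cutoff, 2.155343e-11, is kept from the
published wide-matrix search this model descends from, and it is provably
out of reach for a two-box score: the P-value of any hit is bounded below by
the background probability of the 12 consensus bases, about $1.6\times
10^{-8}$ at 62% GC (and never below $0.19^{12} \approx 2\times 10^{-9}$ for
any realistic composition). Only a matrix with many informative columns --
for example one trained on real promoters whose spacers are themselves
biased -- can reach such cutoffs. Scans meant to find two-box hits should
therefore configure a cutoff in the $10^{-6}$--$10^{-8}$ range; the package
deliberately does not silently substitute one. The literal consensus
`CTTGAC-N17-CTATAT` matcher is independent of the probabilistic model and
reports every (possibly overlapping) occurrence.

# Structure well-definedness: abstract shapes and Z-scores

Whether a transcript folds into a *well-defined* structure is measured not
by its minimum free energy but by how much Boltzmann probability mass
concentrates on one *level-5 abstract shape* -- the coarsest structure
skeleton, in which every maximal helix nesting collapses to one bracket
pair (`[]` per hairpin, `[[][]]` for a Y-shape) and unpaired stretches
vanish. The *shape probability* $\mathrm{Prob}(t, p)$ is the accumulated
probability of all foldings of transcript $t$ sharing shape $p$; unlike
folding energies it is comparable across lengths and base compositions.

The ensemble is computed with a compact nearest-neighbor model: stacking
energies per adjacent pair-on-pair (AU/UA/CG/GC/GU/UG), affine hairpin
($5.0 + 0.1\,(s-3)$ kcal/mol), interior/bulge ($3.0 + 0.25\,s$, total size
capped at 30 nt) and multiloop ($3.4 + 0.4$ per branch $+ 0.1$ per unpaired
base) penalties, minimum hairpin loop 3 nt, at 37 °C. The partition
function is computed by McCaskill-style dynamic programming in compiled
code, and $k$ structures are drawn by stochastic traceback ($k = 1000$ by
default; standard error of a shape frequency is at most
$1/(2\sqrt{k}) \approx 0.016$). Sampling replaces a shape-indexed partition
DP because it is a statistically equivalent estimator of the same quantity
and is certified in the tests against exhaustive enumeration of all
structures for sequences up to 20 nt (sampled minus exact within 0.02 at
$k = 5000$). Dominant-shape ties break toward the lexicographically smaller
shape string. The model intentionally omits dangles, terminal-AU penalties,
coaxial stacking and pseudoknots; the Z-score contract only requires one
consistent ensemble for transcript and background, and the same parameter
table serves both folding and the RBS duplex screen.

The background for a transcript of length $n$ with dominant shape $p$ is
built from same-strand genome windows of length $n$: windows whose dominant
shape is also $p$ contribute their $\mathrm{Prob}(w, p)$, giving mean
$E(p, n)$ and standard deviation $S(p, n)$, and
$Z = (\mathrm{Prob}(t,p) - E)/S$. Scanning every genome window is not
desk-scale, so the default policy folds a seeded random subsample (500
windows standalone; 100 in the pipeline driver), and a test asserts the
subsampled mean agrees with the full scan on a small genome. Fewer than two
qualifying windows, or zero variance (e.g. a phase-locked repeated genome),
leaves the background undefined and the Z-score errors rather than
reporting infinity. Leave-one-out self-Z-scores over the background windows
are centered at 0 with unit spread, which the acceptance suite checks over
more than 200 windows.

# Small-ORF and RBS screen

Candidates are screened for peptide-coding potential: complete ORFs (start
codon ATG/GTG/TTG through an in-frame stop) of at least 60 nt, counted
start through stop inclusive, in the three sense-strand frames. The
ribosome-binding-site test slides the anti-Shine-Dalgarno tail of the 16S
rRNA (5'-UCCUCCA-3') ungapped and antiparallel across the window -20..-4
relative to the start codon and sums nearest-neighbor RNA:RNA stacking
energies over consecutive complementary (including G:U) pairs; the minimum
over offsets is the duplex energy, and an RBS is called at or below
-3.4535 kcal/mol. That threshold is inherited as an opaque calibration
constant and is configurable. ORFs are relatable to the candidate's
associated gene by mod-3 frame arithmetic (shared stop in frame, other
frame overlap, wholly upstream); ORFs starting at the gene's own start
codon are excluded because their stop lies outside the sRNA.

# Hybridization filters

For two-channel arrays, $M = \log_2(\mathrm{small}/\mathrm{long})$ and
$A = \tfrac12 \log_2(\mathrm{small}\times\mathrm{long})$ (the standard
MA-plot transform; the half-log-product formalizes "dual logarithm of the
combined intensities"). Probes with $M \ge 3$ -- an 8-fold enrichment of
the small-RNA fraction -- are candidate markers. For tiling chips, probes
with signal at least twice their background are significant, and at least
two significant probes within the same intergenic region at most 200 nt
apart form a candidate region; 200 nt is the documented criterion, with
150 nt exposed as an alternative preset where the stricter spacing is
wanted. Normalization and FDR testing belong to array preprocessing and
are out of scope: the module consumes normalized intensities.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; it is not a tuning dial.

* **Genome**: i.i.d. bases at 62% GC (alphaproteobacterial composition),
  default three replicons (one chromosome, two plasmid-sized replicons).
  Genes of 180--1200 nt are placed non-overlapping with intergenic gaps of
  at least 150 nt; 92% are CDS with a small admixture of rRNA, tRNA,
  repeat and transposase features to exercise the exclusion filters.
* **Planted transcripts**: lengths 50--348 nt, classes drawn from
  proportions matching the observed candidate spectrum (trans 0.15,
  antisense 0.10, leader 0.34, sense 0.40, orf_cover 0.01). Every placement
  is verified against the classification geometry and re-drawn if it fails,
  so the truth table satisfies its class rules by construction. 70% of
  transcripts are primary (carry a true TSS).
* **Reads**: per-transcript counts are Poisson(mean depth 25 per library).
  In s1, primary transcripts yield reads starting at the TSS plus rounded
  Gaussian noise (sd 0 under the validation conditions); non-primary
  transcripts appear only as 10%-depth uniformly fragmented background,
  emulating the enrichment. In s2 every transcript starts reads at the TSS
  or, with probability 0.5, at one per-transcript internal cleavage site --
  this produces the alternative-5'-end phenomenon the end-comparison stage
  is built to detect. Reads run through to the transcript 3'-end with
  probability 0.5 (giving distinct 3'-ends) and otherwise stop early;
  lengths stay within 50--350 nt (36 nt fixed in short-read mode). Uniform
  background reads at $10^{-5}$ per nt per strand exercise the coverage
  filter; the real libraries' degradation rates are unknown, so this is a
  free parameter chosen merely to be nonzero and well below the calling
  thresholds.
* **Not emulated**: sequencing errors and quality values, adapters, mapping
  ambiguity, operon read-through, condition-dependent expression, and
  enzyme efficiencies beyond the end-distribution contract. Passing the
  recovery tests therefore demonstrates the correctness of the calling,
  labeling and classification logic under the stated read model -- not
  robustness to mapping artifacts or biological noise on real libraries.

Reads on circular replicons wrap across the origin and are emitted as two
alignment segments sharing a read id; replicons are linear by default.

# Numerical and reproducibility choices

All randomness flows through per-stage seeds derived from one configured
seed, so identical configurations give byte-identical outputs (asserted in
the tests down to the written TSV files). Coordinates are 1-based inclusive
everywhere inside the package; BED and bedGraph exports convert to 0-based
half-open through rtracklayer, and the conversion is covered by tests. The
minimal SAM dialect (FLAG 0/16, match-only CIGAR, `*` sequence) carries
stranded alignments; unstranded libraries use the 6-column TSV dialect,
since SAM has no strandless alignment. Validation experiments in the test
and acceptance suites use a 500 kb genome with 200 genes and 120 planted
transcripts for parameter recovery, exhaustive structure enumeration up to
20 nt, 450 sampled background windows for the self-Z calibration, and 500
random coverage tracks against the brute-force contig oracle; these sizes
were chosen so the full validation remains comfortable on a laptop while
keeping every statistical check well-powered.

# Known limitations

The classifier resolves each contig to exactly one class; dual sense/
antisense relations to different genes report only the higher-precedence
class, with the rest visible in the per-gene relations. The promoter module
reports no hits at its literal default cutoff, as analyzed above. The
folding model's absolute energies are approximate; Z-scores are meaningful
relative to the same model's background, not as thermodynamic predictions.
Read mapping, homology searching and covariance-model screens are outside
the package's scope: alignments are an input.
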