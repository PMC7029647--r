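---
title: "alloscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{alloscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models behind each detector, the tunable
parameters with their defaults and rationale, what the synthetic-data
generator does and does not emulate, and the decisions taken where the
underlying method descriptions were open to interpretation. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The biological setting

An allotetraploid nucleus carries two subgenomes, A and B, descended from
two diploid progenitors. Reads from the tetraploid mapped onto the
combined progenitor reference expose several post-polyploidy processes:

* **Homoeologous sequence exchange (HSE).** A segment of one subgenome is
  overwritten by its homoeologous counterpart. The donor segment then
  appears twice in the sample, the replaced segment not at all — doubled
  read depth on the donor, near-zero on the replaced interval.
* **Structural variants (SVs).** Deletions and insertions relative to the
  reference leave soft-clipped reads at their breakpoints; the clipped
  subsequence of an insertion-spanning read is a copy of the inserted
  sequence and can be traced to the insertion's donor locus.
* **Selection asymmetry.** The per-pair ratio &omega; = Ka/Ks of
  homoeologs differs systematically between subgenomes.
* **Expression dominance.** One copy of a homoeolog pair is consistently
  expressed above its partner across developmental stages.

## HSE detection

Depth is averaged in nonoverlapping windows (`window_size`, default
10 kb). The genome mean depth is estimated twice: windows whose ratio to
the first-pass mean exceeds 10 are treated as collapsed repeats and
excluded from the second pass. The last window of a chromosome is kept
truncated, with its mean computed over its true width, so telomeric
signal is not discarded.

States: ratio in `[double_low, double_high]` = [1.5, 4.0] (inclusive) is
*double*; ratio &le; `deleted_max` = 0.25 is *deleted*; else *normal*.
The phrase "between 1.5 and 4 times greater than the genome average" is
read as the ratio interval [1.5, 4], consistent with its "double
coverage" intent — the literal reading (1.5&times; *greater* = 2.5&times;)
would exclude exact doubling. The deleted cutoff is unstated in the
source method; 0.25 sits midway between Poisson noise at 30&times; and
true copy-0, and is configurable.

Runs of one state are linked across gaps of at most `max_gap_windows` = 5
non-target windows; gap windows count toward the span; runs spanning
fewer than `min_span_windows` = 8 windows (80 kb) are dropped. The span
minimum is read inclusively ("more than eight windows (80 kb)": the
parenthetical pins 80 kb = 8 windows).

A double run is projected onto the other subgenome by linear
interpolation between flanking homoeolog anchor midpoints (with
nearest-slope extrapolation just beyond the outermost anchors); a
deleted run reciprocally overlapping the projection by
`min_reciprocal_overlap` = 0.5 yields a directed HSE. Unmatched double
runs are reported as *unpaired candidates* and excluded from the summary
ratios; unprojectable runs are flagged, never silently dropped.

**Boundary refinement.** Window-level Poisson noise occasionally pushes a
stray window past the 1.5 threshold next to a true HSE, and gap-linking
then drags the double run past the true edge. The deleted side has no
comparable failure mode (P(Poisson(30) &le; 7) &asymp; 10^-6^), so the
reported donor segment is the intersection of the double run with the
deleted run projected back onto the donor chromosome. This keeps per-edge
errors within one window at 30&times; without weakening the linking rule.

## SV confirmation and insertion origin

Soft-clipped alignment records whose clip junction lies within 300 bp
(two-sided) of a candidate breakpoint, with clip length strictly greater
than 10 bp, are confident evidence. An SV is confident when a breakpoint
has strictly more than `min_support` = 5 confident clips; both strict
inequalities are read literally from the method description and are
configurable. Deletions have two breakpoints while the description speaks
of "breakpoint" in the singular: the default requires the threshold at
&ge; 1 breakpoint and reports per-breakpoint counts (`require_both`
enables the strict mode). Note that for deletions shorter than the 300 bp
window both junctions' reads pool at either breakpoint — a faithful
consequence of the distance rule. Deletions and insertions outside
5 bp&ndash;10 kb (inclusive bounds) are discarded; inversions and
translocations pass through confirmation but are exempt from the size
gate, which names only deletions and insertions.

Insertion flags are remapped end-to-end: substitution-only matching with
at most 2 mismatches (`Biostrings::matchPattern` is the engine; a
brute-force scan pins its behavior in the tests). Classification order:

1. any flag matching within 10 kb (inclusive) of the breakpoint — tandem;
2. else a 5&prime; and a 3&prime; flag both matching one locus on the
   same chromosome &le; 10 kb apart — intra if that chromosome is the
   breakpoint's, inter otherwise;
3. else unresolved.

Donor candidates are ranked by total mismatch count first (best
end-to-end alignment), because a flag whose donor lies on one subgenome
often also matches the donor's homoeologous copy — at the ancestral
divergence here, a 20 bp flag matches the homoeolog with zero mismatches
about 40% of the time. On a mismatch tie the breakpoint's own chromosome
is preferred: this rescues intra donors shadowed by their homoeologs and
cannot corrupt inter calls, whose candidate loci never sit on the
breakpoint chromosome.

Gene annotation is strand-aware: an SV overlapping the gene body or the
`upstream_bp` = 2000 bp window upstream of the transcription start marks
the gene. The upstream width is a regulatory-window convention (the
source never defines "upstream"); the SV-abundance-by-distance profile,
computed alongside a matched random-interval control, makes the choice
visible. Homoeolog pairs partition exhaustively into SV/non-SV (one copy
hit; the side is labeled), both-SV, and unaffected; the both-SV class is
kept separate because the source definitions only cover the first two.

## Synteny and homoeolog pairs

Anchors come either from a 12-column tabular protein hit file (E-value
strictly below 1e-5, top 5 hits per query by score) or from the built-in
aligner: an amino-acid k-mer prefilter (k = 5, &ge; 2 shared k-mers)
followed by global Needleman&ndash;Wunsch with BLOSUM62 and affine gaps
(opening 10, extension 0.5). The default score threshold of 50 was
calibrated so unrelated length-100 proteins anchor at under 1%.

Chaining is exact dynamic programming per chromosome pair and
orientation: anchor ranks must strictly increase on side 1 and increase
(decrease) on side 2 for + (&minus;) orientation, with rank gaps of at
most `max_gap_genes` = 25 (a common collinearity default; the source
defers to an external tool's defaults). The maximum-scoring chain is
extracted, its anchors removed, and extraction repeats while chains reach
`min_pairs`. The block minimum is 5, inclusive, adopted uniformly — the
source says both "more than five gene pairs" and "at least five collinear
genes"; the inclusive reading keeps the two uses consistent. Gene rank is
by start coordinate with gene-id tie-breaks, and block ids order by
score, then size, then chromosome pair, so outputs are deterministic.

Homoeolog pairs are all anchor pairs inside retained blocks, made
one-to-one by keeping the highest-scoring assignment per gene. The
one-to-one rule is a declared convention: the real-data pair count cannot
be reproduced without the real data, and deduplication is required for
the pair-level analyses downstream. Self-synteny excludes self-hits,
collapses mirrored anchors by chromosome/rank order, and feeds internal
paralog pairs to the Ks-peak machinery.

## Ka/Ks, Ks peaks and dating

Codon alignments are built by translating the two CDS (universal code),
aligning the proteins globally (BLOSUM62, affine gaps), back-translating,
and dropping columns with a gap or stop codon in either sequence.

The Ka/Ks engine is NG86-style counting rather than the ML machinery of
YN00: codon-frequency and transition/transversion weighting is out of
proportion for this artifact, the counting method has a closed-form
exhaustive oracle (every ordered pair of sense codons is checked to
10^-9^ in the tests), and the engine sits behind a small interface should
a weighted variant be wanted. Sites: at each codon position the fraction
of the three possible substitutions preserving the amino acid is
synonymous; substitutions creating stop codons count as nonsynonymous, so
S + N = 3 per codon exactly. Differences: averaged over all orderings of
the differing positions with equal weights; pathways through stop codons
are excluded (all orderings are used if every pathway is blocked).
Proportions are Jukes&ndash;Cantor corrected, d = &minus;(3/4) ln(1 &minus;
4p/3); p &ge; 0.75 is flagged saturated and excluded from Ks peaks and
&omega; tests; &omega; is undefined when Ks = 0.

Ks peaks: Gaussian KDE with Silverman's rule-of-thumb bandwidth on a
512-point grid over [0, 99th percentile], argmax ties broken toward the
smaller Ks — all fixed for determinism. Dating is T = peak Ks / (2m),
m = 8.12 &times; 10^-9^ substitutions/site/year by default. A
`rate_multiplier` argument accommodates lineages with accelerated silent
substitution rates; deep events dated in the literature under a different
clock (e.g. an ancient whole-genome duplication at Ks &asymp; 0.78) should
take their age from that literature rather than from this formula, which
is why the demo dates only the recent ancestor split.

The subgenome comparison reports per-pair &omega; with median contrasts —
the source's "average Ka/Ks value" phrasing is ambiguous between per-pair
and per-subgenome averaging, and medians match how it reports the
contrast. Tests: two-sided Wilcoxon rank-sum (exact when both n &le; 25
without ties, else normal approximation with tie correction) and a
permutation test on |difference of medians| with the add-one estimate
p = (#{|stat| &ge; |obs|} + 1)/(n_perm + 1), 10 000 permutations by
default.

## Expression bias

RPKM = count &times; 10^9^ / (library total &times; gene length);
expressed means RPKM strictly above 0.1. Homoeolog copies are compared on
RPKM (they may differ in length; the source does not state length
handling) after adding a pseudocount of 0.01 before log2. Per stage, a
Welch t-test on log2 RPKM between the copies' replicates; identical
constant replicates give p = 1 by convention. BH correction is applied
per stage across pairs — each stage is its own FDR family, matching the
"in at least one stage" phrasing; a global family is a config switch away.

Dominance: some stage has fold change &gt; 2 (or &lt; 1/2) at FDR &lt;
0.01, all significant stages agree in direction, and every other stage
where both copies are expressed is direction-consistent — same sign, or
|log2FC| &lt; `consistency_eps` = 0.25 for flat stages. The consistency
clause operationalizes the qualitative "expression pattern was consistent
in other stages". DEGs use fold change &gt; 2 or &lt; 0.5 at FDR &lt;
0.05. The t-test + BH branch is the one implemented; the alternative
external negative-binomial GLM route is out of scope here because the
dominance rule's FDR is tied to the t-test description.

The SV&ndash;expression integration compares per-stage |log2FC|
distributions of SV-carrying vs unaffected pairs (Wilcoxon rank-sum),
with an optional split by SV type.

## The synthetic world

The generator is first-class, tested code; its defaults are the stated
conditions of the emulated system, chosen once:

* ancestor divergence 0.036 substitutions/site — the Ks peak between the
  two diploid progenitors; post-polyploidy extra divergence 0.008, split
  evenly between the subgenome branches, putting the subgenome Ks peak
  near 0.044;
* sequencing depth 30&times;, 150 bp reads, 10 kb windows;
* 8 supporting soft-clipped reads of 20 bp clips per SV breakpoint, with
  5% of background reads carrying sub-threshold (&lt; 10 bp) clips to
  exercise the confident-clip filter;
* expression: negative binomial with dispersion 0.05, baseline mean 500
  counts per kb (a mid-expressed gene at this depth), 4 stages &times; 3
  replicates, bias factor 4 for biased pairs;
* genes every 5 kb with CDS of 300&ndash;1500 bp filled with sense
  codons, so Ka/Ks truth is computable and divergence hits synonymous and
  nonsynonymous positions uniformly.

Substitutions are i.i.d. per site, always to a different base, so the
realized difference rate equals the configured rate; indels occur only as
explicit SV implants. Depth is simulated at window resolution —
Poisson(depth_mean &times; copy number) per window, with overlap-weighted
copy number for boundary windows — because the HSE detector consumes
windows; read-level realism would add nothing the detectors see.
Insertions copy their inserted sequence from a donor locus placed per the
requested origin class, which makes origin truth exact. All randomness
derives from one master seed through named per-operation streams, so any
stage can be re-run in isolation and byte-identical.

What the generator does **not** emulate: sequencing error and quality
scores, paired-end insert-size artifacts, mapping ambiguity in repeats,
GC or mappability bias in depth, gene-order rearrangements between
subgenomes, and isoform structure. A green recovery test therefore
establishes that a detector implements its rule correctly and is
well-calibrated under idealized noise, not that it is robust to
real-library artifacts.

## Numerical and degenerate-input conventions

* Depth ratio thresholds are inclusive at both ends; a genome-mean pass
  excludes ratio &gt; 10 windows first.
* KDE grids are fixed (512 points) and argmax ties resolve to the smaller
  Ks; constant samples return their common value directly.
* Welch tests on two constant equal groups return p = 1 (p = 0 when
  constant but unequal); permutation p-values are never below
  1/(n_perm + 1).
* All tie-breaks in chaining, pairing and block naming are documented and
  deterministic; pathological gene models (shared start coordinates)
  order by gene id.
* Candidate SV tables are parsed leniently, preserving unknown columns;
  all coordinate outputs state their convention (BED 0-based half-open,
  SAM/GFF3 1-based) in headers or documentation.

## Known limitations

* The NG86 engine deliberately omits transition/transversion and
  codon-frequency weighting; &omega; levels on real data will differ from
  YN00's, though subgenome *contrasts* are the analysis target.
* Interval projection between subgenomes assumes locally collinear
  homoeology; across large rearrangements the projection flags intervals
  rather than resolving them.
* The expression model tests assume homoeolog pairs are independent;
  shared regulatory variation across pairs would make the per-stage FDR
  families optimistic.
* With 3 replicates, dominance power at fold change 4 is high only when
  the FDR family is not null-dominated; in mixtures with few biased pairs
  the classifier is conservative by construction (FDR &lt; 0.01).
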