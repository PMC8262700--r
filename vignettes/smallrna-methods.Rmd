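---
title: "smallrna: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smallrna: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

smallrna is a desk-scale pipeline for small non-coding RNA (sncRNA)
sequencing data: raw FASTQ in, quantified miRNAs/isomiRs and other ncRNA
classes, differential-expression statistics, sample-structure summaries,
variance decomposition and novel miRNA precursor candidates out. This
vignette explains the methods, the tunable parameters, and the design
choices made where the design was genuinely open.

## Preprocessing

Each read passes through adapter trimming, fixed-base extraction, quality
trimming, N handling and a minimum-length filter, in that order. The order
matters for two reasons: small-RNA inserts are shorter than the read, so the
3' adapter must be located before positional logic can run; and the UMI and
barcode positions are defined relative to the adapter-free insert. Whether
quality trimming should instead precede adapter trimming is a genuinely open
choice; adapter-first is used and documented here because adapter bases in
small-RNA data are usually high-quality (they are sequenced early in the
read), so quality-first would rarely change the outcome while complicating
the position arithmetic.

**Adapter search.** The 3' adapter is located by semi-global alignment
against every candidate start position: substitutions and indels each cost
one, the adapter may run off the 3' end of the read (overhang) or be
followed by further bases (which are discarded with it), and an occurrence
must cover at least `min_overlap` read bases (default 10) at an edit
distance of at most `max_adapter_edit_dist` (default 1). Among qualifying
positions the minimal distance wins and ties go to the leftmost position,
i.e. the longest removable adapter stretch. An exact-match fast path covers
the overwhelming majority of reads; the full dynamic program runs only when
no exact occurrence exists.

**Quality trimming.** Windows of `qual_window` bases (default 4) slide 5'
to 3' in steps of one; the read is truncated at the first base of the first
window whose mean Phred quality drops below `qual_threshold` (default 20).
Reads shorter than the window are assessed as one whole-read window.

**UMIs and collapsing.** Reads are collapsed to unique sequences. Without
UMIs the collapsed count is the sequence multiplicity; with UMIs it is the
number of *distinct* UMIs observed for that sequence, i.e. exact-match
deduplication of PCR copies. No UMI error-correction clustering is
attempted — with the short UMIs of current sncRNA protocols, one-off UMI
errors inflate counts by a bounded factor that the exact rule keeps simple
and auditable. Deduplication happens before mapping, so one original
molecule contributes one count regardless of where it maps.

**Compression.** Collapsed reads serialize as `sequence TAB count` lines and
gzip-compress. Because sncRNA libraries are dominated by a few thousand
distinct sequences, the payload is typically more than 90% smaller than the
raw FASTQ; the reported ratio is `1 - compressed_bytes / raw_fastq_bytes`.

## References and mapping

Internal coordinates are 0-based half-open everywhere; GFF3/BED conventions
are converted only at the I/O boundary. Class references supplied as genomic
intervals are extracted to sequence space at load time (minus-strand
features reverse-complemented), so every counting step runs in sequence
space.

The mapper is deliberately simple: a k-mer index over both strands anchors
an exact seed of `seed_len` nt (default 18, the first bases of the read),
the remainder is verified ungapped, and alignments with more than the
class-specific mismatch cap are discarded. Reads with more than `max_hits`
(default 5) qualifying loci are dropped as multimappers. Indels are out of
scope for the internal mapper; externally produced SAM (with `NM` tags) is
accepted instead. The mapper targets correctness at fixture scale, not
aligner performance, and is verified against an exhaustive position-by-
position search in the test suite.

## Quantification

**miRNA counting.** A read counts toward an annotated mature iff its start
lies within `offset5` (default 2) nt of the mature 5' end, its end within
`offset3` (default 5) nt of the mature 3' end, and it carries at most one
mismatch. Among a read's precursor alignments only those with that read's
minimum mismatch count are considered; a read compatible with several
matures counts toward each, and multimapped counts are assigned in full (no
fractional splitting), which can multi-count — the trade-off is documented
rather than hidden. Classes other than miRNA are counted mismatch-free, all
lowest-mismatch alignments each receiving the full collapsed count.

**isomiRs.** Mapping runs with one extra mismatch; 3'-terminal read bases
that disagree with the templated precursor continuation are reclassified as
non-templated additions (NTA) by a greedy scan from the last base inward
that stops at the first templated match. After reclassification the record
must satisfy the ordinary mismatch cap and the positional tolerances,
measured on the templated portion only (the NTA does not shift the 3'
coordinate). Variant labels encode 5'/3' shifts, internal substitutions and
the NTA length; canonical reads carry the label `NA`. Results export as
miRGFF3 with header pragmas and `Read`/`UID`/`Name`/`Parent`/`Variant`/
`Expression` attributes, and the package's parser restores the records
exactly.

## Expression statistics

Features are *detected* in a sample at >= 3 reads and kept when detected in
at least 50% of all samples, or of at least one level of the grouping
variable when one is supplied; both comparisons are inclusive. Counts
normalize to `log2(RPM + 1)` where the RPM depth is the sample's total
genome-mapped reads (configurable).

Per feature and per pair of levels the suite reports Shapiro-Wilk normality
p-values per group, Welch's t-test (the unequal-variance form, since equal
variances are never guaranteed post-normalization), the Wilcoxon-
Mann-Whitney (WMW) test (exact where R provides it, normal approximation
with tie/continuity correction otherwise), the AUC with ties counted 1/2,
Cohen's d on the log2 scale with pooled SD, and the fold change of group
mean RPM computed on RPM + 1 so empty groups stay finite. Both t and WMW
p-values are always reported rather than auto-switching on normality; the
BH-adjusted WMW p is the headline value. BH families are formed per
comparison and per RNA class. With three or more levels, every pairwise
comparison runs (k(k-1)/2 of them) plus one-way ANOVA and Kruskal-Wallis
per feature.

The default candidate filter is the conjunction: mean RPM >= 1 in at least
one level, AND AUC >= 0.7 (or <= 0.3), AND adjusted p < 0.05. "Effect size"
is interpreted as the AUC; Cohen's d is reported but not filtered on, since
the AUC's 0–1 scale matches a 0.7 threshold naturally while d has no such
calibration.

## Sample structure and PVCA

Embeddings use PCA (deterministic; component signs fixed by making the
largest-magnitude loading positive) and UMAP (`n_neighbors = 15`,
`min_dist = 0.1`, seed 42 recorded in the output; single-threaded so runs
reproduce exactly). Sample similarity uses Spearman correlation of the
RPM matrix; clustering is complete-linkage on Euclidean distances via
`stats::hclust`, exported as an explicit merge trace and a Newick-like
string. Tie-breaking among equidistant merges follows `hclust`; ties have
probability zero on continuous data and the merge heights — the scientific
content — are tie-invariant.

PVCA standardizes features to unit variance (so high-expression features do
not dominate), projects samples onto the principal components that
cumulatively retain `pc_variance_threshold` (default 0.6, the conventional
choice) of the variance, fits each retained PC with a REML mixed model
carrying a random intercept per annotation variable and per pairwise
interaction (lme4), falls back to a method-of-moments estimator when a fit
fails, averages the per-term variance fractions across PCs weighted by the
PC eigenvalues, and normalizes the result to sum to one. Two caveats
matter in practice: two-level random effects are intrinsically noisy, and
if two annotation variables induce the same sample partition their variance
is mathematically unattributable — the decomposition can place it on either
variable or their interaction. Keep designs unconfounded. PVCA runs on
log2(RPM+1); the choice between log and raw RPM was open, and the log scale
was chosen to match every other analysis stage.

## Novel miRNA discovery

Reads are grouped by shared 5' start per contig and strand; a group becomes
a *stack* when its summed collapsed count reaches `min_stack_height` and is
strictly maximal within +/- 70 nt on its strand (ties to the 5'-most
group), and reported stacks never fall in each other's window. From each
stack two 70-nt windows are excised: one placing the stack as the 5' arm,
one as the 3' arm, each with a 10-nt flank on the stack-distal side.
Windows that would extend beyond the contig are discarded rather than
truncated, so a stack near a contig edge yields a single candidate. Minus-
strand windows are reverse-complemented so candidates are always in
transcript orientation.

Candidates fold by a weighted Nussinov dynamic program (GC = 3, AU = 2,
GU = 1, minimum hairpin loop 3 nt); the energy is the negated pair-weight
sum, a unit-free stability score — an external thermodynamic folding tool
can be substituted where physical kcal/mol values are needed. The mature
arm is the stack interval; the star arm is the paired partner region read
off the fold with the canonical 2-nt 3' overhang. Because maximum-weight
pairing on arbitrary sequence is promiscuous, candidates must additionally
look like a single hairpin: at least half of the mature bases paired, the
partner span no more than 10 nt wider than the mature, the star disjoint
from the mature, and exactly one terminal loop between them. The Dicer
consistency fraction is the share of window reads whose 5' ends fall within
`boundary_tolerance` (default 2) nt of the mature or star 5' end; a
candidate is retained when it reaches `min_dicer_fraction` (default 0.66)
and the mature length lies in `[18, 25]` nt.

Retained candidates are categorized against the known annotation: `novel`
(no overlap with known miRNA loci, predicted mature not within edit
distance 2 of any known mature), `known_precursor_new_mature` (window on a
known precursor whose overlapping arm carries no annotated mature), or
`overlaps_known`. Ranking is a NovoMiRank-style score: five features
(precursor length, GC fraction, energy per nt, mature length, paired-base
fraction) are z-scored against a reference table of known-miRNA feature
moments and averaged as absolute values, so 0 is maximally miRNA-like. The
shipped reference table is synthetic (plain text under `inst/extdata/`),
not a database snapshot; users can substitute their own.

## The synthetic-data generator

`make_toy_bundle()` plants hairpins with perfectly complementary 22-nt arms
around an 8-nt loop into a random genome (default 50 kb), annotates the
known ones, and embeds the other ncRNA-class features downstream so that
class reads contribute to genome-mapped depth. `simulate_sample_reads()`
draws reads from the feature pool under a Zipf abundance model (exponent
1.2 by default, the skew typical of small-RNA libraries; 1.5 for the
dedicated low-complexity compression fixture), applies group effects as
`2^log2fc` multipliers on the second level, batch effects as per-(feature,
batch) lognormal factors, per-base substitution errors, then appends the 3'
adapter, prepends a random UMI when configured, and emits exactly
`depth_per_sample` reads with high qualities and a mildly degraded 3' tail.
Everything is deterministic given the seed.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: ligation and sequence-composition bias, indel
sequencing errors, chemically modified bases, imperfect (bulged) hairpin
stems, overlapping transcription, and genomic repeat structure. The
perfectly complementary planted arms in particular mean that hairpin reads
legitimately map to both strands of their locus, so discovery reports
mirror-image candidates of the same hairpin; real arms pair imperfectly and
rarely do this.

## Numerical and scale choices

Tests and the acceptance checks run at deliberately modest problem sizes,
chosen so the whole suite completes in minutes while every rule still binds:
fixture studies of 4 samples at 3–8 thousand reads on 25–40 kb genomes;
mapper/oracle cross-checks at 1 000 reads against a 10 kb reference;
statistical calibration at 2 000 features with 20 samples per group; PVCA
recovery at 200 features on 40 samples; folding oracle equivalence for all
lengths up to 18 nt; the compression claim at one million reads from 500
distinct sequences. Degenerate inputs follow fixed conventions: constant
groups give p = 1, zero pooled SD gives a missing Cohen's d, constant
samples give missing Spearman entries, empty samples give compression
ratio 0, and sub-10-nt sequences are not folded.
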