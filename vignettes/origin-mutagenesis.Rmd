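---
title: "Quantifying mutational processes at replication origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutational processes at replication origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orimut)
```

# The scientific problem

Constitutive DNA replication origins are recurrent initiation sites that
fire across cell types. Somatic mutations in cancer genomes are not
uniformly distributed around them: several mutational processes focus on
the ~1 kb *origin domain* (origin midpoint ± 500 bp), producing a local
excess of single-base substitutions, structural-variant break ends and
copy-number boundaries relative to the surrounding ±10 kb *flanks*.
`orimut` implements the quantitative machinery needed to detect and
characterise that focal mutagenesis:

* per-window mutation densities and per-sample **burden ratios**
  (origin-domain density / flank density);
* **background-adjusted 96-context signatures** at origins, cosine
  clustering of tumours, and non-negative exposure refitting against a
  signature catalog;
* **G4Hunter** G-quadruplex propensity scoring and quadparser-style
  motif discovery, linking T>G mutagenesis and duplication break ends
  to G4 structures in origin domains;
* strand-resolved **excision-repair profiling** with
  reactive-dinucleotide correction, exposing replication-associated
  repair deficits and fork-strand asymmetries;
* **SV and CNV signature classes** and a permutation test for the
  enrichment of amplified-segment boundaries at origin domains;
* expression covariates: TPM, replicative-stress biomarker Z-scores and
  cyclin-derived cell-cycle phase fractions.

Because the cancer-genome call sets these methods were designed for
cannot be redistributed, the package ships a fully seeded
**synthetic-cohort generator** that plants each effect at known strength
and records the truth, so every stage has a parameter-recovery test that
runs from nothing but a seed.

# Geometry and conventions

All coordinates are **0-based half-open**; BED input is native and
1-based tabular input is converted at the reader. The origin *midpoint*
of an even-length interval is the floor of the mean — a deterministic
integer rule matching BED arithmetic. From the midpoint we derive:

| unit | definition | default |
|---|---|---|
| domain | midpoint ± `domain_halfwidth` | ± 500 bp (1 kb) |
| flank | midpoint ± `flank_halfwidth`, minus the domain | ± 10 kb (19 kb total) |
| window grid | tiles of `width` bp over the ± flank span | 100 bp → 200 windows |

*Isolated* origins are those whose midpoint has no neighbouring
midpoint within 10 kb; the filter is defined on midpoint distance, which
is equivalent to requiring that an origin's 20 kb window contain a
single origin, and it is idempotent. Origin *clusters* are built by
single-linkage chaining of midpoints at 20 kb and retained when they
span more than 20 kb and hold at least two origins; the chaining rule is
the simplest construction satisfying that definition and both the link
distance and the filters are arguments. Two origin sets are matched as
"the same origin" when midpoints are within 5 kb, greedily by increasing
distance with each origin used at most once.

Intervals that would extend past a chromosome end are clipped with a
warning rather than dropped: the synthetic mini-genomes place origins
much closer to ends (relatively) than a human chromosome would, and
dropping them would silently change denominators.

Every substitution is expressed on the **pyrimidine strand**:
purine-reference records are reverse-complemented (reference, alternate
and flanking context together). The 96 context classes are ordered
substitution-major (C>A, C>G, C>T, T>A, T>C, T>G) with 5′ and 3′ bases
each in A, C, G, T order — the standard catalog column order.

# Densities, burden ratios and corrected rates

`density_profile()` counts mutations per offset window over all origins
and divides by covered bases (window width × origins, less clipping).
`burden_ratio()` is the per-sample focal-mutagenesis statistic: domain
density / flank density, with zero-flank samples reported as missing
rather than infinite so cohort medians stay defined.

`corrected_rates()` converts counts into per-opportunity rates. In
`"base"` mode the denominator for a C-class (or T-class) window is the
number of C **plus** G (T plus A) bases in it: since the numerator is
pyrimidine-normalized — a G>A record counts as C>T — the opportunity
space must collapse strands the same way, and this keeps the panel
invariant under reverse-complementing the genome. In
`"trinucleotide"` mode each class rate is the mean of its sixteen
per-context rates. The *background* is the unweighted mean over flank
windows and is subtracted, so corrected rates are negative wherever a
window is quieter than the flanks; flooring is deliberately not applied
here (negative rates are informative), only in signature space (below).

# Background-adjusted signatures

For a sample (or a pooled cluster), origin-domain context counts are
divided by the domain occurrences of each context's central
trinucleotide (both strands collapsed), and the same rate computed in
the flanks is subtracted:

$$ r_c \;=\; \frac{o_c}{O_{t(c)}} \;-\; \frac{f_c}{F_{t(c)}} $$

where $o_c, f_c$ are domain/flank counts of context $c$ and
$O, F$ the trinucleotide occurrence vectors. This single formula
reproduces both behaviours required downstream: the raw rate vector may
be negative (a process depleted at origins), while flooring at zero and
renormalising yields a proper probability signature for display and
cosine comparison. Whether to floor is an explicit flag because the two
uses genuinely differ; the provenance (counts and occurrence vectors) is
kept on the object so any adjusted signature can be recomputed exactly.

Samples passing the ≥ 50 origin-mutation filter are clustered by
**average-linkage hierarchical agglomeration on 1 − cosine** of their
adjusted rate vectors. Average linkage is the conventional choice for
cosine dissimilarities; the number of clusters is a user parameter
(a data-dependent quantity, not a constant of the method). Cluster
signatures are computed by pooling member counts *before* adjustment —
adjustment is not linear in the counts, so pooling first is the
correct order.

`fit_exposures()` solves a non-negative least-squares problem per row
(Lawson–Hanson, via `pracma::lsqnonneg`). The `strict` mode iteratively
removes the catalog signature whose removal least degrades the
reconstruction cosine, as long as the degradation stays within
`delta = 0.004` — the conventional default of strict refitting — then
refits on the survivors; signatures never reaching `min_contribution`
(default 50) fitted mutations anywhere are zeroed. Both constants are
arguments, not assumptions.

The fork-strand convention, used both for mutations and repair tracks:
for a rightward-moving fork (offset ≥ 0 from the midpoint) the
reference plus strand is the **lagging-strand template**, mirrored left
of the origin; a mutation exactly at the midpoint is counted on the
right side. The convention is arbitrary up to a global flip and is
recorded on all outputs.

# G-quadruplex scoring and motifs

G4Hunter gives every base an integer score: each G in a maximal G-run
of length $n$ scores $\min(n, 4)$, each C in a C-run $-\min(n, 4)$,
A/T/N score 0 and N breaks runs (a conservative reading — an ambiguous
base neither extends nor bridges a run). The sequence score is the
plain mean, hence bounded in [−4, 4] and exactly antisymmetric under
reverse complement. The worked telomeric value
`g4hunter_score("GGGTTAGGGTTAGGGTTAGGG")` = 36/21 ≈ 1.714 follows
directly: four GGG runs contribute 3 × 3 each over 21 bases.

Motifs follow the quadparser pattern with extended loops:
`G3+ (N1–12 G3+) × 3`, plus five flanking bases on each side included in
the reported interval and in the G4H score (sign-normalized to the
motif strand, reported as a positive magnitude with the strand kept).
Matches are non-overlapping per strand, leftmost, with *lazy* loops —
a deterministic parse; the minus strand is scanned as the plus pattern
on the reverse complement, which makes the motif set strand-closed by
construction rather than by accident of regex semantics. `core_start`
is the genomic position of the first G of the first tract *on the
motif strand* (the rightmost base of the match for minus-strand
motifs), because break ends and oriented profiles are anchored there.

`g4access_top_window()` slides a 25-nt window across a peak and keeps
the window with maximal |G4H|; window sums are integers, so ties are
exact and resolved leftmost.

# Repair profiles

Coverage is binned at 50 nt per strand. `dinuc_correct()` divides each
bin by the count of reactive dinucleotides — TT for CPD, CC/CT/TC for
6–4PP — **on the strand carrying the signal**, read 5′→3′ on that
strand (lesions are strand-resident; counting on the reference strand
would misattribute the opportunity). Bins without a reactive
dinucleotide become missing rather than zero. Strand bias is
`log2((plus + ε)/(minus + ε))` on 100-bp windows with ε = 0.5 by
default to keep sparse bins finite; at realistic coverage the
pseudocount is negligible, and it is configurable wherever exactness
matters.

# Rearrangement signatures and origin enrichment

Break-end pairs are classified by orientation (break ends ordered by
position): tail→head deletion, head→tail duplication, equal
orientations inversion, zero-span with inserted sequence insertion,
inter-chromosomal translocation. SV classes are type × length over the
bins 0–0.1, 0.1–0.5, 0.5–1, 1–5, 5–10, 10–100 kb, 0.1–1 Mb, > 1 Mb;
CNV classes are LOH-status × copy-number class {0, 1, 2, 3–4, 5–8, 9+}
× length over 0–0.1, 0.1–1, 1–2, 2–3, 3–5, 5–10, > 10 Mb. All length
bins are **lower-open/upper-closed** — one rule applied uniformly and
tested at every printed edge. Translocations form a single length-free
class (their length is undefined).

For origin-coverage excess, origin midpoints are counted per 100 kb
bin; each CNV segment in (0.1, 5) Mb and its ± 2 Mb flanks are rescaled
to 100 equal windows per part, per-window means are averaged over
segments, and the excess is the in-segment value minus the mean flank
value. Windows truncated by a chromosome end are weighted by covered
fraction.

`boundary_permutation_test()` takes amplified-segment boundaries as
1-bp intervals, counts overlaps with 1-kb origin domains, and compares
against `n_perm = 1000` uniform, per-chromosome, length-preserving
re-placements, with the plus-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$.
The p-value is therefore never exactly zero and is conservative
(super-uniform) under the null. Because the statistic is a discrete
count, calibration studies must use a geometry whose expected overlap
is large enough (tens to hundreds) for the null to be effectively
continuous; the package's calibration study uses 400 breakpoints
against targets tiling 25% of a 2 × 1 Mb genome (expected overlap
≈ 100) and observes rejection at the nominal 5% within sampling error,
with the empirical CDF of p-values never exceeding uniform by more
than 0.05.

# Expression covariates

TPM is computed per sample as $10^6 \cdot (c_g/\ell_g) / \sum_h
(c_h/\ell_h)$ from raw counts and exon lengths. Stress-biomarker
Z-scores use the **population SD** across samples (the deliberate
convention here; with the two points 2 and 4 this gives ∓1) and are
computed on raw counts by default with a TPM switch, since both usages
occur in practice. Cell-cycle phase fractions come from cyclin-class
TPM sums (A: CCNA1/2; B: CCNB1/2; D: CCND1/2/3; E: CCNE1/2):
G1/S = E/(A+B+D+E), S/G2 = A/total, G2/M = B/total — the fractions need
not sum to one because cyclin D anchors no phase of its own, and they
are invariant to rescaling a sample's TPMs. Subtype labels come either
from an external file or from a 2-component PCA embedding of
standardized log1p(TPM) followed by k-means with 20 random starts
under a fixed seed; PCA is the embedding used here — the labelling
contract only requires *some* 2-D embedding ahead of k-means, and PCA
is deterministic given the seed policy.

# The synthetic cohort: what it emulates and what it does not

`simulate_genome()` draws i.i.d. bases at GC 0.40 (close to the human
genome-wide value) and places origin midpoints by rejection sampling
with 25 kb minimum spacing, so by construction every origin passes the
isolation filter — the study conditions concern isolated origins. The
default genome is 2 × 5 Mb with 100 origins: large enough that domain
and flank trinucleotide occurrences are well estimated, small enough
that a full analysis runs in minutes. Half the origin domains receive a
planted G4 core (four GGG tracts, loops 1–7 nt over A/C/T starting
with T, random strand, a T immediately 5′ of the core so the T>G
process always has an eligible site); decoy cores go into flanks.

Mutational processes are site-resampling models: `flat` draws uniform
positions; `aid_wrcy` draws C>T at WRCY-motif cytosines (W = A/T,
R = A/G, Y = C/T, both strands); `uv_ner_deficit` draws C>T at
dipyrimidine cytosines with an optional lagging-strand weight; `g4_tg`
draws T>G within 2 nt of the first-tract edges of planted origin G4s.
Site processes multiply in-domain weights by `origin_fold`. Per sample,
the burden is Poisson, the mixture multinomial, and positions are
unique (collisions re-drawn from the flat background). The truth object
stores each process's expected 96-spectrum in two spaces — count space
and occurrence-normalized **rate space** — because the
background-adjusted estimator lives in rate space; recovery tests
compare like with like. It also stores the domain/flank site-weight
masses, from which the expected burden ratio of any mixture follows in
closed form.

Repair tracks are Poisson around a mean proportional to the reactive
dinucleotide count per bin (20 reads per dinucleotide by default — deep
enough that pseudocounts are negligible in bias estimates), multiplied
by the NER-deficit factor inside domains and by $2^b$ on the
lagging-template strand of each side. SV simulation seeds ~100 bp
duplications at G4 core starts; CNV simulation places amplified (CN
3–4, Het) segment boundaries inside origin domains with configured
probability. Expression is negative-binomial (size 10) with subtype
shifts on the stress panel, the cyclins and marker blocks.

Determinism: one global seed fans out to fixed per-component child
seeds, so regenerating a single component reproduces it exactly, and
identical seeds give byte-identical FASTA/BED/TSV outputs across runs.

What the generator does **not** emulate — and what passing recovery
tests therefore cannot show about real data: replication-timing and
chromatin covariates of mutation rate, sequence autocorrelation beyond
i.i.d. bases, subclonal structure and purity, coverage-dependent call
sensitivity, and selection. The tests demonstrate that the estimators
recover planted effects of the stated sizes under the stated noise,
not that real cancer genomes contain such effects.

# Problem sizes and numerical choices

The validation studies run on scaled-down geometries chosen so the full
suite completes in a few minutes on one core while keeping every
statistic well inside its asymptotic regime: recovery cohorts use a
2 × 1 Mb genome with 40 origins and 30 samples of ~3,000 mutations
(≈ 300 origin-domain mutations per sample, comfortably above the ≥ 200
condition and the ≥ 50 filter); burden-fold studies use 12 samples per
fold; the permutation calibration uses 1,000 replicates of 1,000
permutations. Degenerate inputs are handled explicitly rather than by
coincidence: zero flank counts give missing ratios, zero-occurrence
contexts with nonzero counts are an error (inconsistent inputs),
all-negative adjusted signatures are flagged degenerate, and empty
cohorts warn rather than fail.

# Known limitations

* The background-adjustment formula is one principled reading of
  "adjusted for trinucleotide composition and flank background"; other
  normalisations (e.g. occurrence-weighted rather than unweighted flank
  means) are defensible and would shift rates by small factors.
* Burden ratios are not adjusted for copy number or purity; on real
  tumours, amplified regions inflate local densities.
* The permutation null treats chromosomes as uniform; on real genomes
  an exclusion mask (assembly gaps) should be supplied, and the test
  accepts one implicitly by restricting the target set.
* `read_strand_track()` rasterises bedGraph intervals onto the fixed
  grid by overlap fraction; tracks whose intervals do not align to the
  bin grid are averaged, not resampled.
* Exposure refitting inherits the usual caveats of catalog fitting:
  collinear catalog signatures make individual exposures unstable even
  when the reconstruction is excellent; the strict mode mitigates but
  does not remove this.
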