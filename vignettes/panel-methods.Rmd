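---
title: "Methods: somatic profiling of targeted tumor/normal panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic profiling of targeted tumor/normal panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the statistical machinery of `somaticpanel`: the
models behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic cohort does and does not emulate,
and the numerical and design choices that were genuinely open.

## The genotype caller

The caller is intentionally minimal: its input is a per-site base-count
pileup (counts of A/C/G/T) plus one mean Phred quality `Q` per site, not
per-read alignments. With error rate `e = 10^(-Q/10)`, a read's emission
probability under diploid genotype `g` is

```
P(b | g) = w * (1 - e) + (1 - w) * e/3,
```

where `w` is the fraction of `g`'s two alleles equal to `b` (1, 0.5
or 0). This is the exact distribution of "draw one of the genotype's
alleles uniformly, then corrupt it to a uniform other base with
probability `e`", and it sums to one over the four bases — a formulation
in which hom and het cases need no special-casing. The site
log-likelihood is the multinomial sum of counts times log emission
probabilities; the posterior uses prior mass `1 - θ - θ²` on homozygous
reference, `θ` split over the three reference-carrying heterozygotes and
`θ²` over the six remaining genotypes, with `θ = 0.001` (standard human
heterozygosity). Assumptions worth keeping in mind: one mean quality per
site (no per-read weighting), no strand or mapping-bias modelling, and no
indels — the analysis targets single-nucleotide substitutions only.

Two Phred-scaled summaries are attached to every call and drive all
downstream filtering:

* consensus quality `CQ = -10 log10(1 - P(best genotype))`, and
* variant quality `VQ = -10 log10(P(hom-ref))`, defined as 0 for
  homozygous-reference calls,

both capped at 255. `1 - P(best)` is computed as the explicit sum of the
other nine genotypes' posteriors: the naive subtraction loses all
precision once the posterior is within ~1e-13 of one, which at 110x
coverage it usually is. Ties are broken toward homozygous reference and
then lexicographically, making output deterministic. One behavioural
subtlety: for a pure alternate-allele pileup the winning genotype
switches from het to hom-alt as the evidence overcomes the prior
(around depth 11 at Q30), and CQ dips at the crossover; CQ is therefore
monotone in depth only once the winning genotype is stable.

## Calibrating thresholds against the genotyping array

Sequencing genotypes are mapped into the array's AA/AB/BB space through
each shared locus's allele pair; a sequenced allele outside the pair
counts as discordant, and no-calls on either platform are excluded. The
threshold grid retains a call when `CQ >= cq_cut`, `depth >= depth_cut`,
and — for non-reference genotypes only — `VQ > vq_cut`; hom-ref calls
carry VQ = 0 by construction and are exempt from the VQ axis, which is
how a "VQ > 0" filter can be applied to variant calls without discarding
every reference call. Threshold selection maximizes concordance among
grid rows retaining at least `min_retained_fraction` (default 0.85) of
the best-populated row — the retention floor is the package's concrete
reading of "maximize agreement while minimizing false negatives", which
names no explicit objective.

The mislabel screen exploits germline sharing: a matched tumor/normal
pair agrees at nearly all shared polymorphic loci, unrelated pairs only
at the Hardy–Weinberg chance level (~0.6 here). A pair is flagged when
its concordance falls below `median(unrelated) + 4 * MAD(unrelated)` —
a robust, deterministic margin; matched pairs sit so far above the
unrelated background that the precise margin is uncritical.

## The somatic filter cascade

A tumor variant survives if it passes the calling thresholds (default
CQ ≥ 50, VQ > 0), is absent from **every** normal sample's variant calls
— not just the matched normal, and tumor-only samples flow through the
same cohort-wide subtraction — and is absent from the known-polymorphism
panel. Matching is by position **and** alternate allele; position-only
matching would discard genuine somatic changes that happen to hit a
polymorphic site with a different allele. Normal-side detection is
deliberately unfiltered: any evidence of the allele in a normal marks
the site germline, which costs little sensitivity and guards against
leak-through.

Stop gains and losses count as "nonsynonymous" in the cascade counts and
rate statistics — protein-truncating changes are at least as consequential
as missense ones, and the boundary has to be fixed somewhere. Cascade
counts are per (sample, site) events; recurrent variants are not
deduplicated across samples, and this choice is deliberate and
documented here because either convention is defensible. The per-gene
deleterious rate divides the count of nonsynonymous events with
deleteriousness score `< 0.05` by the CDS length in amino acids, where
the stored CDS includes the stop codon but the amino-acid count excludes
it (a 1062-nt CDS encodes 353 residues). Variants without a score are
excluded from the numerator and reported as `n_unscored`. Percentages
(validation accounting, cohort frequencies) round halves away from zero,
so 16/68 prints as 24% and 2/68 as 3%.

## Copy number and integration

Segmentation is a simplified circular-binary-segmentation scheme: within
each contig, find the interior split maximizing the two-sample t
statistic (computed in O(n) by cumulative sums), test it against a
permutation null (default 1000 permutations in the standalone function,
500 in the pipeline; p ≤ alpha = 0.01 splits), and recurse with at least
`min_probes = 3` probes per segment. The full reference algorithm's
pruning and undo steps are omitted; on panel-scale probe sets the
maximal-t recursion recovers clean breakpoints (the test suite requires
≥ 95% of single-step breakpoints within ±2 probes at step/noise = 10).
Segment means are arithmetic probe means, so `Σ mean × n_probes`
conserves the probe sum exactly.

Gene-level copy number is the mean of probes overlapping the gene span
(probe-level rather than segment-level integration — it degrades
gracefully when a segment boundary crosses a gene). Amplification is a
strict `log2 > 0.6`; loss is the symmetric `log2 < -0.6` (only the gain
cutoff has an external anchor; symmetry is the package's choice).
Overexpression is a z-score > 2 against the normal-sample distribution,
echoing the "two standard deviations" present-call convention. The
concordant-gene ranking orders by (amplification frequency across
tumors, mean tumor z) rather than applying a hard frequency cutoff,
which no external source specifies. In the profile matrix, cell-state
precedence is confirmed mutation > unconfirmed mutation > amplified+
overexpressed > overexpressed > DNA loss, and a sample is actionable
when any gene on the configured actionable list is in a non-none,
non-loss state — the biology (which genes are actionable) lives in
configuration, not code.

## Expression statistics

Intensities are shifted by +1 before the base-2 logarithm (zeros are
legitimate; the offset is the smallest that admits them), then
quantile-normalized via `limma::normalizeQuantiles(ties = TRUE)`, so
tied values receive the mean over their rank range. Signature scores are
mean per-gene z-scores over a gene set, with z computed across **all**
samples (an option for normals-only exists; all-samples is the default
because the scores are used to order a mixed tumor/normal heatmap).
COPA median-centres and MAD-scales each gene over all samples and scores
the 90th percentile of the transformed values among tumors (the
reference algorithm's customary percentile); genes with zero MAD have no
scale and are excluded. qPCR CT values convert to abundance as
`10^((40 - CT)/3.5)` — parenthesized so that CT 40 maps to abundance 1
and each 3.5-cycle decrease is exactly one decade, the behaviour of an
assay near standard efficiency. Housekeeper adjustment computes a
per-sample robust score as the median of the two housekeepers' log10
abundances and regresses each target gene's log10 abundance on that
score, returning residual + grand mean; "robust score" and the ANCOVA
realization are underdetermined by any external description, and the
median-plus-regression reading is the simplest model consistent with
"used as a covariate".

## What the simulator emulates — and what it does not

Defaults reproduce the study conditions this pipeline is designed for:
36 matched pairs plus 8 tumor-only samples (44 tumors), 110x mean
Poisson coverage over a panel of coding exons, an array arm sharing
~1000 polymorphic loci with the sequenced targets (`germline_rate =
0.025` per bp is a **locus density** chosen to reproduce that shared-locus
count at desk scale; it is deliberately denser than genome-wide human
heterozygosity), per-genotype array error 0.5% and 1% no-calls, tumor
purity uniform on 0.4–0.9 (no external value exists; this range is a
stated assumption), 20% of somatic events subclonal at cancer-cell
fraction 0.3, somatic rate 8e-4/bp with an 8x hot gene, and
deleteriousness scores U(0, 0.05) for truly damaging variants versus
U(0.05, 1) otherwise, so the 0.05 boundary is meaningful by
construction. Germline leak-through is produced mechanistically — any
sample's site drops to Poisson(3) coverage with probability 0.02, and
each individual additionally carries 6 private novel germline variants —
not injected by fiat: tumor-only samples therefore leak their private
variants, and matched pairs leak only when the normal's coverage happens
to miss the allele, which are exactly the two mechanisms the validation
accounting attributes its germline class to. The expression matrix
carries 200 transcriptome background probes beyond the panel genes
because rank-based normalization over a 20-gene matrix is degenerate
(the implanted outlier gene would occupy the same rank in every column
and collapse to zero MAD); real arrays measure far more genes than a
panel sequences.

Not emulated: read-level artifacts (strand bias, mapping error, indels),
sequence-context mutation signatures, copy-number-adjusted allele
fractions (somatic VAF is purity × clonal-fraction × 0.5, uncoupled from
the simulated copy segments), linkage between polymorphic loci, and
population structure. Passing tests therefore demonstrate that the
statistics recover the generative structure they model — not that the
pipeline is robust to alignment artifacts real data would add upstream.

## Reproducibility and problem sizes

Every generator takes its seed from `sim_config`; per-stage child seeds
are derived with a fixed linear-congruential step, so a configuration
reproduces byte-identical outputs, reports and files. Desk scale is the
default: 20 genes of 1.5–2.4 kb (~39 kb of targets, ~80 samples,
~3 million simulated pileup rows, under a minute end to end); the
full-scale panel is a configuration choice, not a code change. The test
suite exercises the default-scale cohort once and shares it across
tests; segmentation recovery uses 100 single-step samples of 100 probes;
the caller oracle checks 500 random pileups against exhaustive
enumeration at 1e-6; the consequence annotator checks 1000 random
substitutions against full-CDS retranslation.

## Known limitations

* The caller's single mean quality per site discards within-site quality
  variation; equivalence with any historical per-read caller is neither
  claimed nor testable here.
* Segmentation significance is permutation-based and therefore has a
  granularity floor of 1/(n_perm + 1); alpha far below that is
  unattainable.
* The somatic filter cannot distinguish a germline variant novel to both
  the panel and all normals from a true somatic event — the simulated
  Sanger re-test quantifies exactly this residual class.
* COPA excludes zero-MAD genes rather than falling back to another scale
  estimate; on heavily discretized data this can drop genuine outliers.
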