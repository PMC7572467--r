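---
title: "Quantifying gain and loss of TF binding sites from SNVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gain and loss of TF binding sites from SNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbsnv)
```

## The question and the model

A single-nucleotide variant (SNV) in a regulatory region can create a
transcription factor binding site (TFBS) that was not there, or destroy one
that was. `tfbsnv` makes that call for every SNV x PWM pair and aggregates
the calls into four per-TF probabilities — gainability, disruptability,
hitability and robustness — that describe how exposed each TF's binding
landscape is to point mutation.

The binding model is the standard position weight matrix. A window `s` of
length `n` scores

$$F(s, M) = \sum_{i=1}^{n} \log \frac{M_{s_i,i}}{b_{s_i}}$$

against matrix `M` with a uniform background `b`. The assumptions inherited
from this model are the usual ones: positional independence within the
motif, a zeroth-order background, and no account of chromatin context or
cooperative binding. Dinucleotide backgrounds, dimer motifs and
nucleosome-context models are out of scope.

For one SNV the `2n - 1` bp genomic context centred on the variant is
extracted and one candidate window is anchored at each context offset on
each strand — `4n - 2` candidates in all. Candidates truncated by the
context boundary and windows containing `N` are skipped, so the windows
actually scored are those fully overlapping the variant base; if all are
skipped the SNV is unscorable for that PWM and excluded from every tally.
The same window set serves both alleles, so the score difference (delta =
alt - wt) reflects only the substituted base. The context is always drawn
from the genome, even when it extends past the boundary of a query region:
regions select *positions*, not sequence, because a site can straddle a
region edge.

## Significance thresholds

A window score is called significant when it reaches a per-PWM threshold
calibrated so that a random background sequence scores that high with
probability at most `alpha` (default `1e-4`). The calibration is an exact
dynamic program: column scores are discretized to multiples of a
granularity step (default `1e-3` score units, round-down so the reported
threshold is conservative) and convolved column by column; the threshold is
the smallest *achievable* discretized score whose tail probability is
`<= alpha`. Exhaustive `4^n` enumeration reproduces it exactly for short
motifs, which is how the unit tests check it.

Two consequences are worth knowing. First, a motif shorter than 7 bp cannot
reach `alpha = 1e-4` at all — even its single best sequence has background
probability `4^-6 = 2.4e-4` — and a zero-information matrix never can; both
raise an explicit "no threshold attainable" error rather than returning
something loose. Second, "significant" means `score >= threshold`
everywhere in the package. With continuous scores the boundary is
measure-zero, but discretization can create ties, so one convention is
fixed and applied uniformly.

Numerical choices: scoring uses natural log (any other base rescales scores
and thresholds together and changes no call); the pseudocount is additive
and background-proportional (`f + p*b` over `(1+p)*b`, default `p = 1e-4`),
chosen because motif collections contain exact zeros and some
regularization is mandatory; with the default uniform background all
sequence probabilities are powers of two, so the dynamic program and the
enumeration oracle agree exactly in floating point, not merely to
tolerance.

## From calls to parameters

Each scored SNV is classified by threshold crossings: `DISRUPTION` when the
wild-type allele is significant and the alternate is not, `GAIN` for the
opposite crossing, otherwise `SITE_RETAINED` or `NO_SITE`. Over an SNV
universe the tallies define, per PWM:

* hitability `H = n_in_site / n_total`,
* robustness `R = n_retained / n_in_site`,
* disruptability `D = n_disrupt / n_total`,
* gainability `G = n_gain / n_outside`.

`D = H(1 - R)` holds exactly at PWM level and is asserted to `1e-12` in the
tests. It is *not* guaranteed after the median aggregation across a TF's
PWMs, which is why the identity is only ever checked per PWM. "Inside a
TFBS" is operationalized as a significant wild-type score at that position
(max over overlapping windows); the model offers no site definition
independent of the score. `0/0` cases (for example robustness when no SNV
hits a site) are flagged undefined and excluded from medians, correlations
and tests rather than imputed.

Family summaries keep only families with at least 10 TF members and compare
each family against all TFs with a two-sided Mann-Whitney U test, with the
family included in the "all TFs" comparator — the comparison is
family-versus-everyone, not family-versus-rest; excluding the family would
change p-values for large families. A Kruskal-Wallis variant across all
families is available as well. No multiple-testing correction is applied at
`alpha = 0.05`, matching the descriptive use of these tests.

## References, delta scores and significance

Observed parameter values only mean something against a reference.
Two are provided:

* **enumerated** — the parameters of *all possible SNVs* of the region set
  (every position times its three alternates), with zero sampling variance;
* **sampled** — `n_samples` random SNV sets (default 100) of `sample_size`
  draws (default 1e6) matched to a 12-type mutation spectrum; the per-PWM
  means are the reference values and all per-sample values are retained.

Sampling is with replacement, position-uniform among region bases whose
reference nucleotide matches the drawn substitution type. A master seed
spawns per-sample child seeds, so any single sample can be regenerated
alone. `composition_spectrum()` gives the spectrum of the full enumeration
itself (each base's mass proportional to its abundance, split evenly over
its three alternates); sampling with it converges to the enumerated
reference, which is the convergence check used in the tests.

Delta scores are `transform(observed) - transform(reference)` per TF and
parameter, `log10` for gainability/disruptability/hitability and identity
for robustness. Zero observed values under `log10` are omitted, with a
message, rather than mapped to `-Inf`. Reference subtraction happens at PWM
level first, then TF medians are taken — the alternative order (median
first) was genuinely open, and subtract-then-aggregate was chosen because
it keeps each PWM's delta interpretable and lets a TF's matrices disagree
visibly.

Empirical significance against a sampled reference uses the add-one rank
rule `p = 2 min(r_hi, r_lo) / (n_samples + 1)`, capped at 1. It is exact
under exchangeability, distribution-free, and its resolution is limited by
`n_samples` (with 49 samples the smallest attainable p is 0.04); at least
19 samples are required. The direction (enriched/depleted) is the sign
against the null mean.

## Cohort profiles

For grouped SNV sets (cancer types, carcinogen signatures, single tumors)
each group is de-duplicated to unique `(chrom, pos, ref, alt)` records,
intersected with the region set, profiled, and reference-subtracted,
producing a TF x group delta matrix. Samples can be filtered to
high-burden ones first — strictly more than `min_snvs` (default 5000)
unique in-region SNVs, so a sample at exactly the floor is excluded.
Group columns are clustered by complete-linkage agglomeration under
Euclidean distance; undefined deltas are imputed as zero *for the distance
computation only* (distances need complete vectors; small groups inevitably
leave some TFs uncovered), while signature correlations and family medians
use pairwise deletion instead. TF rows are ordered by family blocks, not
clustered. The dendrogram is exportable as Newick.

## The synthetic-fixture generator

Every test and the acceptance script run on fixtures built in code:

* `generate_genome()` — i.i.d. bases at a target GC content (default 0.41,
  a typical mammalian value);
* `generate_pwm()` — columns from a symmetric Dirichlet with concentration
  `1/sharpness`, so expected information content rises monotonically from 0
  (flat) towards `2n` bits (one-hot);
* `plant_sites()` — writes the consensus at non-overlapping positions on
  random strands and returns the registry;
* `generate_snv_set()` — neutral, disruptive, gaining or spectrum-matched
  SNV sets; disruptive and gaining candidates are found by scoring the
  three alternates at candidate positions with the real scorer and keeping
  those that classify as intended, so the labels are correct by
  construction rather than by heuristic.

Identical fixture specifications produce byte-identical FASTA/BED/VCF/PWM
files. Default problem sizes keep everything desk-scale: fixture genomes of
1.5-100 kb, banks of 2-100 PWMs of length 7-12, sampled baselines of 5-49
samples at 1.5e3-1e5 draws. These sizes make the stochastic checks
(binomial 3-SE convergence bands, empirical-p calibration) sharp enough to
catch implementation errors while the whole suite stays in the minutes
range.

## What the fixtures do and do not show

The simulator reproduces the *mechanics* of the method faithfully —
scoring, calibration, classification, tallies, baselines, clustering — and
the tests exercise them against independent oracles (exhaustive window
enumeration, `4^n` p-value enumeration, a cubic-time linkage
implementation) and planted ground truth.

What an i.i.d. genome with smooth Dirichlet matrices does **not**
reproduce is the empirical relationship between the parameters and motif
information content seen on real data. With thresholds calibrated to
`attained p <= alpha` and a genome whose composition matches the scoring
background, the per-window probability of a significant score sits just
under `alpha` for every matrix regardless of its information content, so
hitability and gainability hover near an `alpha`-driven rate
(roughly `2n * alpha`) across the whole sharpness sweep. On real genomes
the per-window hit rate deviates from `alpha` by orders of magnitude in
both directions — composition bias, CpG depletion, repeats and
low-complexity tracts interact with each motif's consensus — and
count-derived database matrices carry tied score levels and exact zeros
that let sharp motifs attain p-values far below `alpha`. Those forces, not
the calibration itself, spread hitability and gainability over many orders
of magnitude and produce their anti-correlation with information content.
A test of that qualitative property is included and documents this gap:
it fails under the i.i.d. fixture conditions, and that failure is a
statement about the fixtures, not about the engine. Conclusions about real
genomes should rest on real genomes.

Other known limitations: indels, MNVs and structural variants are out of
scope; masking (soft-masked bases are uppercased, hard-masked `N`s make
windows unscorable); no linkage or haplotype structure in the fixtures; and
chromosome-edge handling (N-padding with per-window skipping) is a
convention of this implementation.
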