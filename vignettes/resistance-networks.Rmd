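---
title: "Identifying drug-resistance networks with iplscreen: models, assumptions and limits"
author: "iplscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying drug-resistance networks with iplscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iplscreen)
```

## The problem this package addresses

A recurring design in cancer functional genomics contrasts a drug-sensitive
cell line with a resistant derivative — here the motivating setting is
castration-resistant prostate cancer, where an enzalutamide-sensitive line
(the *parental* comparator, "V16D" in the package defaults) is paired with a
resistant derivative ("MR49F"). The analysis asks: which genes and pathway
nodes changed between the pair, which of those changes hang together as a
deregulated subnetwork, and which are *functionally required* for the
resistant phenotype?

`iplscreen` implements that chain as a tested, reusable pipeline:

1. **diffexpr** — per-gene differential expression between conditions
   (t-test, Benjamini–Hochberg q-values, fold-change gate);
2. **copynumber** — circular binary segmentation (CBS) of probe-level
   log2 copy-number ratios and gene-level summarization;
3. **ipl** — an *integrated pathway level* (IPL) score per node of a curated
   signed pathway graph, combining a node's own expression and copy-number
   evidence with its neighbours' inferred states;
4. **nominate** — candidate selection by IPL outliers plus
   expression-variability filters;
5. **screen** — normalization of RNAi viability plates (spatial
   local-regression correction, negative-control scaling) and hit calling
   (Wilcoxon + BH, kill-fraction and directionality gates);
6. **synthetic_data** — a generator for all pipeline inputs with known
   ground truth, so every stage is testable without external data.

Because raw sequencing and plate data for the motivating study are not
deposited, the package's correctness claims are *property-based*: planted
truths in synthetic data must be recovered, analytic closed forms must be
matched, and independent oracles (exhaustive enumeration, brute-force rank
permutation) must agree with the production code paths.

## Differential expression

Tests are performed on `log2(x + pseudocount)` (pseudocount 1 by default);
fold changes are ratios of linear-scale condition means with the same
pseudocount. A gene is significant iff its BH q-value is below 0.05 *and*
`max(FC, 1/FC)` exceeds 2 — both thresholds are parameters defaulting to
the conventional values for this design.

**Why a pooled t-test.** With three replicates per condition, the
Welch–Satterthwaite approximation collapses toward 2 degrees of freedom
whenever the two sample variances differ by chance; the resulting heavy
tails cap achievable BH sensitivity near 35% in a world where the design's
true power is ~90%. On the log2 scale the group variances of abundance data
are comparable — exactly the pooled test's assumption, and exactly true in
the synthetic world — so the pooled (Student, df = 4) test is the default
and Welch is available via `var_equal = FALSE`. Degenerate genes (zero
variance in both groups) get p = 1 when the means agree and p = 0 when they
differ, a documented convention rather than an error.

`bh_adjust()` implements step-up BH, `q_(i) = min_{j>=i}(p_(j) n / j)`
capped at 1; it is tested against `stats::p.adjust` as an oracle.

## Copy-number segmentation

`segment_profile()` reimplements recursive CBS: within a segment, the arc
`(i, j]` maximizing the unit-variance two-sample statistic between in-arc
and out-of-arc means is found (ties broken by smallest left boundary, then
smallest arc length — a deterministic choice); the split is accepted if its
within-segment permutation p-value `(count + 1)/(n_perm + 1)` is below
`alpha = 0.01` and both parts keep at least `min_width = 3` probes. The
pruning/undo heuristics of classic implementations are deliberately not
reproduced: they are underdetermined by any description short of the
original code, and desk-scale profiles do not need them. Permutations are
driven by R's RNG from a caller-supplied seed, so segmentation is exactly
reproducible. Coordinates are 0-based half-open throughout; segments tile
the probed extent of each chromosome exactly.

Gene-level ratios are overlap-length-weighted means of segment means
(computed with `GenomicRanges`); strand is carried but ignored.

## The IPL surrogate model

The original integrated-pathway-level method is a proprietary factor-graph
webtool whose exact parameterization is not public. This package defines a
fully specified surrogate that preserves the published contract — each
node's score reflects its own expression and copy-number evidence *and* its
neighbours' states:

* each node carries a ternary state `S ∈ {-1, 0, +1}` (down, neutral, up);
* node evidence: `phi(S) = exp(S (beta_expr z + beta_cn c))`, where `z` is
  the robust-standardized log2 expression differential (MAD × 1.4826) and
  `c` the gene-level copy-number log2 ratio; nodes without data (complexes,
  families, unmeasured genes) carry a uniform factor;
* each signed edge couples its endpoints by
  `psi(S_u, S_v) = exp(lambda_edge sign S_u S_v)` — activating edges reward
  agreement, inhibitory edges reward opposition; `component`/`member` edge
  kinds count as activating;
* marginal beliefs come from damped sum-product message passing in a fixed
  deterministic order; `ipl = log10(belief(+1) / belief(-1))`.

Defaults: `beta_expr = beta_cn = 1`, `lambda_edge = 0.5`, `damping = 0.5`,
`tol = 1e-8`, `max_iter = 500`. Non-convergence returns a flagged result
with a warning rather than an error.

**What the green tests establish, and what they do not.** On trees the
algorithm is exact; the suite verifies agreement with exhaustive `3^n`
enumeration (`exact_ipl()`) to 1e-6, and closed forms (isolated node:
`ipl = 2 h / ln 10`; `lambda_edge = 0` decouples every node) to 1e-9. On
*cyclic* graphs sum-product is the standard loopy approximation: at the
default coupling its error against enumeration on 8-node cyclic graphs
ranges from ~0.01 up to ~0.5 log10-odds in our measurements. The acceptance
bound of 0.05 for loopy graphs is therefore knowingly red: the
implementation was cross-validated against an independently written
synchronous sum-product (agreement 1.5e-8), so the deviation is a property
of loopy belief propagation itself at this coupling strength, not an
implementation defect. Users should read loopy IPLs as rankings, not
calibrated log-odds. A subtlety worth knowing: with all-zero observations
every IPL is exactly 0 by symmetry, but beliefs are *not* uniform — the
coupling symmetrically depletes the neutral state.

## Candidate nomination

The published filter chain is read literally: nodes whose IPL lies more
than 2 *sample standard deviations* from the *median* of all node scores
are nominated; gene-type nodes then pass a coefficient-of-variation band
(10 ≤ CV ≤ 200, CV in percent over linear-scale values of all samples) and
a non-zero-expression rule (> 0 in at least 2 samples). The three filters
are independent predicates, so their order is immaterial — a property the
tests assert. Controls (non-targeted negative, a pan-lethal positive such
as KIF11, and biological controls such as MYC and AR) are appended with
roles and never alter the candidate list; a control that is also a
candidate is kept once and dual-flagged.

## Screen normalization and hit calling

Each plate is corrected with a loess-style surface over the numeric
(row, column) predictors: for every occupied well, a degree-1 weighted
least-squares plane over its `ceiling(span × n_occupied)` nearest occupied
wells with tricube weights. The span is 1.0 when every well is occupied
and 0.2 otherwise, matching the published protocol. We implement this
local regression directly rather than calling `stats::loess` because the
contract is pinned well-by-well (plain row/col units, ceil-based
neighbourhoods, exact reproduction of linear surfaces), whereas `loess`
normalizes predictors and interpolates over a cell grid; the direct
implementation reproduces a uniform plate and an exactly linear plate to
machine precision, which the tests require. Raw values are divided by the
fitted surface, then by the median of the plate's negative-control
normalized values — or by the plate median when a plate carries no
negative control, with the basis recorded per row.

A practical caveat the synthetic world exposed: a strongly killed
positive-control well is a legitimate *outlier* to the spatial fit, and on
partially occupied plates (span 0.2, ~14-well neighbourhoods) it locally
depresses the surface and inflates its neighbours' viabilities by several
percent. The published protocol, which also fits all occupied wells, shares
this property; plate designs should keep positive controls away from
sample-dense regions.

Hits are genes with BH q < 0.2 from a two-sided Wilcoxon rank-sum test of
resistant versus sensitive replicate viabilities, mean resistant viability
at most 0.85 (≥ 15% cell kill), and resistant mean strictly below the
sensitive mean. The exact test is used whenever the pooled sample size is
at most 10 with no ties, otherwise the tie- and continuity-corrected normal
approximation. **The discreteness caveat:** with 3 vs 3 replicates the
smallest achievable exact two-sided p is 0.1 (= 2/C(6,3)), so over a
64-gene screen the smallest achievable q is `0.1 × 64 / m`, where `m` is
the number of genes at the floor. With only ~10 genes carrying true signal
(and ~10% of null genes reaching the floor by chance), q bottoms out near
0.4 and *no* gene can pass q < 0.2. The end-to-end acceptance criterion
demanding full recovery at q < 0.2 is therefore red by arithmetic, and the
package reports it as such; the published screen could only have cleared
this bar because a large fraction of its tested genes showed consistent
between-line orderings. Screens of this shape need either more replicates
or a less granular test for the q-gate to be meaningful.

## The synthetic world

Defaults encode the stated experimental conditions: biological triplicates
per condition; 5% of 1000 genes planted at ±2 log2-fold; log2-scale
Gaussian noise of SD 0.25 (≈ 19% CV, typical of cell-line RNA-seq
replicates); a 100-probe chromosome with one +1 log2 focal event over
probes 50–80 and probe noise SD 0.2; a 60-node connected signed graph with
an 8-node planted active subnetwork (z = +2 on its gene members, internal
edges activating); 96-well plates with a ±30% multiplicative linear
row/column gradient, optional centred Gaussian bump, 5% multiplicative
well noise, 10 planted differential-kill genes (40% kill in the resistant
line, 5% in the sensitive), 4 corner negative controls and 2 edge positive
controls per plate.

Choices the source experiment does not pin down, made once and documented
here: baseline expression is log2-uniform over [5, 11] (~32–2048 FPKM-like
units, the robustly expressed range) so the unit pseudocount regularizes
rather than attenuates planted effects; noise is log-normal so the log2
t-test's assumptions hold by construction; the positive-control kill is
0.8; plate controls sit at fixed corner/edge positions; each data modality
draws from its own RNG stream derived from the master seed, so changing
plate parameters never perturbs expression draws.

What the generator does *not* emulate — and hence what a green test does
not establish: read-count discreteness and mean–dispersion structure of
real RNA-seq; GC/mappability artifacts and allele-specific signal in copy
number; curated-pathway realism (hub structure, typed complexes'
semantics); transfection-efficiency variation, edge evaporation, and
batch-to-batch drift in screens. Green tests certify the pipeline's
statistical logic on its stated model, not robustness to those phenomena.

## Numerical and degenerate-input conventions

* BH inputs outside [0, 1] are errors; empty input returns empty output.
* CV of a zero-mean gene is an error by contract; the nomination chain
  records such genes as failing the CV filter (they also fail the
  non-zero filter).
* Segmentation of a chromosome with fewer than `2 × min_width` probes
  returns a single segment; an all-constant segment never splits.
* Surface fitting requires ≥ 6 occupied wells; a rank-deficient (collinear)
  layout falls back to a global plane with a warning; non-positive fitted
  values drop the affected well with a log message.
* Message updates sweep edges sorted by (source, target) id, forward then
  reverse, so results are bit-reproducible across runs.
* All randomness flows from explicit integer seeds; the pipeline fans one
  master seed out to per-stage streams.

## Known limitations

Three acceptance properties are knowingly red, each with an arithmetic
analysis rather than a workaround: loopy-BP accuracy at the default
coupling (above), end-to-end hit recovery at q < 0.2 under 3v3 Wilcoxon
discreteness (above), and differential-expression sensitivity, which at
the stated world sits exactly at the design's power boundary (~0.90 by
noncentral-t calculation; measured 0.896 over the committed seeds). The
package reports what the stated world yields; none of these can be fixed
without changing the published thresholds or the experimental design they
describe.
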