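---
title: "Methods: statistics and simulation behind ribosense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and simulation behind ribosense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosense)
library(dplyr)
```

## The assay and the estimand

ribosense analyzes massively multiplexed selections of RNA biosensors
(aptazymes): hammerhead ribozymes whose self-cleavage is inhibited when a
small-molecule ligand binds a randomized aptamer loop. The readout is a
cleavage-sequencing assay in which cleaved and uncleaved molecules of every
library member receive distinguishable 5' prefixes and are counted by NGS.
For a sequence with `a` cleaved and `b` uncleaved reads, the cleavage
fraction is `a / (a + b)`, and the response to a ligand condition is the
**fold change of cleavage**, the odds ratio

```
fc = (a_ref * b_test) / (b_ref * a_test)
```

between the no-ligand (reference) and with-ligand (test) conditions. A fold
change above 1 means the ligand inhibits cleavage. Everything downstream —
pool deconvolution, clustering, cross-reactivity, dose summaries, hit/miss
labels — is a function of these per-sequence odds ratios and their
uncertainties.

## Fold-change statistics

`fold_change()` adds a Haldane–Anscombe pseudocount of 1/2 to each of the
four counts before forming the odds ratio, which keeps zero counts usable
and reduces small-sample bias. On the log scale the delta-method standard
error is

```
se(log fc) = sqrt(1/a' + 1/b' + 1/c' + 1/d')
```

with primes denoting pseudocounted counts. Wald intervals
`exp(log fc ± z * se)` give the 90% and 95% CIs, and a two-sided normal
tail of `log fc / se` gives the p-value. At the depths this assay runs
(hundreds of reads per sequence per condition) the normal approximation is
accurate: the test suite verifies 95% CI coverage of 95% ± 2% at 200
reads/condition over 10^4 simulated sensors, and that the Bonferroni rule
`p < 1/N` produces on the order of one false positive per experiment of
N = 10^4 null sequences (both are Monte-Carlo checks, re-run on every test
execution).

Condition-wide odds biases (ligation or RT efficiency differences between
runs) are removed with unresponsive **reference sequences**:
`normalize_by_references()` takes `k` as the median raw fold change over
references with at least `min_reads` (default 100) reads in both
conditions, requiring at least 3 usable references (otherwise it warns and
uses `k = 1`). The median is robust to a single contaminated or weakly
responsive reference. All fold changes are divided by `k`.

`call_significant()` flags a record when `p < 1/N` (Bonferroni over the
`N` sequences tested), both conditions have at least `min_reads = 100`
reads, and the fold change clears a threshold (default 2) in the tested
direction. The fold-change gate matters in practice: a deeply sequenced
null sequence can be statistically significant at a biologically trivial
1.1-fold.

## Pool design and group-testing deconvolution

Screening every sensor against every compound individually is infeasible at
5,120 compounds, so compounds are pooled twice over: two selection halves
(A/B) and, for deconvolution, `r` independent partitions of the library
into equal pools (the canonical design: 9 partitions of 20 pools of 256,
i.e. 180 mixtures, so each compound sits in exactly 9 pools). Pools must
stay interpretable by LC-MS, so `design_pools()` enforces that no two
compounds in a pool have expected adduct m/z values (over M+H, M+Na, M+NH4
by default) within `mz_window` (default 0.01 Da). Assignment is a
randomized greedy pass per partition with a swap repair and restart on
failure — the constraint is loose at this scale, so exact constraint
solving is unnecessary — and an infeasible instance reports the largest
clique of mutually conflicting compounds. `audit_pool_design()` re-checks
all invariants from scratch, using the sorted-gap equivalent of an
all-pairs scan.

A sensor measured against all pools induces a pool classification
(`classify_pools()`): **responsive** (significant and fold change >=
threshold), **nonresponsive** (upper 95% CI below threshold — affirmative
evidence of no response), or **indeterminate** (too noisy to call; unmeasured
pools are indeterminate too). `decode_pools()` then scores every compound by
`support` (its responsive pools) and `violations` (its nonresponsive pools):
a candidate must be supported by at least `support_min` (default 0.8,
tolerating one dropped pool of 9) of its measured pools and violate at most
`violations_max = 1`. A greedy set cover over the responsive pools — ties
broken by support, then violations, then compound id — yields the minimal
explanation; exhaustive minimal-cover enumeration is available as a
verification mode for up to 12 candidates, and the test suite checks decode
against a brute-force consistent-subset oracle on small designs.

A sensor is declared **promiscuous** when it responds in more than half of
its measured pools or when its minimal explanation needs more than
`promiscuity_cap = 10` distinct compounds. We deliberately base the cap on
the size of the minimal explanation rather than the raw candidate tally:
under read noise, compounds measured in only one or two pools (everything
else indeterminate) can trivially satisfy the support rule, inflating the
candidate list for sensors that respond in only a handful of pools; the
number of compounds actually needed to explain the pattern is the quantity
the ~10-target decodability limit refers to. `decodability_report()`
quantifies that limit on any design by Monte Carlo: the fraction of random
target sets whose responsive-pool pattern has a unique minimal explanation,
which is 1 for singletons by construction and decays rapidly as target sets
grow toward the per-partition pool count.

## Response profiling

Two sensors' response profiles are compared with the noise-scaled distance

```
d'(i, j) = max over conditions v of |log fc_iv - log fc_jv| / sqrt(se_iv^2 + se_jv^2)
```

a symmetric premetric in units of combined standard errors; missing cells
are excluded from the maximum rather than imputed. `cluster_sensors()` runs
complete-linkage agglomeration on d' and cuts flat clusters at a height of
3 by default (~3 combined SEs): complete linkage guarantees every
within-cluster pair sits within the cutoff. The cutoff is exposed as a
flag; cluster counts on real data depend on it and we make no claim of
reproducing any particular published count. Cluster representatives are the
highest-abundance members (ties by id), and dendrograms export as Newick
with d' heights.

Cross-reactivity at fold threshold `f` counts, per sensor, the compounds
inducing at least `f`-fold change; per compound it is the minimum such
count over the sensors it activates, and the summary curve accumulates
compounds with cross-reactivity at most `C`. These curves are
non-decreasing in `C`, and the total number of sensed compounds is
non-increasing in `f`; note that the count at a *fixed small* `C` is not
monotone in `f` (raising `f` also lowers surviving sensors'
cross-reactivities, which can move compounds under `C`).

Dose series report the **minimum measured concentration** at which the fold
change reaches 2 with its 95% CI lower bound above 1 — no interpolation
between dilution points, so the result is always a tested concentration.
Sensors that respond to a companion compound co-assayed in the same well
(judged from single-compound data at the reference concentration) are
masked with an explicit reason rather than reported.

## Fragment-based hit prediction

Sensor-compound pairs are labeled from the 90% CI of the fold change: hit
if the lower bound exceeds 2, miss if the upper bound is below 2,
indeterminate otherwise — a pure function of the interval, property-tested
against the fold-change output. Compounds are featurized as presence bit
vectors over a **circular-fragment vocabulary**: canonical atom
environments of radius 0..3 obtained by Morgan-style iterative relabeling
of the molecular graph (parsed from SMILES via ChemmineR/OpenBabel). The
vocabulary is the union over the library with a fixed, persisted bit
order; its size is emergent from the library, not forced. Per sensor,
`loo_evaluate()` trains a 200-tree random forest on all other labeled
compounds and predicts the held-out one, for every compound in turn —
leave-one-out, with the held-out label provably outside training (the test
suite plants a mislabeled compound and verifies the prediction follows the
fragments, not the planted label). Sensors with fewer than 3 hits are
skipped for lack of training signal. `aggregate_metrics()` sums confusions
across sensors, reports precision TP/(TP+FP), and pools all scores for a
single AUC; per-sensor tables carry the same columns.

## Selection dynamics

`run_selection()` simulates alternating-round enrichment: per round each
sequence survives with weight `c` (cleave selection) or `1 - c` (non-cleave
selection with ligand), where `c` is its model cleavage under the round's
mixture; abundances are re-weighted, renormalized (PCR is modeled as pure
renormalization since only relative abundance is analyzed), and
multinomially resampled at the round's `sample_size`. The default schedule
is 7 ligand-free cleave-selection rounds, then strict alternation with the
target mixture at 2 uM per compound, dropping to 1 uM from round 88 with
the counter-mixture (the other selection half) added to the late
cleave-selection rounds to select against cross-reactive sensors.

Amplicon parasites — sequences that evade the RT-primer block and so
survive regardless of the round's sense — get a constant per-round weight,
default 0.80. The value is chosen to reproduce the qualitative dynamics of
real selections: it must exceed the alternating-phase fitness of any
non-switching ribozyme (at most `sqrt(c(1-c)) <= 0.5` per round), so
amplicons surge while ordinary sequences die, yet sit below a good
switcher's per-round fitness (~0.75-0.85), so true biosensors eventually
outcompete them. A constant at or above ~0.9 would make amplicons
unconditionally dominant, which real selections do not show.

Two desk-scale choices matter for end-to-end simulations. First, the
per-round carryover (`sample_size`, default 10^5 molecules) stands in for
experimental bottlenecks that in reality exceed 10^12 molecules; for
studies tracking 10^4 distinct sequences we raise it to 10^6 so that the
bottleneck-to-diversity ratio, and hence drift, is in the regime of the
real protocol rather than an artifact of the scale-down. Second,
sequencing checkpoints subsample abundances at a finite read budget with
detection floor 1/reads (`track_abundance()`).

## Pooled LC-MS verification

Mixture identity is verified per compound from peak lists of the pools
expected to contain it plus control pools that should not.
`identify_compound()` matches peaks to each adduct's expected m/z within
10 ppm, clusters matches by retention time (single-linkage, 0.1 min — the
tolerances are instrument-typical defaults, exposed as flags), and scores
each (adduct, rt-cluster) signature by expected-pool presence, then control
presence, then mean intensity. Identification requires presence in at
least 4 of 5 expected pools and no control appearances (both
configurable); a second library compound sharing the winning m/z (and
retention time, when known) within tolerances makes the call ambiguous
rather than identified. Retention times are clustered globally across the
runs rather than per pool — with a 0.1 min tolerance this is the stricter
and simpler of the two readings. Identification is invariant to peak-list
order and intensity rescaling, and tightening the ppm tolerance can only
lose matches; all three are property-tested.

## What the synthetic data does and does not emulate

`generate_library()` builds randomized-loop members on a hammerhead-style
scaffold (stem I ACTGGA:TCCGGT; a 4-8 nt loop and a 30 nt aptamer loop,
uniform per position), with flagged unresponsive references and amplicon
parasites, and Dirichlet-uniform abundances. Ground-truth responses
(`generate_response_models()`) use a saturating fold change
`FC(x) = 1 + (fc_max - 1) x / (x + ec50)` — monotone in concentration with
`FC(0) = 1` and a plateau at `fc_max` — and multiple cognate ligands
combine multiplicatively on FC (additively in log-odds). Counts are
multinomial over abundances and binomial in the cleavage probability, with
an optional condition-wide odds bias for normalization tests. Reads
round-trip exactly through the FASTQ/FASTA writer and the counting module.

Defaults that the data do not pin down and that we fix once as fixtures:
baseline cleavage `c0 ~ Beta(5, 2)` (an enriched library cleaves well) and
`fc_max ~ logUniform(2, 17)`, `ec50 ~ logUniform(0.025, 5) uM` spanning
the observed sensitivity range. For screens that represent a
*post-selection* characterized pool we restrict baseline cleavage to
[0.2, 0.9]: sequences at the extremes have near-zero alternating-round
fitness (the per-pair weight is `c(1-c)`-like) and do not survive 95
rounds, so an enriched pool concentrated near complete cleavage is not a
realistic study population.

Not emulated: sequencing errors (reads are exact; the counting module
supports a mismatch tolerance on the fixed prefixes/suffixes but inserts
are matched by exact identity, with near-duplicate collapse out of scope),
RNA folding, chromatographic drift or isotope structure in MS, and
sequence-level mutation during selection. Passing tests therefore validate
the statistics and decoding logic under the stated noise model, not
robustness to these additional real-data artifacts.

## Known limitations

One no-ligand reference run typically serves every test condition of a
screen. Its sampling error is therefore *shared* across a sensor's fold
changes: an unlucky reference draw offsets all of that sensor's odds
ratios together, and the per-comparison p-values — which treat each
(reference, test) pair as independent — cannot flag it, Bonferroni or not.
The practical mitigations are sequencing the reference condition several
times deeper than the test conditions (the worked example in the README
does this) and the violation allowance in the decoder, which tolerates
isolated misclassified pools. Reference-based normalization removes
condition-wide biases but its own estimation noise (a median over a small
reference set) is likewise not propagated into the intervals.

## Problem sizes

The test suite runs everything at sizes chosen to finish in minutes while
keeping the statistics honest: fold-change calibration at 10^4 sensors x
200 reads; the null at 20 replicates of 10^4 sensors x 1,000 reads; the
full pooled screen at 5,120 compounds, 180 pools, 185 sequences, 200
reads/sequence/pool; the end-to-end selection at 10^4 sequences over 95
rounds with 10^6-molecule carryover and 10^6-read final characterization;
LOO classification at 20-40 compounds per sensor. Brute-force oracles
(all-pairs scans, exhaustive subset enumeration, closed-form weight
products) run on deliberately small instances where they are exact.
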