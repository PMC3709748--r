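---
title: "Methods: discovering miRNA-regulated protein interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering miRNA-regulated protein interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpin)
```

## The problem

MicroRNAs repress their target mRNAs, so a miRNA that is differentially
expressed between normal and tumor tissue and whose predicted targets move
in the *opposite* direction is a candidate regulator of a tumor-associated
program. `mirpin` implements a five-stage discovery pipeline for such
regulators in breast-cancer-style two-group expression designs:

1. **Differential expression** of miRNAs and mRNAs with a SAM-style
   permutation statistic.
2. **Consensus pairing** of oppositely regulated miRNA-gene pairs backed
   by at least two of the supplied target-prediction databases.
3. **Network construction**: each miRNA's consensus targets (layer L0)
   are expanded by their direct protein-interaction partners (layer L1)
   from a reference interaction map such as HPRD.
4. **Functional characterization** by level-filtered hypergeometric GO
   enrichment with Benjamini-Yekutieli FDR control, plus a keyword rule
   flagging cancer-related terms.
5. **Marker evaluation** of each network's miRNA by ROC analysis on an
   independent expression profile.

The package consumes normalized TSV matrices, per-source target tables,
a PPI edge list, an OBO-subset ontology and GMT annotations; it does not
download or parse vendor-specific database dialects.

## Differential expression

For each feature the moderated statistic is

$$ d = \frac{\bar x_T - \bar x_N}{s + s_0}, \qquad
   s = \sqrt{\left(\tfrac1{n_T} + \tfrac1{n_N}\right)
   \frac{\sum_T (x-\bar x_T)^2 + \sum_N (x-\bar x_N)^2}{n_T+n_N-2}} $$

computed on log2-scale values. Linear-scale input is transformed as
$\log_2(x + 1)$; the pseudocount (configurable) keeps count-like zeros
finite. The exchangeability factor $s_0$ defaults to the median of the
per-feature scatter; a Tusher-style percentile search (minimizing the
coefficient of variation of the within-decile dispersion of $d$ over the
$s$-percentiles $0, 5, \dots, 100$) is available as
`s0_strategy = "percentile_search"`. With constant scatter the search is
degenerate and the median is returned with a warning.

The false discovery rate attached to each feature uses the permutation
null: with the observed $|d|$ as threshold $t$,

$$ q = \frac{\text{mean over permutations of } \#\{|d_{perm}| \ge t\}}
            {\#\{|d_{obs}| \ge t\}}, $$

clipped to $[0,1]$ and monotonized (step-up) so that $q$ never increases
with $|d|$; ties in $|d|$ share a value. Two numerical choices matter
here:

* The observed group assignment and its mirror image are **excluded**
  from the null set. $d$ is antisymmetric under the group swap, so both
  reproduce the signal rather than the null; including them would floor
  the q-value of a perfectly separated feature at $2/P$ instead of the
  exact 0 that full enumeration should deliver.
* When $\binom{n}{n_T} - 2$ is at most the permutation cap (default
  1000) all assignments are enumerated and the result is
  bit-reproducible; otherwise the cap is sampled from the run seed.

Selection combines both study thresholds: a feature is kept iff
$q \le q_{thr}$ (default $10^{-6}$, the literal reading of an
"FDR $\le$ 0.0001%" rule) and $\max(fc, 1/fc) \ge fc_{thr}$, with fold
change computed as the linear-scale mean ratio tumor/normal. The
two-sided form is required because down-regulated features are expressed
as ratios below 1. Defaults are 2.5 for miRNA runs and 1.9 for gene
runs. Features with fewer than two observations in a group, a
non-positive normal mean, or $fc = 1$ are never selected. Missing values
are ignored per feature and group.

## Consensus pairing and networks

A pair (miRNA, gene) enters the candidate set when the directions are
opposite and at least `min_support = 2` *distinct* databases list the
gene as a target; record multiplicity within one database never counts.
The number of databases is not hard-coded: support is the count of
distinct source names. Identifier matching is exact and case-sensitive —
reconciling mature-name variants (miR-125b vs miR-125b-5p) or gene
aliases is deliberately left to the caller, because alias maps are
database-version-specific.

Each miRNA's network is the one-shell expansion of its L0 target set:
L1 contains every gene sharing an interaction with an L0 gene, and the
edge set is the induced subgraph on L0 ∪ L1 (L1–L1 edges are retained;
node counts, the quantity summarized downstream, are unaffected by that
choice). L1 membership is *not* restricted to differentially expressed
genes: the interaction map contributes genes that the expression filter
would never pass, which matches how published network members (e.g.
AKT1, BCL2) are absent from the differential tables. Isolated targets
are allowed, so a network can equal its L0 layer.

## GO enrichment

For a network with $n$ annotated genes out of an $N$-gene universe (the
union of all annotated genes, configurable), a term annotating $K$
universe genes and $k$ network genes scores

$$ p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n), $$

the inclusive upper tail (so $k = 0$ gives $p = 1$). Three filters
mirror the study design:

* **Network size**: networks with five or fewer genes are not tested
  (`min_pin_size = 6`). The source text states the bound once as "≤ 5
  genes" and once as "less than 5 proteins"; the stricter reading is the
  default and the parameter is configurable.
* **Term level**: only terms whose shortest `is_a` path to a namespace
  root has at least `min_level = 5` edges are tested, excluding overly
  generic terms. Root level is 0; `part_of` and other relations are
  ignored. The companion wording "larger than 5" versus "less than 5
  excluded" differs by one level; the inclusive `level >= 5` reading is
  the default.
* **FDR**: p-values are adjusted per network (the family is the set of
  terms tested for that network) with Benjamini-Yekutieli, which is
  valid under the arbitrary dependence created by overlapping GO terms;
  terms with adjusted p below `alpha = 1e-4` are reported.

Annotations are taken as given and are not up-propagated to ancestor
terms; whether the original analysis propagated them is unknowable from
the published tables, and propagation would change $K$ for every
ancestor. A term is flagged cancer-related when its lowercased name
contains any of the keywords *cell proliferation, cell death, apoptosis,
signaling, microtubule, actin*.

The printed enrichment tables of the original study are packaged as
fixtures (`load_fixture("S6")` and friends). Their adjusted p-values
were produced against a GO release and universe that are not recoverable,
so they serve as structural fixtures — row counts, member-gene lists and
the keyword classification are testable; the p-values themselves are not
recomputation targets.

## ROC marker evaluation

The AUC is the Mann-Whitney rank statistic (ties credited 0.5), its
standard error the Hanley-McNeil closed form with
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$, and the p-value the upper normal
tail of $z = (A - 0.5)/se$. Scores are used as-is with tumor as the
positive class — no automatic reorientation, because the study's own
result table contains AUCs on both sides of 0.5 for down-regulated
miRNAs. An explicit `flip` argument and a null-variance mode
(`se_mode = "null"`, evaluating the standard error at $A = 0.5$) are
provided.

One calibration caveat is worth knowing: the $Q_1/Q_2$ closed form rests
on an exponential score model. On Gaussian scores with a strongly
unbalanced design it is mildly conservative when the smaller group is
positive and mildly anticonservative when the larger group is positive;
the test suite asserts exactly this bracketing at the study's 15-vs-101
group sizes rather than pretending the nominal 95% level is exact.

## The synthetic study

`simulate_study()` generates every pipeline input with planted ground
truth, and its defaults *are* the conditions under which the package's
statistical guarantees are stated:

| parameter | default | rationale |
|---|---|---|
| normal / tumor samples | 11 / 20 | 11 normals as in the source profiles; tumor arm scaled down from 110+ |
| miRNAs / genes | 60 / 400 | keeps full runs in seconds while leaving >90% of features null |
| planted fraction | 0.1 | split evenly up/down per matrix |
| log2 effect | 3 | fold change 8, clearly above the 2.5 / 1.9 thresholds |
| noise sd (log2) | 0.5 | array-like lognormal noise |
| planted pairs | 3 down-miRNAs × 5 up-genes + 1 up-miRNA × 5 down-genes | covers both pairing orientations |
| planted support | 2 of 3 databases | exactly at the consensus threshold |
| decoy targets | 3× planted count per source | each decoy in exactly 1 source |
| PPI | 3 dedicated partners per target + ER(p = 0.02) background | first planted network has exactly 20 genes |
| ontology | depth 6, branching 2, planted term at level 5 | 96 testable terms at level ≥ 5 |
| planted term | 30 genes, 15 shared with the focal network | hypergeometric signal far beyond `alpha` |

Noise is Gaussian in log2 space (lognormal on the linear scale), the
simplest model consistent with normalized array data. The generator does
**not** emulate negative-binomial sequencing counts, batch effects, or
informative missingness — passing tests demonstrate correctness of the
pipeline's logic and calibration of its statistics under a clean
two-group lognormal design, not robustness to those real-data
complications. Every generator consumes one documented RNG stream per
call and is byte-reproducible given its seed; `simulate_study()` derives
per-generator sub-seeds from the master seed.

## Problem sizes used in the checks

The packaged checks run differential-expression recovery on 200-feature,
10-vs-10 matrices over 20 seeds (planted recovery ≥ 95% with zero false
positives at the default thresholds); enrichment null calibration over
200 random 20-gene networks against 96 uniformly annotated terms;
interval coverage over 500 ROC replicates; and the full pipeline over 10
simulated studies at the defaults above (planted pairs recovered exactly,
planted term ranked first). These sizes were chosen so the whole suite
exercises every guarantee in well under a minute per module.

## Known limitations

* Gene and miRNA identity is the literal string; no alias resolution.
* Annotations are not propagated along `is_a`; enrichment is sensitive
  to the annotation granularity supplied.
* The permutation FDR is an estimate: with few possible permutations
  (small groups) its resolution is limited to multiples of
  $1/\#\text{perms}$.
* The Hanley-McNeil p-value is a large-sample normal approximation and
  degenerates at $A \in \{0, 1\}$ (reported as $p = 0$ with a flag).
* The original study's GOBO survival analysis is an external web
  service and is out of scope.
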