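---
title: "Methods: from risk genes to validated drug candidates"
author: "pepScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from risk genes to validated drug candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepScreen)
```

# The screening model

pepScreen implements a pathway-level drug repurposing screen for a
disease with an annotated risk-gene list (the motivating application is
glioblastoma, with Temozolomide as the reference treatment and a panel of
glioma cell lines for validation). The screen has five stages:

1. **Pathway annotation.** Each risk gene is mapped to the flat gene
   sets (GO/KEGG-style biological processes) that contain it. Genes that
   fall outside the collection are skipped — a GWAS-derived list
   typically only partially maps into a pathway corpus.
2. **Pathway expression profiles (PEPs).** A perturbagen corpus supplies,
   per treatment instance, a total ranking of the gene universe by
   differential expression (rank 1 = most up-regulated). For every
   pathway the Kolmogorov–Smirnov running-sum statistic of its members'
   positions gives an enrichment score in $[-1, 1]$; ordering pathways by
   score yields the instance's pathway ranking.
3. **Per-gene drug lists.** For one risk gene, its pathway set is scored
   against every drug's pathway ranking with a *second-level* KS
   statistic (universe = all pathways). Drugs are sorted by empirical
   permutation p-value; those with $p < \alpha_\text{list}$ (default
   $10^{-2}$) form the gene's candidate list.
4. **Co-occurrence merge.** Drugs are counted across the per-gene lists;
   drugs in at least `cutoff` lists are kept, then restricted to
   FDA-approved, CNS-active compounds. The kept set is mapped back to
   pathways by drug-set enrichment (E-scores).
5. **Viability validation.** A pooled-barcode screen provides per-cell-line
   sensitivities; candidates are ranked by mean sensitivity with 95%
   t-intervals, tested against the reference by Mann–Whitney U, screened
   for discordant replicate datasets, and probed for mutation
   associations and sensitive-vs-non-sensitive differential expression.

# The running-sum statistic

For a set occupying sorted positions $p_1 < \dots < p_t$ in a ranking of
$n$ items,

$$a = \max_j\left(\frac{j}{t} - \frac{p_j}{n}\right), \qquad
  b = \max_j\left(\frac{p_j}{n} - \frac{j-1}{t}\right),$$

and the score is $a$ if $a > b$, else $-b$ (the unweighted two-sided
statistic of the Connectivity-Map family). Positive scores mean
concentration at the top (up-regulation). Numerical choices:

* The maxima are computed as integer numerators over the common
  denominator $tn$, so the $a$-vs-$b$ comparison is exact; ties go to the
  negative branch deterministically rather than by float rounding.
* The score is bounded by $|es| \le 1 - 1/n + 1/t$; a set equal to the
  whole universe is forced to $-1/n$.
* Reversing a ranking maps $a \to b - 1/n$ and $b \to a + 1/n$: the sign
  flips whenever the excursion gap exceeds $2/n$, while near-tie scores
  stay on the negative branch in both orientations. The property tests
  assert this exact form.

The same primitive drives all three enrichment levels: genes in pathways,
pathways in a pathway ranking (per-gene drug lists), and drugs in a
drug ranking (drug-set E-scores, positive = pathway up-regulated by the
candidate set).

# Empirical p-values

All p-values at the enrichment levels are empirical: the observed $|es|$
is compared against scores of random same-size sets, with the add-one
correction $p = (1 + \#\{|es_\text{rand}| \ge |es|\}) / (n_\text{perm} + 1)$,
which guarantees $p \in (0, 1]$ and validity at finite permutation
counts. Two-sided tests are used throughout the enrichment stages because
a perturbation in either direction is of interest; sidedness of the
viability tests is exposed as a flag (the screen reads "treatment more
sensitive than reference", hence one-sided `greater` by default there;
mutation association is two-sided).

For a *fixed* ranking, a random same-size set occupies a uniformly random
subset of positions, so the permutation null depends only on the set size
and the universe size. The implementation therefore draws one seeded null
table per size (sub-seeded by size, so results do not depend on which
sizes are requested together) and shares it across pathways and
instances. This makes runs bit-identical for identical seeds and inputs
and keeps the permutation cost independent of the corpus width. The
default is `nPerm = 999`; with $\alpha_\text{list} = 10^{-2}$ this leaves
a granularity margin (minimum attainable $p = 10^{-3}$). A permutation
count of 99 or lower makes nothing pass the default list filter — the
count must satisfy $1/(n_\text{perm}+1) < \alpha_\text{list}$.

# Replicate aggregation

Perturbagen corpora carry several instances per drug. Drug-level pathway
ranks are the ranking of the mean per-replicate pathway rank (a
Borda-style merge: scale-free across replicates), with ties broken by
pathway id; drug-level scores are the mean score, and aggregated
p-values are undefined by construction (set to `NA`). Aggregation before
the per-gene drug ranking was chosen over aggregating the per-gene lists
themselves; the alternative order is not exposed.

# Candidate selection

* The list filter is strict ($p < \alpha$), matching the screen's
  inclusion rule.
* The merge cut-off keeps drugs with count $\ge$ `cutoff`. The default 4
  follows the motivating corpus, where candidate drugs co-existed in 4–6
  of nine lists and the median of that range was chosen; the histogram
  of counts is reported alongside so the rule stays inspectable.
* Kept drugs are ordered by descending count, then minimum p across
  lists, then lexical id — a deterministic total order, since the
  original protocol's ordering is not reproducible.
* Drugs below the cut-off remain in `counts` for reporting; the FDA/CNS
  filter treats missing annotation as "not approved".

# The synthetic benchmark

`genCorpus()` emulates the profile corpus: 1000 genes, 150 pathways of
10–50 members drawn without replacement, 100 drugs with 3 instances
each, 9 risk genes each explicitly placed into 2–6 pathways, and 10
active drugs. An active drug perturbs the full pathway membership of 1–3
risk genes (uniformly chosen): member genes receive a score shift
$\text{direction} \times \delta$ (default $\delta = 2$, a strong but not
saturating perturbation on the standard-normal score scale) before
ranking, so rank statistics see realistic competition. A risk gene's
pathway set in the planted truth is its *full* membership — explicit
assignments plus incidental membership from the random pathway draw —
because that is exactly what the annotation lookup returns at screen
time; defining the truth on the assigned subset only would make the
benchmark query a mixture of perturbed and unperturbed pathways.

`genViability()` emulates the validation screen: sensitivities
$s_{dc} = \mu_d + \gamma_c + m_{dc} + \varepsilon_{dc}$ over 140
treatment series (reference included) and 42 cell lines, with cell-line
effects $\gamma_c \sim N(0, 0.25)$, noise $\sigma = 0.5$, planted potent
drugs at $\mu = 1$, per-gene mutation calls at rate 0.3 with one planted
(drug, gene) sensitivity shift per mutation gene, and an expression
matrix with 20 genes shifted by $3\sigma$ in the sensitive half of the
lines for one focal drug. Treatments default to FDA-approved/CNS-active
annotations, emulating a screen restricted to an approved neurology
panel.

**Benchmark cut-off.** The end-to-end recovery benchmark runs the full
pipeline with `cutoff = 1`. Planted drugs perturbing a single risk
gene's pathways are genuine positives that any count cut-off above 1
discards by construction (a drug hitting 1–3 of nine gene lists cannot
systematically reach 4), so the benchmark keeps every list member and
lets the per-list significance filter carry the specificity burden. The
cut-off's own semantics are validated separately (brute-force tally,
monotonicity, and the published co-occurrence histogram when the
supplementary lists are supplied). The false-positive load admitted by
`cutoff = 1` is reported by the acceptance script rather than hidden.

What the generators do *not* emulate: transcriptome covariance between
genes, dose structure, batch effects, or annotation errors. Passing the
planted-truth benchmarks therefore demonstrates that the statistical
machinery is correct and calibrated, not that the screen's biological
hit rate on a real corpus matches the synthetic one.

# Viability statistics

* Sensitivity is stored so that higher = more killing; viability
  log-fold-changes from pooled screens are negated at ingest, and
  `sensitivityFromCounts()` derives $-\log_2$ ratios from barcode
  abundances with a pseudocount guard.
* Mean-sensitivity confidence intervals are two-sided 95% t-intervals.
* Mann–Whitney tests are exact (null enumeration) when both samples have
  at most 8 untied values, otherwise normal approximation with tie and
  continuity correction; the exact path is verified against exhaustive
  labeling enumeration.
* Replicate concordance: a treatment screened in several datasets is
  excluded when any dataset pair sharing at least 3 lines has Pearson
  $r < 0.3$; pairs with fewer shared lines are flagged for manual review
  instead, because a correlation on two points is meaningless. The 0.3
  default is a stand-in for a "disparate responses" judgement that the
  motivating protocol does not quantify.
* The direct screening protocol treats replicate datasets as separate
  treatments, counts series with a higher mean than the reference and,
  among those, series significant at $\alpha_\text{screen} = 10^{-3}$.
* Differential expression uses per-gene Welch tests with a raw
  $p < 10^{-3}$ threshold; genes constant in both groups get $p = 1$.
  Heatmap columns follow descending sensitivity; rows follow hierarchical
  clustering with correlation distance and average linkage. The
  sensitive/non-sensitive split is a median split by default, exposed as
  a quantile parameter because the motivating protocol leaves it
  undefined.
* No multiple-testing correction is applied anywhere, matching the
  protocol's raw thresholds; the per-gene and per-pathway tables carry
  raw p-values so a user can apply `p.adjust` downstream.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data:
oracle checks use up to 1000 random instances at $n \le 50$; calibration
uses the default corpus (45 000 pathway-instance p-values at 199
permutations) and a 200-treatment null screen; the end-to-end benchmark
runs 20 seeded corpora at the default sizes. These sizes were chosen so
the whole suite completes in a few minutes on a single core while
keeping binomial tolerances tight. Every random draw flows from an
explicit integer seed; identical seeds give bit-identical outputs,
including the stage artifacts and manifest checksums written by
`runScreen()`.

# Known limitations

* The per-gene drug ranking's empirical null has coarse granularity for
  very small query sets ($t = 2$ in a universe of 150 pathways); a true
  signal can sit just above the $10^{-2}$ threshold when many pathways
  are co-perturbed. Larger pathway annotations mitigate this.
* E-score p-values permute the drug set, not the pathway labels; with
  few profiled drugs the two-sided minimum attainable p can exceed
  nominal thresholds (the singleton case is documented in the tests).
* The screen does not model SNP-to-gene mapping, target docking, or
  literature curation; those stages of the motivating protocol are out
  of scope.
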