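---
title: "Concordance and outcome analysis of section 7 consultation records"
author: "concord7"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance and outcome analysis of section 7 consultation records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concord7)
```

## The problem

Under section 7 of the U.S. Endangered Species Act, a federal "action
agency" proposing an action that may affect listed species consults an
expert wildlife agency (for marine and anadromous species, NMFS).  The
action agency *proposes* a per-species effect determination — `no effect`,
`NLAA` ("may affect, not likely to adversely affect"), `LAA` ("likely to
adversely affect"), or, rarely, a direct jeopardy-range proposal — and the
expert agency issues the *final* determination: `no effect`, `NLAA`, or,
after an LAA finding triggers formal consultation, `no jeopardy` or
`jeopardy`.  A consultation can carry many such determination pairs, one
per species or per listed population unit (DPS/ESU).

`concord7` measures how well the two sets of determinations agree, where
they diverge, and what the outcomes of consultation look like: frequency
and trend analyses, the rarity of jeopardy findings, which
species-by-work-type combinations are jeopardized out of proportion, and
which species pairs tend to be jeopardized by the same action.  Because the
underlying tracking database is not redistributable, the package ships a
synthetic record generator with the same statistical structure, so every
stage of the pipeline is testable end to end.

## Ordinal discrepancy scoring

Each (expert, agency) determination pair receives an ordinal score in
$\{-3,\dots,+3\}$ (`score_matrix()`).  Agreement cells score 0; this
includes an agency LAA proposal resolved by the expert into *either*
jeopardy or no jeopardy, since LAA is exactly the proposal that triggers
that resolution.  Positive scores mean the agency rated effects more
severe than the expert's final finding (overestimation); negative scores
mean underestimation.  Moving the agency proposal one step up the severity
ladder (`no effect` < `NLAA` < `LAA`) at fixed expert category never
decreases the score.

The rare direct proposals follow the same logic: `proposed no jeopardy`
agrees (0) with a `no jeopardy` finding but scores $-1$ against a
`jeopardy` finding; `proposed jeopardy` agrees with `jeopardy`.

## Weighted kappa

Overall chance-corrected agreement is summarised by a disagreement-weighted
Cohen's kappa.  With observed counts $O_{ij}$, margins $r_i, c_j$, total
$N$ and disagreement weights $w_{ij}$,

$$K_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij} / N}
                 {\sum_{ij} w_{ij} r_i c_j / N^2}.$$

$K_w = 1$ at perfect agreement (all mass on zero-weight cells) and $0$
when the table equals the outer product of its margins.  Weights are drawn
from $\{0, 0.25, 0.5, 0.75, 1\}$ with agreement cells at 0.  That weight
*set* leaves the assignment of non-zero weights open; the package default
is $w_{ij} = |s_{ij}|/4$ — 0.25 per ordinal step of the discrepancy score
— because it is monotone in the discrepancy, symmetric in $|s|$, and uses
the full stated set.  Any other assignment can be passed to
`weighted_kappa()`.  On the published reference cross-tabulation
(`reference_concordance_table()`, $N = 91{,}435$) the default mapping gives

```{r}
weighted_kappa(reference_concordance_table())
```

This value is pinned by a regression test.  The headline statistic
published alongside that table ($K_w = 0.38$) is **not** reproduced by any
weight assignment documented with it; rather than guess, the package
treats the weight mapping as a configuration choice and reports its own
deterministic value.

Similarly, the published headline shares (79% agreement; 71% of
disagreements being underestimates) are not recoverable from the printed
table under any orientation we examined: the zero-score cells sum to 84.0%
of the printed total, and negative scores are 23.8% of printed
disagreements.  `replicate_reference_tables("concordance")` therefore
reports the shares in both orientations and leaves the discrepancy
visible instead of forcing either number.

## Per-agency deviation

`ks_by_agency()` compares each agency's discrepancy-score distribution
against the pooled distribution over all agencies with a two-tailed
two-sample Kolmogorov–Smirnov test, skipping agencies with fewer than
`min_n = 20` scores.  The focal agency is *included* in the pooled
reference by default (the literal "all agencies" pooling); a
`leave_one_out` flag removes it.  Scores are discrete, so ties are
pervasive; $D$ is the exact sup distance between the step CDFs and the
p-value is asymptotic.  The unit and acceptance suites check $D$ against a
brute-force sup-distance oracle across the score support.

## Outcome frequencies and trends

Frequency analyses count consultations, with all DPS/ESUs of a species
collapsed to the species (`aggregate_dps()`): three steelhead DPS rows in
one consultation are one steelhead consultation, while determination-level
analyses keep all three rows.  Unevenness across species, agencies, work
types and regions is tested with `chisq_gof()` ($X^2 = \sum (O-E)^2/E$,
$df = k - 1$; the df always derives from the number of levels actually
compared).  Yearly counts are fitted with `fit_yearly_counts()` under a
Poisson log-link GLM (count processes) or a Gaussian identity-link GLM;
both families are available because count trends are sometimes reported as
arithmetic per-year deltas, and the family used is recorded in the output.
The yearly jeopardy *rate* (jeopardy consultations / formal consultations)
is fitted with the Gaussian identity-link model
(`fit_jeopardy_trend()`).

Percentages replicated against printed one-decimal tables use half-up
rounding (`round_half_up()`), since banker's rounding disagrees with
printed values at exact .05 boundaries.

## Jeopardy enrichment: fixed-margin permutation

`build_jeopardy_matrix()` counts jeopardy determinations per
(species, work type) cell.  `permutation_enrichment()` compares each
observed cell against `n_perm` (default 1000) randomisations that hold all
row and column totals fixed, drawn from the conditional (multivariate
hypergeometric) distribution of tables given margins via Patefield's
algorithm (`stats::r2dtable`, wrapped by `sample_fixed_margins()` and
verified in tests against exhaustive enumeration).  Per cell it reports
the effect (observed $-$ mean simulated), the sd of simulated counts, and
both tail probabilities.

Two p-value conventions are provided:

* `"greater"` (default): $p_{gt} = \#\{sim > obs\}/n_{perm}$, the plain
  proportion rule.  On sparse matrices this rule is anti-conservative: a
  singleton cell with tiny margins can receive $p \approx 0$ simply
  because the randomisations rarely reach its observed count.
* `"smoothed"`: $p_{gt} = (\#\{sim \ge obs\} + 1)/(n_{perm} + 1)$, which
  never returns 0 and is a valid (conservative) p-value.  This is the
  convention used for the package's null-calibration study, precisely
  because the plain rule cannot be calibrated on sparse matrices.

Zero-margin rows/columns are dropped before permutation (and reported);
single-row or single-column matrices are forced by their margins, so every
cell gets effect 0 and sd 0.  No multiple-testing correction is part of
the core procedure; a clearly-labelled supplementary Benjamini–Hochberg
column is emitted.  Results are bit-reproducible given
(matrix, `n_perm`, `seed`).

## Co-jeopardization: hypergeometric null

`build_binary_matrix()` builds the binary species-by-consultation matrix
(1 = species jeopardized in that consultation; species without any
jeopardy determination excluded; DPS/ESUs collapsed).  For a species pair
with margins $N_1, N_2$ over $N$ consultations, the co-jeopardization
count under the fixed-margin null is hypergeometric,
$P(j) = \binom{N_1}{j}\binom{N-N_1}{N_2-j}/\binom{N}{N_2}$, giving exact
tail probabilities, the expected count $N_1 N_2 / N$ and the effect
(observed $-$ expected).  The analytic null is used instead of Monte-Carlo
permutation because it is exactly testable (the suite checks it against
complete enumeration of placements for $N \le 12$ and against a
row-shuffle Monte-Carlo oracle); it is the same null the permutation
converges to.

The "probability that a pair is jeopardized by the same action" has no
single established denominator, so `cooccur_test()` reports
observed$/N$, observed$/N_1$, observed$/N_2$ and observed$/|$union$|$;
`all_pairs()` tracks the maximum observed$/N$ pair.  The column universe
defaults to consultations with at least one jeopardy determination; a
`universe = "formal"` flag widens it to all formal consultations.

## The synthetic generator

`synthetic_config()` collects every generative parameter.  The latent
process is:

1. Consultation-level draws: year (uniform in `year_range`), agency, work
   type and region (weighted pools), formal flag (`p_formal`), a
   truncated-geometric number of species (mean `species_mean`, maximum
   `species_max`), and extra DPS/ESU rows for multi-unit species
   (`p_extra_dps`).
2. Latent expert category per determination from
   `base_determination_probs`; informal consultations renormalise over
   `no effect`/`NLAA` (jeopardy-range findings only arise from formal
   consultation).  Enrichment multipliers and co-jeopardy shocks scale the
   conditional jeopardy probability before renormalisation.
3. The agency proposal is generated *conditionally* on the expert
   category through an ordinal shift kernel: with probability `noise` the
   proposal moves one step from the agreeing category on the
   `no effect` < `NLAA` < `LAA` ladder, upward with probability
   $(1+b)/2$ where $b \in [-1, 1]$ is the agency's bias.  A step off the
   end of the ladder leaves the proposal in agreement, so with
   `noise = 0` and all biases 0 every pair scores 0 and $K_w = 1$
   downstream.  Direct jeopardy-range proposals are emitted with
   probability `p_proposed_jeopardy` (default $3\times 10^{-4}$),
   mirroring their extreme rarity.
4. One RNG stream per consultation, seeded from (config seed, record
   index), so insertion order can never change output and identical
   configurations are byte-identical.

Defaults emulate the observed regime: ~19.9% formal consultations;
NLAA-dominated determinations with the base jeopardy component calibrated
to 0.004 so that ~1.5% of formal consultations end in jeopardy under the
default enrichment and shock settings; an agency pool with the most
frequent agency ~6x the next and a mix of over- and under-estimating
biases; a waterway-dominated work-type pool; salmonids split into multiple
DPS/ESUs.  The species-per-consultation distribution is not documented for
the real database; the truncated geometric with mean 2 is a configurable
placeholder.

**Co-jeopardy shocks are joint exposures.**  A shock that fired
independently of species presence would raise single-species jeopardy
margins exactly as much as joint counts, and the fixed-margin null absorbs
that — no within-pair association results (we verified this directly).
The shock therefore applies only when at least two group members are
present in the consultation, which is also the mechanism's ecological
meaning: one wide-ranging action affecting several co-occurring species.
Note also that in a symmetric group of three species whose joint events
are pairwise, the overlap for any one pair approximately equals its
margin-expected value, so demonstration configs use a two-species group.

## Validation study sizes

The simulation-based checks in the test suite use the following designs,
chosen once by power reasoning on a focused pool (6 species, 5 uniform
work types, unbiased agencies, 30% formal, 4% jeopardy within the formal
draw):

* planted enrichment: one multiplier-10 cell, $n = 2000$ consultations,
  1000 permutations, 50 generator seeds — detected at $p_{gt} < 0.05$ in
  at least 80% of seeds;
* null calibration: no enrichment, no shocks, $n = 600$, 400
  permutations, 200 seeds, smoothed convention — pooled cell-level
  false-positive rate at $\alpha = 0.05$ stays at or below 7%;
* bias recovery: bias $-0.6$, noise 0.3, $n = 5000$, 20 seeds — the
  majority of disagreements score negative in every seed;
* co-jeopardy: two-species group, shock probability 0.2, $n = 2000$ —
  the within-group pair is significant in at least 80% of seeds.

## Cleaning rules and degenerate inputs

* Reversed date pairs are swapped and flagged (`date_corrected`), never
  dropped — this preserves sample size and stays auditable.  Unparseable
  dates become `NA` and are excluded only by the window filter.
* The analysis window is a closed interval on the consultation start
  date, default 2000-01-01 to 2017-06-30, and fully configurable (the
  anchoring date and exact end of the real study window are not
  documented; the start date is the only date guaranteed present).
* A consultation-type string with no complexity qualifier maps to
  `standard` complexity (the dominant case) and is auditable via the raw
  string; unrecognised strings map to `missing`/`missing`.
* Determination vocabulary, critical-habitat vocabulary, and name aliases
  are shipped as two-column CSVs, not code, so raw-export vocabularies can
  be accommodated without a release.  An `LAA` string in the expert-final
  column is non-final and maps to `missing`.
* Parsing never drops rows: every anomaly is logged in `rejects(x)` with a
  row number and reason, and row counts are conserved.
* Empty tables, all-zero margins, absent disagreements and missing formal
  denominators raise typed errors or flagged `NA`s rather than silent
  zeros.

## What the synthetic data cannot show

The generator reproduces the *statistical* structure the analyses assume —
ordinal proposal bias, skewed pools, rare correlated jeopardy — but not
free-text vocabulary drift, entry errors beyond reversed dates, the manual
review steps applied to unclear real records, spatial structure, or any
species biology.  A pipeline that passes every test here is validated as
an *analysis* of records with this schema; conclusions about the real
consultation program require the real export, which can be supplied to
`run_pipeline()` as a CSV mapped onto the same columns.
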