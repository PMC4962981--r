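---
title: "emapkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emapkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emapkit)
options(emapkit.verbose = "quiet")
```

emapkit analyzes quantitative genetic interaction screens of the E-MAP/SGA
family: all-vs-all crosses of a gene set, each double mutant grown in
quadruplicate, colony sizes quantified, and every pair scored for deviation
from the neutral expectation. This vignette is the package's own account of
the models behind each stage, the tunable parameters, and the design
decisions taken where several defensible choices existed.

## The neutral model and the S score

Double-mutant fitness is modeled as multiplicative: a cross of query `q` and
array gene `a` grown on plate `p` has expected colony size

    E[size] = plate_scale_p * f_q * f_a * (1 + epsilon_qa)

where `f` are single-mutant fitnesses and `epsilon_qa` is the interaction
deviation — negative for synthetic sick/lethal pairs, positive for
alleviating/suppressing ones. The product form is the standard neutral
expectation of this screen family; everything the pipeline does is an attempt
to estimate `epsilon` robustly from replicate colony sizes.

Scoring proceeds in four steps (`score_screen()` runs them all):

1. **Normalization** (`normalize_grid()`). Every plate is scaled so its
   median colony size equals the global median, and every query row is then
   scaled the same way. The query step matters: single-mutant fitness
   differences between query strains otherwise masquerade as interactions of
   that query with every array gene. An optional log-space median polish
   (`polish = TRUE`, via `stats::medpolish`) removes residual row/column
   trends such as plate-geometry gradients; it is off by default because the
   plate and query medians already absorb the dominant effects.
2. **Control statistics** (`fit_control_stats()`). Per array gene, the
   expected size is the *median* across queries of the per-cross mean sizes,
   and the spread is the scaled MAD (`1.4826 * MAD`, consistent with a
   standard deviation). Medians and MADs are used throughout because true
   interactions contaminate means: a handful of strongly interacting queries
   must not drag the control expectation. Spreads are floored at the
   screen-wide median spread.
3. **The S score** (`compute_s_score()`), a modified t-statistic:

       S = (mean(obs) - expected) / sqrt(spread^2 / n_ctrl + v_mod / n_obs)

   with `n_ctrl` the effective control replicate count (default: the
   replicate count, 4) and `v_mod` the *moderated* replicate variance,

       v_mod = ((n_obs - 1) * var(obs) + d0 * v_typ) / (n_obs - 1 + d0).

   `v_typ` is the screen-wide median replicate variance and `d0 = 6`
   pseudo-degrees of freedom. A quadruplicate's raw variance has 3 degrees
   of freedom; dividing by so noisy an estimate gives the score heavy
   t-like tails, which an empirical null evaluated against the normal then
   mis-calibrates (we measured the nominal 0.005 tail at ~0.007 with a hard
   median floor instead of moderation). Shrinking each cross's variance
   toward the screen-typical value — the same idea as the moderated t of
   microarray analysis — brings the null tails close to normal while still
   letting genuinely erratic crosses widen their own denominators. Both
   floors carry a tiny absolute backstop (1e-6 of the median size) so the
   noise-free limit stays finite.
4. **Symmetrization and significance** (`symmetrize()`, `s_pvalues()`).
   Each unordered pair is scored in both reciprocal directions
   (`[query A x array B]` and `[query B x array A]`); its S score is the
   mean of the available directions, with `ONE_DIRECTION_ONLY` flagged when
   one is missing. P values come from an empirical null: the bulk of pairs
   is assumed non-interacting, so the S distribution is centered at its
   median and scaled by the central 80% interquantile range calibrated to
   the normal (`(q90 - q10) / (2 * qnorm(0.9))`), then evaluated two-sided
   against the standard normal. The 80% range rather than the MAD: it is
   still immune to tail contamination by up to ~10% true interactions, and
   for the mildly leptokurtic score distribution it estimates the bulk
   scale with less downward bias (the 95% range would already be inflated
   by a realistic 2% planted-interaction load, which is why it was
   rejected). A permutation null (replicate shuffling within array genes,
   default 2000 permutations, seeded) is available for screens too small
   for an empirical null; fewer than 50 finite scores refuse the empirical
   route outright.

## Thresholds

`emap_thresholds()` carries every cutoff. Defaults: S significance at
unadjusted `P <= 0.005` and correlation significance at `P <= 0.05`
(boundaries inclusive); Bonferroni family alpha 0.05 (`bonferroni_cut()`
divides by the number of tested pairs); high-correlation listing at
`r > 0.5` strict; curve windows of 10 pairs; linkage masking strictly below
100 kb; region calls requiring at least 5 consecutive genes below `S = -3`.
The masking and region defaults are conventions for screens of this
family — regions of concerted artifact interactions observed in practice
span roughly 4–12 genes with edge scores near −3 and centers far below —
and all of them are settable from a flat `key = value` configuration file
(`read_config()`).

## Quality control

`reciprocal_concordance()` is the Pearson correlation of the unaveraged
directional scores over pairs scored in both directions; restricting it to
significant pairs isolates the signal-bearing subset, which in a healthy
screen is markedly more concordant than the noise-dominated bulk.

`detect_noisy_strains()` flags strains whose median reciprocal discordance
`|s_qa - s_aq|` over partners exceeds 3 times the screen-wide median, with
one re-iteration after removal. The discordance is computed on
*variance-stabilized* directional scores (the same statistic with the
screen-typical replicate variance in place of the cross's own): the
modified t divides by an estimate of its own noise, so a strain with
10-fold inflated replicate noise still produces near-unit-scale scores and
its discordance saturates around 1.6 times the screen median — below any
reasonable multiplier. The stabilized scores scale linearly with strain
noise, putting such a strain at 6–9 times the screen median where the
3-fold rule separates cleanly. Flagged strains' pairs receive the
`NOISY_STRAIN` flag and drop out of all downstream analyses; S values of
unrelated pairs are untouched, and removal is a single deterministic
iteration so the result does not depend on processing order.

## Profile correlations and network analytics

A gene's interaction profile is its vector of S scores against all other
genes. `profile_correlations()` computes pairwise-complete Pearson
correlations over partners excluding the two genes themselves — a pair's
own (possibly huge) S value must not inflate its profile similarity — with
P values from the t transform on `n_used - 2` degrees of freedom.
`classify_pairs()` partitions pairs into the four joint-significance
categories (significant S only, significant correlation only, both,
neither). The curve analytics (`s_vs_correlation_curve()`,
`pos_neg_ratio_curve()`) sort qualifying pairs by correlation and summarize
windows of 10; windows are non-overlapping by default since "a window of n
values" is ambiguous between chunked and rolling — both are implemented
(`mode = "rolling"`), chunked is the default because its points are
statistically independent. Ratio windows with no negative interaction
report `NA`, never infinity.

`hierarchical_cluster()` is average-linkage agglomeration on distance
`1 - r` with missing correlations treated as `r = 0` (no evidence of
similarity); genes are pre-sorted lexicographically so ties break
deterministically on gene id. `hyper_interactors()` flags genes whose
significant-interaction count exceeds `mean + 2 SD` of per-gene counts
*and* covers at least 20% of their tested partners. The breadth floor is
deliberate: per-gene counts in a sparse screen are near-Poisson, so the
`mean + 2 SD` rule alone fires on chance in most screens, and a gene whose
interactions are concentrated in one chromosomal region (the suppressor
signature the region scan looks for) must not be silenced as a
hyper-interactor; true hyper-interactors interact throughout the profile.

## Two-condition comparison

`compare_conditions()` computes `delta = S_drug - S_control` per pair and
calls `AGGRAVATED` (`delta <= -2` and drug-significant) or `ALLEVIATED`
(`delta >= +2` and control-significant). The significance gate defaults to
the genome-wide Bonferroni threshold rather than the unadjusted 0.005:
the delta of a typical pair fluctuates on the same unit scale as S itself,
so over thousands of pairs an unadjusted gate admits enough chance calls to
swamp a realistic number of true condition-specific shifts. Pairs scored in
only one condition are reported in a separate `unpaired` attribute, never
silently dropped. `axis_artifact_scan()` flags pairs significant in exactly
one reciprocal direction — the signature of direction-specific,
condition-specific noise.

## Genome-order analytics

`mask_linked_pairs()` flags pairs on the same chromosome whose start
coordinates lie strictly within 100 kb: their double mutants are depleted
by meiotic linkage, not interaction. Coordinates are 0-based half-open (BED
convention) and a gene's representative position is its start; the strict
inequality and the start-to-start distance are fixed conventions so every
boundary case is decidable.

`detect_regions()` looks for the undeclared-suppressor signature: a strain
carrying an unselected suppressor mutation that rescues its growth defect
loses the suppressor exactly where the selected partner marker is linked to
the suppressor locus, faking a contiguous block of negative interactions
between that strain and one chromosomal region. The scan traverses each
chromosome in genome order over finite, unmasked scores of each candidate
distant gene and collects maximal runs below the S cutoff. Missing cells
are skipped without breaking a run by default — a failed cross should not
split a real region — with `missing_breaks_run = TRUE` as the strict
alternative. Runs touching the distant gene's own linkage neighborhood are
discarded (that is linkage, the very thing the mask exists for), and genes
flagged as hyper-interactors are never candidates, applied to the distant
gene only, not to region members. `region_null_rate()` permutes the
gene-to-locus assignment (default 200 permutations, seeded) and reports the
call-count distribution, so an observed call can be judged against
positional chance. The region cut (`S < -3`) and minimum run (5) are single
cuts; a two-tier edge/center rule was considered and rejected as
unidentifiable at screen scale — the calls report `min_S` and `median_S` so
the center depth is visible anyway.

## The synthetic screen generator

`generate_truth()` / `simulate_colonies()` emulate the statistical
structure the analysis assumes, with every planted parameter returned for
recovery testing. The default screen: 120 genes on 4 chromosomes (one gene
every 20 kb), quadruplicate crosses in two conditions, single-mutant
fitness uniform on (0.7, 1), 2% of pairs interacting (70% negative,
`epsilon` in (−0.8, −0.3); positives in (0.3, 0.6)), lognormal replicate
noise with coefficient of variation 0.15, per-plate scale factors lognormal
with sd 0.1, and one suppressor with rescue factor 2.5 whose locus sits
midway between two gene starts so that exactly 10 genes fall strictly
within the 100 kb window. Plates are unordered blocks of 30 x 30 crosses,
so reciprocal cells share a plate. Condition-specific shifts
(`n_drug_shifts`, off by default) plant aggravations on neutral pairs and
alleviations on planted negative pairs at `|delta_epsilon| = 0.45`, sized
so the induced `|delta S|` clears twice the differential calling threshold
with margin. These defaults are the package's reference conditions; the
effect-size distributions are conventions of this generator, chosen as
typical for screens of this kind, not measured values.

Suppressor loss is deterministic inside the linkage window and absent
outside it; no recombination-frequency gradient is modeled. Noise is purely
multiplicative-lognormal (positive, right-skewed, as colony sizes are) with
an optional linear within-plate column gradient as a normalization
stressor; there are no spatial row/column plate effects beyond that, no
batch structure across screen repetitions, no missing-data mechanism other
than what a test plants explicitly. Passing recovery tests on this
generator therefore demonstrates correctness of the estimators under the
model's own assumptions — multiplicative fitness, exchangeable replicates,
sparse interactions — not robustness to everything real plates do.

A useful exact property: when single-mutant fitness is uniform and noise is
zero, every robust estimate in the pipeline is tie-exact (medians of sets
with an identical majority), so non-planted pairs score exactly 0, planted
pairs score with the planted sign, and the two reciprocal directions agree
bit-for-bit. The test suite uses this limit as a machine-precision oracle.
With heterogeneous fitness the medians carry order-statistic displacement
of the order of one neighbor gap, so the noise-free limit is exact only up
to that displacement — a real property of median-based scoring, documented
rather than hidden.

## Problem sizes and determinism

The test suite and the acceptance script simulate screens of 60–142 genes:
large enough that the empirical null has thousands of pairs (a 142-gene
screen gives 10,011) and the planted region is recoverable, small enough
that a full simulate-and-score cycle takes a fraction of a second, so
recovery rates can be estimated over 100 seeds. Every stochastic step —
truth generation, colony noise, permutation nulls, positional
permutations — takes an explicit integer seed, and identical seeds
reproduce identical output to the bit.

## Known limitations

* The empirical null assumes most pairs are non-interacting; screens where
  a large fraction of pairs truly interact need the permutation null.
* The replicate-noise model is exchangeable lognormal; systematic spatial
  plate effects beyond a column gradient are out of scope, as is
  batch correction across independent screen repetitions.
* Region calls name a chromosomal interval, not the suppressor gene within
  it; identifying the suppressor is follow-up genetics, not statistics.
* The noisy-strain rule is reciprocal-discordance based and declared as
  such; other definitions (e.g. replicate-variance based) would flag
  different strains.
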