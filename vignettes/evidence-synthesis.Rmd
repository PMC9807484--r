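---
title: "Evidence synthesis for microRNA biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence synthesis for microRNA biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamirna)
```

## The problem

Case-control expression-profiling studies of circulating microRNAs report
wildly heterogeneous results: the same microRNA appears upregulated in one
serum cohort, unreported in a plasma cohort, and downregulated in whole
blood. Before a microRNA can be proposed as a diagnostic biomarker (here for
type 2 diabetes, though nothing in the machinery is disease-specific), the
per-study evidence has to be pooled statistically, screened for
selective-reporting artefacts, and cross-checked against what the microRNA
actually does in disease-relevant signalling pathways. `metamirna`
implements that whole chain as composable, tibble-first functions, and ships
a synthetic-data generator with planted ground truth so the chain can be
validated end to end without any external database.

The unit of analysis is the *substudy*: one study-by-microRNA comparison
contributing a 2x2 table of dysregulation events — how many case and control
samples exhibited dysregulated expression of that microRNA. We treat "one
dysregulation event" as "one sample classified as dysregulated by the
study's own criteria"; this is the most direct reading of event-count
meta-analysis over profiling studies and is an assumption, not a fact about
any particular source corpus. Several substudies may share one parent
publication (multi-cohort studies), which matters for the bias tests below.

## Random-effects meta-analysis

For a substudy with `a` events among `n_case` cases and `c` events among
`n_ctrl` controls, the effect size is the signed natural-log odds ratio

$$y = \ln\frac{a\,d}{b\,c}, \qquad v = \frac1a + \frac1b + \frac1c + \frac1d$$

with `b`, `d` the non-event counts. If any cell is zero, the
Haldane–Anscombe correction adds 0.5 to all four cells and flags the record.
Internally everything is signed; report writers output `|logOR|` plus a
direction column, which reconciles absolute-value presentation with a
sign-based up/down call.

Substudies of one microRNA are pooled under the random-effects model
$y_i \sim N(\mu, v_i + \tau^2)$. The between-substudy variance $\tau^2$ is
estimated twice:

* **REML** — bounded 1-D maximisation of the restricted log-likelihood over
  $[0, \max(10, 100\,S^2_y)]$, with the boundary at zero checked explicitly;
* **empirical Bayes / Paule–Mandel** — the root of
  $\sum_i w_i(\tau^2)\,(y_i - \hat\mu(\tau^2))^2 = k - 1$ found by bisection,
  truncated at zero. These two names refer to the same fixed point in
  standard implementations; we verify the root directly against its defining
  equation in the tests rather than assuming the equivalence.

Pooling uses inverse-variance weights $w_i = 1/(v_i + \hat\tau^2)$, Wald
standard errors, normal confidence intervals (z quantile 1.959964, no
Knapp–Hartung adjustment — matching the conventional default of the
mainstream meta-analysis toolchain) and two-sided normal p values. Raw p
values are Bonferroni-multiplied by `m`, the number of microRNAs
meta-analysed *in the analysis set at hand* — not a global constant — and a
microRNA is declared significant only when **both** estimators give adjusted
`p < alpha` *and* agree on the sign of the pooled effect. The sign-match
clause makes "identified by both methods" operational; disagreements are
rare (they require $\hat\mu$ near zero) and are surfaced rather than silently
passed.

MicroRNAs observed in fewer than two substudies cannot be meta-analysed and
are excluded with a log record. Substudies sharing a parent publication are
pooled as independent; this is a documented limitation, not an endorsement.

Subgroup analyses partition the corpus by tissue class, blood fraction
(within blood), or detection platform (PCR and sequencing strata only — the
other platforms are singletons in realistic corpora and are skipped with a
message), each stratum with its own Bonferroni `m`. Sensitivity analyses
re-run the overall analysis keeping substudies with combined sample size at
or above each threshold (inclusive; defaults 25 and 50). A microRNA is
*direction-consistent* when every analysis set in which it is significant
agrees on the direction; sets where it is not significant are vacuously
consistent.

## Publication bias

Three complementary instruments, all operating on one microRNA's effects:

* **Begg–Mazumdar rank correlation.** Kendall's $\tau$ between the
  variance-standardised deviates
  $y^*_i = (y_i - \hat\mu_{FE}) / \sqrt{v_i - 1/\sum_j v_j^{-1}}$ and the
  variances $v_i$. For $k \le 8$ without ties the two-sided p value is the
  exact permutation tail (all $k!$ orderings; $8! = 40320$ is comfortably
  enumerable); beyond that, the normal approximation with tie-corrected
  variance of Kendall's S. The exact convention is the small-k default
  because it is the one a fully concordant funnel at $k=4$ and $k=6$
  ($p = 2/k!$) reproduces.
* **Egger regression.** OLS of $y_i/se_i$ on $1/se_i$; the test statistic
  defaults to $z = \text{intercept}/SE$, with a Student-t variant on
  $k - 2$ degrees of freedom behind a flag. A zero-residual fit is flagged
  `perfect_fit` rather than reported with a spurious standard error.
* **Duval–Tweedie trim-and-fill.** The iterative $L_0$ estimator: with the
  funnel centred at the fixed-effect estimate of the currently trimmed set,
  $L_0 = (4T_n - k(k+1))/(2k-1)$ from the signed ranks of all deviations;
  $k_0 = \max(0, \text{round}(L_0))$, iterated to stabilisation (cap 50).
  The $k_0$ trimmed effects are mirrored about the trimmed centre (keeping
  their variances) and the observed-plus-filled set is re-pooled under the
  REML random-effects model. `side = "auto"` trims the side with the larger
  positive $L_0$, breaking ties by the sign of the Egger intercept. The
  $R_0$ estimator is out of scope.

Any microRNA with fewer than 3 substudies, or whose substudies all share one
parent publication, is `not_testable` — the tests assume independent
studies.

The *post-correction gate* asks whether the trim-and-fill corrected pooled
effect is itself significant (raw `p < alpha`). We deliberately do not
multiply this p value by the meta-analysis Bonferroni `m`: the correction is
a single follow-up test on an already-selected microRNA, and the
multiplicity correction in the pipeline attaches to the discovery stage.
The gate is hard only for microRNAs on which bias tests were actually run
(by default the top-reported subset per direction); a configuration flag can
widen testing to all.

## Interaction evidence and robust pairs

MicroRNA–target ledgers from experimental and prediction databases are
merged after name canonicalisation (so alias spellings collapse), then
filtered:

1. predicted records must fall in the top percentile cut
   (`top_pct = 1.4`, boundary inclusive — a "top x%" names a quantile cut
   that contains its boundary);
2. retracted PMIDs are removed from every record *before* support counting,
   so a pair with three supporting articles that loses one retraction can
   still qualify — the strictest-about-evidence reading that does not
   double-penalise;
3. a pair is **robust** when its surviving experimental PMIDs number at
   least two *and* the pair also has a prediction record — two types of
   database. The two supporting PMIDs may come from the same experimental
   database; requiring distinct databases would be a stronger, unstated
   assumption.

Stage counts are recorded at each clause, so the filter's accounting is
auditable and provably monotone (raising `min_pmids` or lowering `top_pct`
never enlarges the set).

## Pathway augmentation and impact analysis

Signed directed pathway graphs (edge-list TSV or GraphML) are augmented
with one node per robust microRNA that targets a pathway gene, connected by
repression edges ($\beta = -1$). Activation/inhibition relations map to
$\pm 1$; unknown relation labels default to $+1$ with a warning. Measured
perturbations $\Delta E$ (the signed pooled log odds ratios of dysregulated
microRNAs) propagate through the linear system

$$(I - B)\,PF = \Delta E, \qquad B_{ij} = \beta_{j \to i} / \text{outdeg}(j),$$

the classic source-out-degree normalisation of signalling-pathway impact
analysis. $Acc = PF - \Delta E$ accumulates downstream perturbation and
$t_A = \sum_n Acc(n)$ is the pathway statistic. Feedback loops of gain one
make $I - B$ singular; if the reciprocal condition number falls below
$10^{-12}$ all $\beta$ are damped by 0.9 and the solve is retried with a
flag (a second failure is an error naming the pathway).

Two probabilities are combined per pathway:

* $p_{acc}$: permutation null obtained by reassigning the observed
  $\Delta E$ values to uniformly resampled measured entities on the
  pathway; two-sided, median-centred, with a +1 pseudo-count, so
  $p_{acc} \in [1/(n_{perm}+1), 1]$. Because $t_A$ is linear in
  $\Delta E$, each draw needs only a dot product with the precomputed
  coefficient vector $\text{colSums}((I-B)^{-1}) - 1$, not a solve.
  Default `n_perm = 2000`, seed mandatory.
* $p_{ORA}$: hypergeometric upper tail for the number of differentially
  expressed entities on the pathway, over the measured universe.

The combination is the Fisher product $p_G = c - c\ln c$ with
$c = p_{ORA}\,p_{acc}$, adjusted across pathways by Benjamini–Hochberg
(Bonferroni selectable). The permutation count, null construction and
cross-pathway adjustment are all configuration-exposed because no single
convention is canonical.

The differentially expressed input set is the union of significant,
direction-consistent microRNAs across *all* analysis sets (overall,
subgroups, sensitivity), each carrying its overall pooled effect where
available and otherwise the estimate from the set with its smallest
adjusted p. Restricting inputs to the overall analysis alone would drop
microRNAs detectable only within a stratum, which is exactly the evidence
subgroup analyses exist to surface.

## Biomarker selection

Candidates must be (a) significant somewhere and direction-consistent
everywhere they are significant, and (b) measured inputs on the target
disease pathway, provided that pathway is itself significantly impacted.
Candidates tested for publication bias must additionally survive the
trim-and-fill gate. Ranking uses the two-key priority — blood-detectable
candidates (significant in the blood tissue subgroup or any blood-fraction
subgroup) form tier 1 ahead of everything else; more supporting analyses
rank higher within a tier — made into a total order with three documented
tie-breaks: smaller minimum adjusted p, larger maximum |logOR|, then name.
A total order costs nothing and buys reproducible output.

## The synthetic-data generator

`simulation_config()` defaults describe a blood-dominated corpus of 50
microRNAs across 40 parent studies (80% one cohort, 20% two), log-normal
combined sample sizes (median 60, sigma 0.5, truncated to [10, 500]),
control-arm event probability 0.15, and a 15% chance that any cohort
reports any given microRNA (about 6–8 substudies per microRNA). Five
microRNAs carry planted effects of |logOR| = 2 with alternating direction
and between-substudy SD 0.3 on the log-odds scale — effects are planted on
the logit of the case-arm event probability, so the 2x2 estimand
approximately equals the planted value. These defaults are the design point
at which the package's recovery properties are stated: about 80–90% of
seeded replicates recover at least 4 of the 5 planted microRNAs after
Bonferroni, and none of the null microRNAs are flagged in a typical run.

Optional selective-reporting censoring (`suppress_small_null`) drops
null-microRNA substudies with |logOR| below 0.5 with probability 0.8,
inducing the funnel asymmetry the bias stage is meant to detect. The
interaction generator gives every planted pair three experimental PMIDs
over two databases plus a well-ranked prediction, and four flavours of
decoy (qualifying, single-PMID, experimental-only, prediction-only); a
configurable fraction of all PMIDs is then retracted. The pathway generator
wires all planted targets into one connected DAG with mixed edge signs and
builds node-count-matched null DAGs from the decoy gene namespace. Each
artefact draws from its own stream derived from the master seed, so stages
can be regenerated independently and reruns are bit-identical.

What the generator does **not** emulate: platform-specific measurement
error, correlated effects within multi-cohort studies, realistic microRNA
sequence families, gene-level expression evidence, or the long-tailed
reporting frequencies of real literatures. Passing the planted-recovery
tests therefore demonstrates that the pipeline's statistics and gates work
as specified under their own model assumptions — not that any particular
real corpus would yield the same biomarkers.

## Numerical choices and degenerate inputs

* tau-squared tolerances: bisection and optimisation to `1e-8`; estimates
  verified against a two-stage grid search at step `1e-6` in the tests.
* Begg standardised variances are clamped at `1e-12` with a warning if the
  fixed-effect subtraction turns non-positive.
* Exact-vs-approximate Begg cutoff: `k <= 8` and no ties.
* Trim-and-fill `k0` is capped at `k - 2` so re-centring always has at
  least two effects to work with.
* Zero cells in the 2x2 table always trigger the continuity correction;
  equal event proportions yield exactly `y = 0`.
* Propagation: `rcond < 1e-12` triggers one damping retry at 0.9.
* Ranking tie-breaks terminate in the microRNA name, which is unique, so
  rank ties cannot occur.

## Problem sizes used in the test-suite

The packaged checks run: 100 seeded replicates for planted-effect recovery
and 100 for null control at the default design point; 50 random DAGs
against a topological-order propagation oracle; 50 seeded instances of the
tau-squared grid-search comparison; and 50 full pipeline replicates (with
`n_perm = 200`) for the planted-pathway and tier-1 recovery rates. These
sizes give stable rates for the thresholds tested while keeping the default
`testthat` run to a few minutes.

## Known limitations

Substudies sharing a parent publication are pooled as independent.
Fold-change magnitudes are not modelled — the event-count odds ratio is the
only effect scale. The trim-and-fill implementation provides the L0
estimator only. KGML pathway files must be converted to the edge-list
dialect externally. The alias table is a small editable mechanism, not a
registry-scale resolution service.
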