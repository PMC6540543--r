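---
title: "Multi-study differential-expression meta-analysis for GBM biomarker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-study differential-expression meta-analysis for GBM biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single gene-expression studies of glioma are small, platform-heterogeneous
and frequently disagree. A biomarker screen that is robust to these
differences combines evidence *across* studies instead of pooling samples:
each study contributes its own differential-expression statistics for a
contrast of interest (glioblastoma, GBM, against non-glioma tissue, NG, or
against the astrocytoma A and oligodendroglioma OD subtypes), and the
combination operates on those per-study summaries. `gliometa` implements
this workflow end to end — per-study statistics, four p-value combination
methods, random-effects effect-size pooling, a dual-method selection rule
with training/validation confirmation and subtype-specificity filtering, and
the downstream survival, diagnostic and enrichment statistics — together
with a synthetic multi-study generator so that every stage can be exercised
and validated against a known truth without any external data.

```{r setup, eval = FALSE}
library(gliometa)
```

## The synthetic cohort generator

`simulate_multistudy()` emulates the statistical structure of a curated
microarray compendium. For gene $g$, sample $j$ of class $c$ in study $k$,
the simulated log2 expression is

$$x_{gjk} = b_g + u_{gk} + \theta_{gk}\,\mathbb{1}[c \in A_g] + \varepsilon_{gjk},$$

with gene baselines $b_g \sim U(4, 12)$, gene-wise study shifts
$u_{gk} \sim N(0, \sigma_b^2)$ standing in for platform effects, residual
noise $\varepsilon \sim N(0, \sigma^2)$, and a planted true effect
$\theta_{gk} \sim N(\pm\delta, \tau^2)$ realized independently per study.
The affected class set $A_g$ encodes the two kinds of planted genes:
*pan-glioma* genes shift GBM, A and OD equally (glioma markers that cannot
distinguish GBM from the other subtypes) while *GBM-specific* genes shift
only GBM samples, up or down. Null genes have $\theta = 0$ everywhere. A
truth ledger records each gene's class and its realized per-study effects,
which is what the end-to-end tests score recovery against.

Defaults (ten studies of 15 samples per class; 2000 genes of which 60
pan-glioma and 40 GBM-specific with a 3:1 up:down split; $\delta = 1.5$,
$\sigma = 1$, $\tau = 0.3$, $\sigma_b = 0.5$) describe a realistic
desk-scale compendium: per-study standardized effects around 1.5 with
moderate between-study heterogeneity ($\tau/\delta = 0.2$) and platform
shifts of half a residual SD. The generator reproduces byte-identical output
under a fixed seed, with per-study substreams derived deterministically from
the master seed.

What it deliberately does **not** emulate: probe-level intensities and
normalization artifacts, correlated gene modules, class-imbalanced dropout,
or non-exponential survival. Passing tests on this generator therefore
demonstrate the correctness and calibration of the *statistics*, not
robustness to every failure mode of real microarray data.

`simulate_survival_cohort()` links survival to expression through an
exponential proportional-hazards model
$\lambda(x) = \lambda_0 e^{\beta x}$ with independent exponential censoring,
which is the minimal model under which a median split of expression should
separate survival curves.

## Per-study statistics

For each study and contrast, `study_de()` computes three summaries per gene:

* **Moderated t**: $t = \bar d / (s_p\sqrt{1/n_1 + 1/n_0} + s_0)$, a
  fudge-constant ("SAM-style") variance-stabilized t. With `s0 = "auto"` the
  stabilizer is the median across genes of the classical standard-error
  term, so genes with vanishing pooled variance cannot produce infinite
  statistics; `s0 = 0` recovers the classical pooled t exactly.
* **One-sided permutation p-values**: class labels are permuted $B$ times
  (default 200) and the null statistics are pooled across genes, giving
  resolution $1/(1 + BG)$ rather than $1/(1+B)$; the add-one estimator
  $p = (1 + \#\{t^\ast \ge t\})/(1 + BG)$ keeps every p-value strictly
  positive, which the downstream log-based combination requires. The
  stabilizer is held at its observed value across permutations. Pooling
  across genes assumes approximate exchangeability of null genes — the
  standard trade-off for genome-wide permutation with few samples.
* **Hedges' g**: $g = J\,\bar d/s_p$ with the small-sample correction
  $J = 1 - 3/(4(n_1+n_0-2) - 1)$ and variance
  $v = (n_1+n_0)/(n_1 n_0) + g^2/(2(n_1+n_0))$. Genes with zero pooled SD
  are reported and excluded rather than imputed.

## Combining evidence across studies

All combination operates on the genes-by-studies matrices of one-sided
p-values over the cross-study intersection universe. Four methods are
provided, matching the standard microarray meta-analysis toolbox:

* **Fisher**: $S = -2\sum_k \ln p_k \sim \chi^2_{2K}$ (an analytic
  reference; a permutation-calibrated variant is available since the
  per-study p-values themselves are permutation-based);
* **maxP**: $\max_k p_k$, with null CDF $m^K$;
* **roP**: the $r$-th smallest p-value, Beta$(r, K-r+1)$ under the null;
  the default $r = \lceil K/2 \rceil$ asks for evidence in at least half the
  studies;
* **AW (adaptively weighted)**: the minimum over prefix sizes $j$ of the
  chi-square$(2j)$ tail of the Fisher statistic on the $j$ smallest
  p-values. For 0/1 weights only sorted prefixes can attain the minimum
  (verified against exhaustive subset search in the tests), so the search is
  linear in $K$; because a minimum of dependent tails is not uniform, the AW
  statistic is calibrated against simulated null matrices of uniforms, and
  the minimizing subset is reported as the per-gene weight vector.

**Two-sidedness.** Each method combines the right-tail (up) and left-tail
(down) p-values separately and reports $p = \min(1, 2\min(p_\mathrm{up},
p_\mathrm{down}))$ with the winning side as the direction. This wrap is
symmetric and *valid but conservative*: the side p-values are exactly
uniform under the null (and are returned as `p_up`/`p_down`), while the
doubled minimum is calibrated in the tails that matter for selection and
stochastically larger than uniform mid-range (for maxP at $K = 6$ the ECDF
sits up to $\approx 0.14$ below the diagonal around $p = 0.8$). The null
calibration tests assert exactly this: uniformity of the one-sided p,
validity plus tail calibration of the two-sided p.

**Effect-size branch.** `pool_random_effects()` implements
DerSimonian–Laird: $Q = \sum w_k (g_k - \bar g_{FE})^2$ with $w_k = 1/v_k$,
$\hat\tau^2 = \max\!\big(0, (Q - (K-1))/(\sum w - \sum w^2/\sum w)\big)$,
random-effects weights $w^\ast_k = 1/(v_k + \hat\tau^2)$, pooled effect
$\hat\mu = \sum w^\ast g / \sum w^\ast$, $se = (\sum w^\ast)^{-1/2}$, and a
two-sided normal p-value for $z = \hat\mu/se$. The implementation is checked
against `metafor::rma(method = "DL")` and recovers $(\mu, \tau^2)$ in
simulation.

Benjamini–Hochberg adjustment is applied within each comparison's gene
universe, never across comparisons. `detection_competency()` tabulates DEG
counts per method across an FDR grid; no ordering among methods is asserted
because it depends on the signal pattern (maxP rewards consistency, AW
rewards concentrated signal).

## The selection cascade

Selection mirrors the discovery design of multi-cohort biomarker screens:

1. **Dual-method rule** (GBM vs NG): genes below the stringent FDR in *both*
   the Fisher branch and the random-effects branch, with agreeing direction.
2. **Training/validation confirmation**: the dual-method rule applied
   separately to disjoint training and validation study sets, intersected
   with direction agreement.
3. **Specificity filter**: intersection with the GBM-vs-A and GBM-vs-OD
   sets (Fisher, FDR < 0.05), again direction-agreeing — pan-glioma genes
   fail here because they carry no GBM-vs-A or GBM-vs-OD signal.

Direction agreement is enforced at every intersection; "consistently
differentially expressed" is not operational without it, and conflicting
genes are reported rather than silently dropped.

**Thresholds.** The stringency of the dual-method threshold must be set
relative to the resolution the cohort can deliver. The default
`fdr_stringent = 0.01` was sized by a power calculation at the generator's
default conditions: with 4 validation studies of 15 + 15 samples the
random-effects z-statistic for a $\delta = 1.5\sigma$ gene is about
$5.7 \pm 1$, and the permutation floor at $B = 200$, $G = 2000$ caps
per-study p-values at $2.5\times10^{-6}$; demanding dual-branch FDR $< 0.01$
then retains the bulk of planted genes while BH keeps the false-discovery
fraction at or below 1%. For compendium-scale cohorts (hundreds of samples
per study, $K \ge 7$ per branch) far more extreme thresholds such as
$10^{-19}$ are attainable and can simply be passed as `fdr_stringent`.

## Downstream statistics

* `survival_by_median()`: patients split at the median expression
  (ties-to-low convention, stated because the median is frequently attained
  at odd $n$), Kaplan–Meier curves per group (`survival::survfit`), and the
  two-group log-rank test (`survival::survdiff`), with an `exclude_flag`
  pass-through so a sensitivity analysis can drop flagged patients (e.g.
  G-CIMP-positive) without re-deriving the flag, which is out of scope.
* `roc_auc()`: ROC/AUC via `pROC` with an explicit positive class; the AUC
  equals the all-pairs Mann–Whitney probability with ties counted half.
* `kruskal_wallis()`: tie-corrected rank H via `stats::kruskal.test`.
* `hypergeometric_ora()`: a local over-representation test —
  $P(X \ge \text{overlap})$ under the hypergeometric law given the
  background universe — replacing web enrichment services; the background
  defaults to the meta-analysis gene universe, and BH is applied across
  sets.
* `score_ihc()` / `fold_change_ddct()`: the two wet-lab quantification
  rubrics. The immunoreactivity score is intensity (0–3) times extent
  (0–4), binned low (0–7) / medium (8–10) / high (11–12). The printed
  extent ranges overlap at 5% and leave (25, 26) unassigned, so percentages
  are rounded to integers first and an exact 5% falls in the higher bin
  (the lower bound of a bin wins); note 11 is unattainable as a product,
  which leaves the printed bins exhaustive anyway. Relative qPCR expression
  is $2^{-\Delta\Delta C_t}$, invariant to shifting all four cycle counts.

## Numerical conventions and degenerate inputs

* Low-signal filtering removes genes strictly below the empirical quantile
  (linear interpolation), mean stage first, SD stage on the survivors; ties
  at the cut survive so the filter never exceeds its nominal fraction. Note
  that re-applying the filter removes a further fraction of the survivors —
  the operation is a fixed two-stage rule, not a projection.
* Probe collapsing keeps the probe with the highest mean expression
  (row-mean and per-sample-max rules are available behind `rule=`);
  deterministic tie-break by probe identifier.
* Gene symbols are upper-cased at construction to blunt cross-platform
  capitalization differences; no alias resolution is attempted.
* All p-values entering log-based combination are strictly positive by the
  add-one construction; zero inputs are rejected rather than clamped.
* Degenerate cases error loudly: zero samples in a class, all-identical
  values at dichotomization or in the Kruskal–Wallis tie correction,
  no events in the log-rank test, empty gene universes.

## Problem sizes used by the test-suite

The packaged checks run the full pipeline at the generator defaults (10
studies, 2000 genes, ~40 s for the whole suite on one core): the
specificity-filtered set is required to contain at least 90% of the planted
GBM-specific genes, at most 10% non-planted members, and no pan-glioma
genes, and the linked survival association must be detected at p < 0.05.
Calibration checks use 5000-gene null matrices over six studies, 300
replicate null cohorts for log-rank/Kruskal–Wallis type-I error, and 500
replicates of a 50-study meta-analysis for DerSimonian–Laird parameter
recovery. These sizes were chosen so each stochastic assertion sits at
least three Monte-Carlo standard errors from its boundary under the stated
conditions.

## Known limitations

* The permutation null is pooled across genes; with strongly dependent or
  heteroskedastic genes the per-gene calibration is approximate.
* The AW weight search covers 0/1 weights only (as is standard); fractional
  weights are out of scope.
* No empirical-Bayes variance moderation (limma-style priors) — the
  moderated t here is the simpler fudge-constant variant.
* Cox modelling, stratified/trend log-rank variants and multi-class ROC are
  intentionally not provided.
* The generator's Gaussian, gene-independent noise understates the
  correlation structure of real expression compendia.
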