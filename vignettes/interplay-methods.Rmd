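---
title: "Methods: taxonomy-driven interplay classification for 2x2 combination experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomy-driven interplay classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interplay2x2)
```

## The model

A 2×2 combination experiment observes log2 expression for each feature *g*
under four conditions: control C, single interventions A and B, and the
combination AB, with $n_c$ replicates each ($n_c = 3$ in the typical design
this package targets). The cell-means model is

$$y_{gci} = \mu_{gc} + \varepsilon_{gci}, \qquad
  \varepsilon_{gci} \sim N(0, \sigma_g^2),$$

with a feature-specific variance shared across conditions. The fit produces
the condition means $\bar y_{gc}$ and the pooled residual variance $s_g^2$
on $d_g = N - 4$ degrees of freedom; with unequal replication the pooled
within-condition sum of squares generalises the balanced formula.

Interplay is expressed through four linear contrasts:
$\psi_A = \mu_A - \mu_C$ and $\psi_B = \mu_B - \mu_C$ (single effects),
$\psi_{int} = \mu_{AB} - \mu_A - \mu_B + \mu_C$ (interaction: combined
effect minus the sum of single effects) and $\psi_{AB} = \mu_{AB} - \mu_C$
(combined effect). Crossing the sign of $\psi_{int}$ (negative / near zero /
positive) with which single constituents are effective gives 12 cells, of
which two are impossible when the combination itself is effective (both
singles inert cannot coexist with a non-positive interaction), leaving the
ten forms the classifier emits, each in an up- and a down-regulated mirror.
Down mirrors flip every strict inequality; near-equality components are
direction-free.

## The compound tests

Each form is a conjunction of partial alternative hypotheses, tested as:

* **strict inequalities** — one-sided moderated t tests of the contrast,
  $t = \hat\psi / \mathrm{SE}(\hat\psi)$;
* **near-equalities** — TOST equivalence tests against the symmetric
  tolerance interval $[-\epsilon, \epsilon]$:
  $U_{upper} = (\epsilon - \hat\psi)/\mathrm{SE}$,
  $U_{lower} = (\hat\psi + \epsilon)/\mathrm{SE}$, each referred to the
  upper tail of $t_{\tilde d}$; the TOST p-value is the larger of the two.

The partials are compounded by an intersection-union test: the compound
p-value is the maximum of the partial p-values, and the compound hypothesis
is accepted exactly when every partial rejects at level $\alpha$. When every
partial test is level-$\alpha$ the compound test is level-$\alpha$ as well;
it is typically conservative, since the compound null is a union.

Standard errors use the empirical Bayes moderated variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ on
$\tilde d = d_0 + d_g$ degrees of freedom. The hyperparameters are estimated
by moment matching on $z_g = \log s_g^2$: the spread of $z_g$ in excess of
the known $\psi'(d_g/2)$ sampling component equals $\psi'(d_0/2)$
(inverted by monotone root-finding), and $s_0^2$ follows from the mean of
$z_g$ through the matching digamma terms. This is the standard moderated-
statistics estimator for gene expression; the suite cross-checks it against
the `limma` implementation.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.05 | — | level of every partial test, hence of each compound test |
| `eps` | 0.15 | log2 | half-width of the near-equality tolerance interval |
| `require_ab_effective` | `TRUE` | — | append an explicit one-sided AB-vs-C partial to every pattern |
| `fdr` | `FALSE` | — | optional Benjamini–Hochberg across features per pattern |

The default $\epsilon = 0.15$ is deliberately small for genome-wide log2
data: a wider interval lets features with small standard errors satisfy a
near-equality *and* an adjacent strict inequality simultaneously, producing
multi-label assignments. The classifier never resolves such conflicts by
priority — it reports the feature as `ambiguous` with the full accepted set.

`require_ab_effective = TRUE` turns the taxonomy's premise "the combined
manipulation is effective" into a tested component rather than an unchecked
assumption; switching it off reproduces the three-partial variant in which
emergent-type patterns rest on the interaction partial alone.

No across-feature multiplicity correction is applied by default: the
canonical report is the per-feature level-$\alpha$ decision. The optional BH
adjustment operates on the compound p-values within each pattern.

## Operating characteristics of the TOST partials

A TOST partial accepts near-equality only when
$|\hat\psi| < \epsilon - t_{\tilde d,1-\alpha}\,\mathrm{SE}$, so its power
at a true zero difference is governed by the ratio
$\epsilon / \mathrm{SE}$. With $n = 3$ replicates, the single-effect
contrasts have $\mathrm{SE} = \sigma\sqrt{2/3}$ and the interaction
contrast $\mathrm{SE} = \sigma\sqrt{4/3}$ — the widest of the four. Useful
rules of thumb at $\alpha = 0.05$:

* acceptance is *impossible* once
  $\mathrm{SE} \ge \epsilon / t_{\tilde d, 1-\alpha}$
  (for the interaction contrast at $\epsilon = 0.15$ this is reached
  already at $\sigma \approx 0.08$);
* near-certain acceptance of a true zero needs roughly
  $\epsilon / \mathrm{SE} \ge z_{0.95} + z_{0.975} \approx 3.6$, i.e.
  $\sigma \lesssim \epsilon / (3.6\sqrt{4/3}) \approx 0.036$ for the
  interaction at $\epsilon = 0.15$.

Consequently, patterns containing near-equality components are only
detectable on data whose residual noise is small against the tolerance.
The suite's full-taxonomy recovery study therefore runs at $\sigma = 0.03$,
chosen from the second rule, while strict-inequality patterns (synergism,
antagonism) are exercised at the noisier $\sigma = 0.1$.

A second intrinsic ceiling concerns *unique* labels. A feature planted
exactly on a near-equality boundary (e.g. an additive feature with
interaction exactly 0) lets each adjacent strict-inequality partial reject
with probability $\alpha$, so the probability of a unique label is capped
near $1 - 2\alpha$ regardless of noise level; the excess mass is reported as
`ambiguous`. `evaluate_recovery()` hence reports both unique-label
sensitivity and accepted-set membership sensitivity.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the classifier assumes: a
features × (4·n) log2 matrix with three replicates per condition by
default, per-feature variances drawn from a scaled-inverse-chi-square prior
($d_0 = 4$, $s_0^2 = 0.04$ by default, matching the moderation model), and
Gaussian noise around planted condition means. Planted means place strict
components at ±`effect_size` (default 1 log2 unit — a twofold change, an
unambiguous effect for this assay class), near-equality components exactly
at 0 (interior of the tolerance interval), and the interaction at
±`interaction_size` (default `effect_size`). Reductive patterns are the one
exception: an interaction of $-e$ would cancel the combined effect entirely
and violate the taxonomy premise $\mu_{AB} > \mu_C$, so reductive cells
plant the interaction at $-e/2$, leaving a combined effect of $e/2$.
Boundary placement (components at exactly $\pm\epsilon$) is a size-check
configuration, not the recovery default.

What the generator does **not** emulate: probe-level effects and
normalization artifacts, correlation between features, heavy-tailed or
heteroscedastic noise, and mean–variance trends. Passing recovery tests on
this generator therefore demonstrates the statistical machinery under its
own assumptions, not robustness to real-array pathologies.

## Numerical choices and degenerate inputs

* All computation stays on the log2 scale as supplied; no re-transformation.
* Trigamma inversion: bracket expanded geometrically, `uniroot` tolerance
  1e-8; $d_0$ above 1e8 is reported as $+\infty$, in which case
  $\tilde s^2 = s_0^2$ for every feature and test tails use the standard
  normal (the $t_{\infty}$ limit). When the observed log-variance spread
  does not exceed the pure sampling component, $d_0 = +\infty$ and $s_0^2$
  is the mean observed variance.
* Zero-variance features (all replicates identical) are excluded from prior
  estimation, retained in the output with status `degenerate`, and never
  classified — every statistic here needs a positive standard error.
* Features containing missing values are dropped with a logged count; no
  imputation rule is imposed.
* $\hat\psi = 0$ gives one-sided p = 0.5 exactly; opposite one-sided tests
  on one contrast sum to 1, so no pattern and its mirror can co-accept at
  $\alpha < 0.5$.
* Moderation metadata records that the plain estimator is used — no
  mean–variance trend and no robust down-weighting variants.

## Reproducing published reference counts (parity note)

The package's defaults ($\alpha = .05$, $\epsilon = .15$, labels
`UNSTIMULATED`/`CURDLAN`/`GM-CSF`/`COMBINATION` mapped to C/A/B/AB) mirror a
published dendritic-cell study of curdlan × GM-CSF (GEO accession
GSE32986, ~45 101 probesets, 3 replicates per condition) whose headline
counts are 1997 classified probesets (1005 antagonistic, 49
synergistic-up) for the 100 μg setup and 1693 for the 1 μg setup. Those
arrays are not shipped here; to attempt the reproduction, place
RMA-normalized log2 matrices and targets files at
`tests/testthat/gse32986/{matrix_100ug.tsv,targets_100ug.tsv,matrix_1ug.tsv,targets_1ug.tsv}`
and the integration test will run automatically. Exact count equality
additionally requires matching the original RMA numerics and empirical
Bayes implementation version: small numeric differences in either move
features across the hard $p < \alpha$ threshold, so near-miss counts should
be judged by magnitude, not equality.

## Problem sizes in the shipped studies

The test-suite simulations use 10 000 features for the boundary-null size
study, 500 features per pattern for recovery runs, and 20 000 simulated
variances for hyperparameter recovery — sizes at which Monte-Carlo error is
a small fraction of the tolerances being asserted while the whole suite
completes in seconds on one core.

## Known limitations

* Mixed-sign interplay (one constituent up-, the other down-regulating) and
  patterns with effective singles but an ineffective combination are outside
  the taxonomy.
* The intersection-union construction is conservative; its true size is
  below $\alpha$ away from the least-favourable null configuration.
* A single $\epsilon$ applies to every near-equality partial, including the
  interaction contrast, although the interaction estimator is intrinsically
  noisier; contrast-specific tolerances would change the taxonomy's
  geometry and are deliberately not offered.
* Probeset-to-gene annotation, pathway enrichment and upstream
  normalization are out of scope: the package consumes an already-normalized
  log2 matrix and passes feature identifiers through untouched.
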