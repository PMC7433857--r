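---
title: "Quantifying semantic storage loss: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying semantic storage loss: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sslscore)
```

## The clinical problem

Anomia — the inability to name pictured objects — is near-universal in
primary progressive aphasia (PPA), but it can arise from two distinct
impairments. A *semantic storage* deficit reflects degraded amodal concept
representations (classically linked to the anterior temporal lobe, ATL):
naming failures resist phonemic cueing and the same items fail across
production and comprehension tasks, often despite relatively preserved
general cognition. A *semantic processing/access* deficit leaves the
representations intact but retrieval impaired: cues help, and failures are
inconsistent across tasks. `sslscore` implements a composite that places an
individual on this continuum.

## The score

Four tasks feed three sub-scores, each in $[0, 1]$, each approaching 0 with
more severe storage loss. With $N$ = spontaneous naming correct (of 64),
$C$ = cumulative cued-naming correct (spontaneous **or** cue-recovered, so
$C \ge N$), $W$ = word–picture matching (WPMT) correct (of 64), and $M$ =
MMSE (of 30):

$$
c_{\mathrm{cue}} = \frac{C - N}{64 - N}, \qquad
c_{\mathrm{cons}} = \frac{W - N}{64 - N}, \qquad
c_{\mathrm{ratio}} = \frac{x}{x + y},\;
x = \frac{N}{64},\; y = \frac{M}{30},
$$

and the omnibus score is their unweighted mean,
$\mathrm{SSL} = (c_{\mathrm{cue}} + c_{\mathrm{cons}} + c_{\mathrm{ratio}})/3$.
Equal weighting is deliberate: there is no prior reason to privilege one
marker of storage loss over another, and all three share range and
direction. $c_{\mathrm{ratio}}$ equals 0.5 when naming and MMSE proportions
match, tends to 0 when cognition outstrips naming (storage-like), and to 1
when naming outstrips cognition.

```{r}
ssl_score(51, cued_correct = 61, wpmt_correct = 63, mmse = 19)
```

### Aggregate versus item-level consistency

The consistency score is defined *per item*: among exactly the items missed
in spontaneous naming, the fraction recognized in WPMT
(`consistency_score_items()`). When only aggregate counts are available the
package reconstructs it as $(W - N)/(64 - N)$, which is exact **iff** every
spontaneously named item was also recognized in matching. Since that
monotone-nesting assumption can fail in real data, aggregate-mode results
carry an `"aggregate-mode"` flag, and item-level data are canonical when
they exist. A worked divergence: aggregate counts (naming 31, WPMT 45)
reconstruct $14/33$, but an item configuration with the same margins in
which three named items went unrecognized yields $17/33$.

A second, non-canonical variant measures consistency relative to *cued*
naming (items missed even with a cue); it is available as
`consistency_score_aggregate(baseline = "cued")` but it is **not** the
definition that reproduces the published per-participant scores, which is
why the spontaneous baseline is the default.

### Numerical choices

- **Clamping.** $(W - N)/(64 - N)$ can be negative (WPMT below spontaneous
  naming occurs in the reference cohort). The quantity is a proportion, so
  it is clamped to 0 and flagged `"clamped"`.
- **Degenerate inputs.** Naming at ceiling ($N = 64$) leaves no missed
  items and both proportion scores undefined; $N = M = 0$ leaves
  $c_{\mathrm{ratio}}$ undefined. Both raise typed errors
  (`ssl_no_missed_items`, `ssl_undefined_ratio`) rather than returning
  sentinels — such participants were excluded from scoring at the source —
  and `score_cohort()` retains the rows with explicit reason codes.
- **Rounding.** Reported scores use 2 decimals, rounding half away from
  zero (`round_display()`): this is required to turn 0.505 into the
  published 0.51. All statistics run on unrounded values; a
  "printed-column" analysis mode (passing `ssl_printed` from the fixture)
  exists solely to reproduce published summary rows.
- **Task maxima.** 64 and 30 are configuration (`naming_max`, `mmse_max`)
  defaulting to the 64-item naming battery and the MMSE, so other
  instruments can be scored.

## The reference cohort

`load_fixture()` ships 28 PPA participants (11 nfvPPA, 5 svPPA, 12 lvPPA)
with raw task counts and the originally reported 2-decimal SSL values.
Recomputing from raw counts reproduces 26 of 28 reported values exactly;
rows DL and WB do not reproduce from their own printed task scores
(recomputation gives .43 and .36 against printed .53 and .41) and are
flagged `reproduces_printed = FALSE` — most plausibly transcription errors
in the source table, so no alternative formula is guessed. Similarly, the
published omnibus $F(2, 25) = 26.90$ was computed on unrounded
per-participant values that were never published; the 2-decimal column
yields $F = 27.92$, so tests assert the *significance* statements (omnibus
and all three Scheffé contrasts), not the printed statistic.

```{r}
fx <- load_fixture()
group_summary(fx$ssl_printed, fx$group_label)
```

## Normative screening

Eligibility for the anomic cohort required abnormal naming (Cambridge
Naming below 60), abnormal semantic memory (CCT-Picture below 54) and
exclusion of very mild anomia (spontaneous naming above 59).
`derive_cutoff()` computes the underlying rule — control mean minus
$k$ SD (default $k = 2$, sample SD) — but the integer thresholds are
deliberately configuration, not derivation: the published pair is mutually
inconsistent as a rounding rule (60 is the floor of
$62.81 - 2 \times 1.00 = 60.81$, while 54 is the ceiling of
$58.80 - 2 \times 2.48 = 53.84$), so the published integers are defaults
and the raw threshold is reported alongside. A control score of exactly 60
is *not* abnormal under the published `< 60` rule even though it lies more
than 2 SD below the mean; the published threshold wins.

## Validation statistics

`oneway_anova()`, `scheffe_posthoc()`, `pearson_r()` and
`hierarchical_r2_change()` are implemented from the classical definitions
(between/within decomposition; Scheffé criterion
$(g-1) F_{\alpha; g-1, n-g}$ against the pairwise contrast statistic;
$t = r\sqrt{(n-2)/(1-r^2)}$ two-tailed; nested-OLS
$F_{\Delta} = (\Delta R^2/q) / ((1 - R^2_{\mathrm{full}})/(n - k - 1))$).
Each is tested against an independent base-R oracle
(`stats::oneway.test`, `stats::cor.test`, `lm()` + `anova()`, and explicit
normal-equations projections) rather than delegating to it. Correlations
use pairwise-complete deletion, matching a validation design in which
different participants were missing different ROI values; all p values are
two-tailed with $\alpha = 0.05$. An exact full-model fit reports
`F_change = Inf`, `p = 0`.

The imaging validation itself (SSL vs ATL FDG-uptake ratios, $r \approx
.78$) cannot be reproduced here — the PET data are not public — so those
numbers are documented expectations, and the package's claim is structural:
the statistics are correct (oracle-tested) and the synthetic generator
recovers a known coupling (below).

## The synthetic cohort generator

`simulate_cohort()` exists so scoring and statistics are testable end to
end without clinical data. Each participant has two latent traits on
$[0,1]$, drawn from truncated normals: semantic integrity $s$ and general
cognition $g$. The four tasks are emulated as:

- 64 Bernoulli($s$) spontaneous-naming outcomes (so $p_{\mathrm{name}}(s) = s$,
  the simplest monotone link);
- each miss recovered with a cue with profile probability
  `p_cue_given_miss`;
- WPMT recognition per item: misses recognized with `p_wpmt_given_miss`,
  hits with `p_wpmt_given_hit` = 0.98 — deliberately below 1 so the
  item-level/aggregate divergence path is exercised;
- MMSE ~ Binomial(30, $g$);
- ROI couplings
  $\mathrm{ATL} = \beta_0 + \beta_1 s + \mathcal N(0, \sigma)$ and
  $\mathrm{dlPFC} = \gamma_0 + \gamma_1 g + \mathcal N(0, \sigma)$, with
  defaults $\beta_0 = \gamma_0 = 0.7$, $\beta_1 = 0.5$, $\gamma_1 = 0.4$,
  $\sigma = 0.05$, giving ratios in a plausible 0.7–1.2 band around the
  reference value 1.

The three default profiles (`default_profiles()`) span the deficit
spectrum. Their parameters were fixed once so that simulated group-mean SSL
scores land near the published group means (0.69 nfvPPA-like / 0.51
lvPPA-like / 0.29 svPPA-like); they are calibration targets for realism,
not estimates of ground truth:

| profile | $s$ (mean, SD) | $g$ (mean, SD) | p(cue) | p(WPMT miss) | expected SSL |
|---|---|---|---|---|---|
| storage-like | 0.20, 0.10 | 0.55, 0.15 | 0.10 | 0.45 | ~0.28 |
| intermediate | 0.35, 0.12 | 0.45, 0.15 | 0.50 | 0.60 | ~0.51 |
| processing-like | 0.65, 0.12 | 0.65, 0.12 | 0.75 | 0.85 | ~0.68 |

Reproducibility is bit-for-bit under `(profiles, n, seed)`: one RNG stream
is seeded once per cohort and consumed in profile order (separate
per-participant substreams were considered and dropped — a single
sequential stream already satisfies the determinism contract in base R and
keeps the generator vectorized).

What a green test does and does not establish: the generator emulates
group-structured task performance and a *linear* latent–metabolism
coupling with Gaussian noise. Real cohorts have item-difficulty structure
(the 8 semantic categories are exchangeable here), correlated
task-specific error, non-linear and spatially structured hypometabolism,
and diagnostic heterogeneity — none of which are modelled. Passing the
parameter-recovery test shows the pipeline recovers a coupling of the
stated form; it says nothing about the clinical validity of the score.

## Known limitations

The score indexes loss of *concrete object* representations only — verbs
and abstract nouns are out of scope — and it is not a diagnostic
instrument: a low score suggests storage loss but cannot by itself assign
a PPA variant. Screening norms are not stratified by age, sex or
education. The MMSE is a coarse proxy for general cognition, and the ratio
component inherits its verbal content.
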