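---
title: "A Delphi-weighted composite score for haemophilia monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Delphi-weighted composite score for haemophilia monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haemoscore)
```

## The instrument and its score

Haemophilia care is monitored across several loosely coupled indicators:
bleeding frequency, joint status by clinical examination (HJHS) and
ultrasound (HEAD-US), pharmacokinetic adequacy of prophylaxis, treatment
adherence, and patient-reported quality of life (EQ-5D-5L). haemoscore
implements a monitoring instrument that folds these into a single weighted
composite: a questionnaire of single-choice items on three- or four-point
ordinal scales, organised into clinical domains, with the relative importance
of domains and items fixed by a two-round constant-sum Delphi consensus among
haemophilia specialists.

Each item contributes

$$\text{points} = \frac{W}{100}\cdot\frac{w}{100}\cdot r \cdot 100,$$

where $W$ is the section (domain) weight in percent, $w$ the item weight
within its domain in percent, and $r$ the standardised value of the chosen
option: $0, 0.33, 0.67, 1$ on four-point scales and $0, 0.5, 1$ on
three-point scales, with $0$ the clinically optimal anchor and $1$ the worst.
The composite is the sum over all items. Because domain weights sum to 100,
item weights sum to 100 within each domain, and $r = 1$ at every worst
anchor, the score spans exactly $[0, 100]$: the all-optimal profile scores 0,
the all-worst profile scores 100. Higher scores mean larger deviation from
the consensus-optimal profile — a signal for structured treatment
reassessment, not a severity grade. The continuous score maps to four
categories: Excellent $[0, 25]$, Suboptimal $(25, 50]$, Poor $(50, 75]$,
Critical $(75, 100]$. The printed bands are integers (0–25, 26–50, …); we
extend them to the continuum as right-closed intervals so every real score
has exactly one category, which keeps the integer anchors (25 Excellent, 26
Suboptimal) intact.

The standardised values are stored exactly as printed (0.33 and 0.67, not
1/3 and 2/3). The thirds alternative would change scores by up to a third of
a point; keeping the printed grid makes the published anchors bit-exact and
keeps the maximum at exactly 100.

Four configurations ship with the package, one per disease–setting pair
(haemophilia A or B, prophylaxis or on-demand). Prophylaxis instruments have
four domains — pharmacokinetics (trough-level satisfaction), bleeding
episodes (ABR), joint health (problem and target joints and their trends,
HJHS and HEAD-US changes, AJBR), adherence and QoL; on-demand instruments
drop pharmacokinetics, which has no meaning under episodic treatment, and
their adherence/QoL domain reduces to the single current-QoL item (no
adherence question exists without a prescribed regimen, so that item carries
weight 100 within its domain).

```{r}
cfg <- load_instrument("B", "prophylaxis")
cfg
```

One deliberate encoding choice: options are ordered by an explicit
`severity_rank` (0 = optimal), not by their position in the questionnaire
text. The source questionnaire lists the pharmacokinetics options worst-first
but the ABR options best-first; a positional rule would invert the
pharmacokinetics item, so the bundled configurations encode clinical
direction explicitly.

## Raw measures and answer bands

Items can be answered directly or derived from raw clinical measurements:

* ABR and AJBR: events / follow-up days × 365.25 (`annualized_rate()`).
* Adherence: administered / expected prophylactic infusions × 100.
* EQ-5D-5L Level Sum Score: the sum of the five dimension levels, 5 (best)
  to 25 (worst); QoL change is the LSS difference from baseline.

The answer bands are printed for integers ("ABR 1–2", "HJHS +2/+3"), so
continuous rates need a convention: `bucket()` rounds half-up to the nearest
integer and then applies the printed bands, giving a total, monotone mapping
in which rates below 0.5 fall into the optimal "0" band. Adherence follows
the printed inequalities literally: above 90% is optimal, exactly 80% and
90% fall in the middle closed band, below 80% is worst. Worsening thresholds
("+4 points" for HJHS, "+2 points or more" for HEAD-US, "+3 points or more"
for QoL) are read as floors. These conventions are the package's own,
documented here because the source tables do not specify the fractional
cases; the banding rule names are part of the configuration format, so a
user configuration can omit or replace them.

```{r}
abr_item <- config_item(cfg, "abr")
bucket(abr_item, 2.4)   # rounds to 2 -> band "1-2" -> rank 1
```

Missing answers are rejected by default. With `allow_missing = TRUE`,
item weights are renormalised over the answered items within each domain, a
fully unanswered domain is dropped with the remaining domain weights
renormalised, and the result is flagged `partial` — an explicit analogue of
handling gaps by clinical judgement, never a silent reweighting.

## The Delphi machinery

Weights were elicited with a constant-sum rule: each expert distributes 100
points across the slots of a scope (the domains of an instrument, or the
items of one domain), so weights read directly as relative percentage
importance. Convergence is summarised per slot by the quartiles of the
panel's allocations; consensus is declared when the interquartile range is
strictly below 8 points — IQR exactly 8 is not consensus. In round two,
experts re-rate within the closed round-1 interquartile interval
$[Q_1, Q_3]$; values kept outside require a written justification, and
`check_round2()` flags unjustified deviations (in strict mode they abort
weight derivation). Final weights are the round-2 medians,
proportionally renormalised when their sum drifts from 100 (the flag and the
raw sum are kept).

The published tables report fractional IQRs (e.g. 4.75, 3.25) from panels of
9–16 raters, which implies an interpolating quantile definition; the exact
convention is not recoverable from the published medians alone. The default
is linear interpolation between order statistics at $h = (n-1)p$ (R's
`quantile` type 7); nearest-order-statistic and Tukey-hinge conventions are
selectable for sensitivity checks. All published-value fixtures in the tests
use constant panels, on which every convention agrees, so nothing downstream
depends on the choice. Rounds may have different rater sets (the elicitation
saw attrition from 16 to 12 and from 12 to 9 raters); statistics are always
computed over the raters present in that round.

## Synthetic panels and cohorts

The generators exist so every pipeline stage is testable without real expert
or patient data; all take an explicit seed and restore the caller's random
stream.

`simulate_panel()` draws each rater's allocation from a Dirichlet
distribution with shape `concentration × target/100`, the natural
constant-sum noise model: allocations are non-negative, sum to 100 by
construction, and concentrate around the target as the concentration grows
(per-slot standard deviation ≈ $100\sqrt{p(1-p)/(c+1)}$, so concentration
500 with a weight of 18% gives a spread of about 1.7 points — comfortably
inside the consensus threshold, which is why the parameter-recovery tests
use 16 raters at concentration 500 against the published domain targets).
Integer mode apportions each draw by the largest-remainder method with ties
broken by slot order, so integer allocations still sum to exactly 100.

`simulate_round2()` emulates re-rating: with probability `compliance` an
out-of-bounds value is projected into its interval; otherwise it is kept
outside with a generated justification. Re-balancing to 100 scales all slots
by a common factor, clamping complying slots to their intervals (kept-outside
slots float), with the factor found by root-finding; infeasible cases fail
loudly. At full compliance every final value lies inside its interval, which
structurally guarantees that round-2 IQRs cannot exceed round-1 IQRs.

`simulate_cohort()` draws each item's severity rank as
Binomial(scale − 1, severity): severity 0 forces the all-best profile,
severity 1 the all-worst, and the response mass shifts stochastically
monotonically toward worse options in between, so the mean composite is
non-decreasing in severity. `simulate_raw_records()` generates measurement
records with Poisson bleed counts at a nominal annual rate (so the derived
ABR is unbiased), a Binomial thinning for joint bleeds, and Binomial
adherence around a target percentage under a twice-weekly regimen.

What the generators do not emulate: correlation between items within a
patient (real joint damage, bleeding and QoL co-vary), rater-specific biases
or anchoring in panels, attrition that is informative rather than random,
and longitudinal within-patient dynamics. Passing tests therefore establish
the arithmetic and the consensus machinery, not clinical validity of the
instrument on real cohorts.

## Numerical conventions and test scale

Weight sums are checked to 1e−6 for user configurations (bundled ones are
integer-exact); constant-sum allocations to 1e−9; the score decomposition
(composite = Σ domain points = Σ item points) to 1e−9. Driver ordering sorts
items by descending contribution with ties left in configuration order. The
test suite exercises 1000-case oracle comparisons for both the composite
score and the quartile engine, 100 seeded panels for the round-2 projection
property, and severity sweeps with 500 patients per level — sizes chosen to
make the stochastic properties stable at fixed seeds while the whole suite
runs in well under five minutes.

## Limitations

The score categories are consensus-derived descriptive anchors, not
outcome-calibrated thresholds; the package deliberately offers no
therapeutic recommendations tied to them. The published raw ratings are not
available, so the bundled weights are reproduced from the published medians
rather than recomputed from data, and whether those medians were themselves
renormalised to sum to 100 is unstated (they do sum to 100 as printed).
Internal scoring of HJHS and HEAD-US, and EQ-5D-5L utility valuation, are
out of scope: the instrument consumes total-score changes and the Level Sum
Score only.
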