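---
title: "Contextuality-by-Default analysis of forced-choice judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextuality-by-Default analysis of forced-choice judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbdcoin)
```

## The generalized coin and the face-judgment design

A *generalized coin* of cycle rank 4 is a black box with four dichotomous
measurements ("facets") $A_0,\dots,A_3$, of which only adjacent pairs can be
measured simultaneously.  The four *measurement contexts*
$C_i \equiv \{A_i, A_{i+1 \bmod 4}\}$ form a cyclic system.  Every toss in a
context reveals one outcome per facet, coded $\top$ (top / "judged fake")
or $\bot$, with the forced-choice constraint

$$P(\top,\top \mid C_i) = P(\bot,\bot \mid C_i) = 0 ,$$

so the two outcomes of a context anticorrelate perfectly.  The ideal coin
additionally has $P(\top,\bot \mid C_i) = 1/2$ for every context.

The behavioural experiment this package models maps faces onto facets: each
"coin" is a set of four face images $\{F_0, R_1, F_2, R_3\}$ — two
AI-generated (even indices) and two real — and a context is a pair of
adjacent faces shown side by side to a participant who must click the one
they believe is fake.  The design is between subjects: each of the four
contexts has its own group of participants (50 in the reference study), and
every participant judges all 20 coins once, ten female sets then ten male
sets, with left/right placement counterbalanced within every cell.

Each context is summarised by one *designated-outcome marginal*: the
probability that a specific facet of the pair is judged fake,

$$p_0 = P(F_0\,\top \mid C_0),\quad p_1 = P(F_2\,\top \mid C_1),\quad
  p_2 = P(F_2\,\top \mid C_2),\quad p_3 = P(F_0\,\top \mid C_3).$$

`designated_outcome()` encodes this mapping (C0→F0, C1→F2, C2→F2, C3→F0).

## The statistics

**Disturbance.**  A facet appears in two contexts; if judgments were
insensitive to the accompanying face its marginal would be identical in
both.  The probability-scale disturbance sums the four discrepancies:

$$\Delta \;=\; |p_0 - p_3| + |p_1 - p_0| + |p_1 - p_2| + |p_3 - p_2|
  \;\in\; [0, 4].$$

Note this is *half* the $\pm1$-expectation-scale disturbance common in the
Contextuality-by-Default (CbD) literature; the package works on the
probability scale throughout because that is the scale of the published
tables it reproduces.

**The criterion.**  For a cyclic system of rank $n$ the CbD criterion is

$$s_{odd} - (n - 2) - \Delta > 0 \quad\Longleftrightarrow\quad
  \text{contextual},$$

where $s_{odd}$ is a maximal odd-signed sum of the context correlations
(product expectations with $\top = +1$, $\bot = -1$).  Forced choice makes
every correlation exactly $-1$.

**Two $s_{odd}$ conventions.**  `s_odd()` implements both of these:

* `"canonical"` — the CbD-literature definition,
  $\max_{\lambda} \sum_i \lambda_i c_i$ over sign vectors with an odd
  number of $-1$s.  For four perfect anticorrelations this gives 2, under
  which the ideal forced-choice coin is *not* contextual: the alternating
  deterministic assignment $(\top,\bot,\top,\bot)$ reproduces all its
  correlations.
* `"study"` (default) — the convention of the behavioural analysis the
  package reproduces: $\max_S |\sum_{i \in S} c_i|$ over odd-cardinality
  subsets $S$.  For four perfect anticorrelations this gives 3, so the
  criterion becomes $3 - 2 - \Delta = 1 - \Delta$ and the ideal coin
  ($\Delta = 0$) is contextual with value 1.

The published 20-coin table is arithmetically consistent only with the
second convention (every row obeys $\mathrm{CbD} = 1 - \Delta$), so that is
the default; the canonical form is provided, clearly separated, for use
outside this design.  The package reproduces the default convention and
does not adjudicate between the two.

**Boole's condition.**  For four events, existence of a joint distribution
requires $\sum_i p_i - \sum_{i<j} p_{ij} \le 1$ (`boole_lhs()`).  The ideal
coin gives $4 \times 0.5 - 0 = 2$: no joint distribution exists.  The two
non-adjacent pairs are never measured in the cyclic design, so their
$p_{ij}$ are explicit arguments (the analysis passes 0, the value the
design forces on every measured pair) rather than silently assumed.

```{r core}
disturbance_delta(c(0.56, 0.46, 0.42, 0.46))
cbd_statistic(s_odd(rep(-1, 4)), 4, 0.28)
boole_lhs(rep(0.5, 4), rep(0, 6))
```

## Bootstrap interval and classification

`cbd_coin()` resamples each context's judgments with replacement —
equivalently $k^* \sim \mathrm{Binomial}(n_i, k_i/n_i)$ per context, since
the statistic depends only on cell frequencies — recomputes the statistic,
and forms a percentile interval from linear-interpolation empirical
quantiles (R quantile type 7) of 10,000 replicates by default.  Percentile
intervals were chosen as the simplest scheme consistent with the published
asymmetric intervals; no BCa or studentizing is attempted.  A coin is
classified *contextual* when the point statistic lies inside the interval
(inclusive) **and** the lower endpoint is strictly positive.

```{r coin}
fit <- cbd_coin(k = c(28, 23, 21, 23), n = 50, coin_id = 1, seed = 1)
fit
```

Whole studies are fitted by `cbd_analysis()`, which accepts raw judgment
records, per-context counts, or a published-style marginals table (counts
reconstructed as $k = \mathrm{round}(n\,p)$; off-grid cells such as a
marginal of 0.55 at $n = 50$ are reported and support per-cell $n$
overrides).

```{r study}
fit20 <- cbd_analysis(face_study_marginals(), n_boot = 2000, seed = 1)
summary(fit20)
```

## Numerical choices

* **Exact grid arithmetic in the bootstrap.**  With equal cell sizes,
  replicate disturbances are computed from integer count differences with a
  single division, so replicates sit exactly on the $k/n$ grid.  Computing
  them from per-context floating ratios leaves $\sim 10^{-16}$ noise on
  replicates that should be exactly 0 — and the strict "lower endpoint
  $> 0$" rule would then classify boundary coins contextual purely through
  rounding noise.
* **Boundary coins.**  When a replicate distribution has an atom at 0 that
  straddles the 2.5% point, the sample lower endpoint alternates between
  exactly 0 and one grid step above it across bootstrap seeds, and the
  classification genuinely flips.  In the 20-coin reference analysis coins
  6 and 9 sit in this regime: coin 9's endpoint is 0 for essentially every
  seed (non-contextual), coin 6's is 0 for roughly six seeds in ten.  The
  analysis marks any coin with an interval endpoint within 0.02 of 0 as
  `boundary` and `summary()` reports them, so seed sensitivity is surfaced
  rather than hidden.
* **Seeding.**  One master seed per analysis; per-coin substreams are
  derived deterministically from it, so any coin can be refitted
  independently and runs are byte-identical given the seed.  Seeded fits
  restore the caller's random-number state.
* **Display.**  Tables render at 2 decimals (the precision of the published
  tables); all computation keeps full precision.
* **Degenerate inputs.**  Saturated cells ($k = n$) are legal and collapse
  the interval; empty (coin, context) cells are an error at analysis time,
  not read time, so partial files can still be inspected.

## The synthetic generator

`generate_judgments()` simulates the full between-subjects study: each
participant belongs to one context, judges every coin once in coin order,
and chooses the context's designated facet with the coin's true marginal —
judgments are conditionally independent Bernoulli draws given the
marginals.  This is the minimal model consistent with an analysis that uses
only cell frequencies, and it is what parameter-recovery tests assume.  It
deliberately omits features real data may have: participant random effects
(no heterogeneity in ability), dependence among one participant's 20
judgments, order or fatigue effects, and any effect of presentation side
(`position_swapped` is generated for counterbalancing checks but never
influences the simulated judgment).  Passing tests therefore certify the
estimator and pipeline under the design's sampling model, not the
psychological adequacy of that model for real participants.

Defaults mirror the reference study — 20 coins (10 female, 10 male sets),
4 contexts × 50 participants, true marginals from
`face_study_marginals()` — so a study-shaped dataset regenerates from a
seed alone.

## Reproducing the reference analysis

`reproduce_study()` runs the whole pipeline against the reference values.
Its default mode reconstructs counts exactly, making the point statistics
deterministic; the comparison then isolates two known quirks of the
reference table: coin 8's $p_2 = 0.55$ is not representable as $k/50$, and
coin 15's reported disturbance (0.26) is inconsistent with its own reported
marginals (recomputation gives 0.28, matching its reported interval).  With
`sampled = TRUE` the generator supplies participant-level data and binomial
noise propagates into the point statistics — differences are then reported,
not treated as failures.

```{r reproduce}
reproduce_study(seed = 1, n_boot = 2000, quiet = TRUE)
```

## Problem sizes

The shipped tests fit the 20-coin study at 10,000 bootstrap iterations
(about a second: replicates are vectorised binomial draws), check simulator
convergence at $10^5$ tosses per context, and run parameter recovery at
50,000 synthetic participants per context (4 million judgment records);
property checks use a few hundred randomized cases per invariant under
fixed seeds.  These sizes give Monte-Carlo error comfortably below every
tolerance asserted, e.g. a binomial standard error of
$\sqrt{0.25/50000} \approx 0.0022$ against a 0.01 recovery bound.

## Limitations

* The per-coin analysis cannot detect dependence across a participant's
  judgments; the generator's independence assumption matches exactly what
  the analysis can see.
* The `"study"` $s_{odd}$ convention is a reproduction choice, not an
  endorsement; under the canonical convention every forced-choice statistic
  drops by 1 and none of the reference coins would be contextual.
* Bootstrap classification near a zero lower endpoint is seed-sensitive by
  nature (see *Numerical choices*); report the `boundary` flag alongside
  any classification.
* No multiple-testing correction is applied across the 20 coins, matching
  the reference analysis.
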