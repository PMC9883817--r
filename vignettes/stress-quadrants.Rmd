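---
title: "Stress-by-rating quadrants: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-by-rating quadrants: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressquad)
```

## The model

`stressquad` treats a company-review corpus as a panel: one row per review
with a company id, a date, a 1–5 star rating, and free text. Two
per-company summaries over a window $T$ drive everything else:

$$\mathrm{rating}(c,T) = \text{mean star rating of } c \text{'s reviews in } T, \qquad
\mathrm{stress}(c,T) = \frac{\#\,c\text{'s stress-related reviews in } T}{\#\,c\text{'s reviews in } T}.$$

A review is *stress-related* when it contains at least one phrase from a
stress-condition lexicon; a review counts once however many mentions it
contains, because the stress score is a fraction of *posts*, not of
mentions (mention-level counts are available separately via
`condition_frequency_table()`).

Both summaries are z-scored against the cohort of companies active in
$T$, and the signs of $(z_{rating}, z_{stress})$ assign one of four stress
types: low stress $(+,-)$, passive $(-,-)$, negative stress $(-,+)$,
positive stress $(+,+)$. Membership strength is the geometric association

$$f = \frac{R}{\gamma + \pi}, \quad R = \sqrt{z_{rating}^2 + z_{stress}^2},
\quad \gamma = \max\!\Big(\alpha - \tfrac{\pi}{4},\, \beta - \tfrac{\pi}{4}\Big),$$

with $\alpha = \arccos(|z_{rating}|/R)$ and $\beta = \arccos(|z_{stress}|/R)$.
Since $\alpha + \beta = \pi/2$, $\gamma \in [0, \pi/4]$ measures angular
distance from the quadrant diagonal: $f$ ranges from $4R/(5\pi)$ on an
axis to $R/\pi$ on the diagonal, grows strictly with $R$ at fixed
direction, and depends only on $|z|$ values. Companies with no review in
$T$ get $f = 0$.

The yearly index aggregates associations with post-volume weights,

$$m(s,y) = \sum_{c \in s} f(c,s,y)\, w(c,y), \qquad
w(c,y) = \frac{\#\,c\text{'s posts in } y}{\#\,\text{all posts in } y},$$

and the finance stage summarises decade growth ratios
$\mathrm{stock}_{2019}/\mathrm{stock}_{2009}$ of yearly average adjusted
closes by geometric mean and geometric standard error within stress types
and association-percentile bins.

## Numerical conventions

These choices were genuinely open; each is fixed for reproducibility and
exposed as an argument where a user might reasonably want the alternative.

- **Population standard deviation for z-scores.** The cohort moments are
  descriptive moments of the full scored cohort, not estimates from a
  sample of a larger population, so `zscore_companies()` divides by $n$.
  `sd_type = "sample"` gives the $n-1$ convention; only the scale of the
  z-scores (not sign, hence not type assignment) changes.
- **Half-open quadrants.** $z = 0$ counts as the nonnegative side, so
  assignment is deterministic everywhere including the origin, which maps
  to positive stress. For continuous scores the boundary has measure zero.
- **Origin convention.** At $R = 0$ the angles are 0/0-undefined and the
  point is the weakest possible association, so $f = 0$ there.
- **Per-year membership.** The yearly index recomputes stats, moments,
  types and $f$ within each year, so a company can change type across
  years; the weight denominator is *all* posts in the year, not the posts
  of the type's companies. Years with a degenerate axis (for instance no
  stress-matching post anywhere) are emitted as `NA` with a warning rather
  than silently dropped, so downstream plots show the gap.
- **Dispersion band.** The "spread" attached to $m(s,y)$ is the population
  standard deviation, across the type's member companies, of their
  contributions $f \cdot w$. The statistic's population was an open choice;
  contributions are the quantity actually summed, so their spread is what
  the band should show.
- **Matcher.** Case-insensitive, word-boundary-respecting phrase matching
  with longest-match overlap resolution (so "extreme stress" suppresses
  the embedded "stress" rather than double-counting it). The matcher finds
  exactly the surface forms in the lexicon — no stemming, no negation or
  figurative-use handling; lexicon files are plain text, one phrase per
  line, and user-extensible.
- **Keyword scores.** `ctfidf_scores()` uses the plain ratio form
  $(k_l/o_l)\cdot(p/\sum_j k_j)$ by default. Some class-based TF-IDF
  implementations damp the second factor with a logarithm; `log_idf =
  TRUE` provides $\log(1 + p/\sum_j k_j)$. Tokens are lowercase
  alphanumeric words, optionally with stop-word removal and adjacent-pair
  bigrams; the plain-ratio default keeps the worked examples exactly
  hand-checkable.
- **Keyword–quadrant association.** A keyword is *associated with* class
  $s$ when (a) it occurs in $s$, (b) a 2×2 chi-square of keyword presence
  against $s$-membership is significant, and (c) it shows no significant
  dependence on any other class *after removing $s$ from the corpus*.
  Condition (c) is evaluated on the reduced corpus because on the full
  corpus a class-concentrated keyword is mechanically dependent — by
  depletion — on every class, which would make the three-condition verdict
  unsatisfiable; a keyword absent from the reduced corpus is trivially
  independent of the remaining classes. No continuity correction and no
  multiple-testing adjustment are applied by default (`correct` and
  `p_adjust` switch both on); verdicts with any expected cell below 1 are
  flagged `unreliable`.
- **GSE conventions.** `geometric_standard_error()` uses natural
  logarithms and the population standard deviation, matching the GM/GSE
  formulas as commonly printed; with the sample convention values differ
  by $\sqrt{n/(n-1)}$.
- **Percentile bins.** "Percentiles" are equal-count (quantile) bins,
  deciles by default, with ties broken by company id so the cut is
  deterministic. The binning variable defaults to the association $f$ —
  the score that ranks companies *within* a type — with the raw
  `stress_score` available via `bin_on`. The per-type "overall" row is the
  pooled GM of all the type's companies, which equals the $N$-weighted
  geometric combination of the bin GMs, not their arithmetic mean.
- **No minimum-review filter by default.** `min_reviews` is available but
  0 by default; a cohort of thinly reviewed companies simply carries
  noisier stress scores.

## The synthetic cohort

`cohort_config()` plants four archetypes, one per stress type, each an
`archetype_spec()`:

| parameter | default | why |
|---|---|---|
| rating mean (stars) | 4.2 (low/positive stress) vs 2.8 (passive/negative) | well-separated satisfied vs unsatisfied employers on a 1–5 scale |
| rating sd (stars) | 0.8 | individual reviewers disagree by about one star |
| stress-post probability | 0.030 (negative/positive) vs 0.002 (low/passive) | a stressed workforce mentions conditions in a few percent of posts; the background is an order of magnitude lower |
| reviews per company-year (Poisson mean) | 68 | the scale of large-cap employers on major review platforms: a corpus of a few hundred thousand posts across ~500 companies and ~13 years averages to roughly this rate |
| growth log-mean | $\ln 5.07$ (positive), $\ln 3.42$ (passive), $\ln 3.84$ (others) | plants the decade-growth ordering of interest — positive stress highest, passive lowest — with the pooled GM of the three non-positive types at 3.70× |
| growth log-sd | 0.5 | realistic dispersion for decade-scale equity growth; keeps the growth distribution visibly log-normal and heavy-tailed on the ratio scale |

Review counts are Poisson per company-year (simplest count law with
testable variance), ratings are Normal rounded and clamped to 1–5, and
stress reviews embed exactly one lexicon phrase verbatim (possibly
capitalised) among neutral filler sentences, which makes the matcher's hit
condition unambiguous in tests. Ground-truth types live in a sidecar table
(`company_roster()`) that no pipeline stage reads.

What the generator does *not* emulate: realistic English prose, reviewer
identity or selection effects, inflected or misspelled condition mentions,
figurative stress talk, rating–text correlation within a review, company
entry/exit, and market co-movement in stock prices. Passing recovery tests
therefore show the pipeline's statistical machinery is correct under the
planted model, not that the lexicon matcher has high recall on real
reviews — on real text a closed 15-phrase lexicon is a lower bound on
stress detection.

## Problem sizes in the tests

Unit tests use cohorts of 8–20 companies over 2–5 years with 50–80 reviews
per company-year — large enough for non-degenerate z-scoring in every
simulated year, small enough to run in seconds. The end-to-end recovery
check uses the default 4 × 50-company cohort (~150k reviews), which
separates the archetypes far beyond the binomial noise of per-company
stress scores: recovery of planted types is essentially complete, and the
per-type pooled GM of growth lands within three geometric standard errors
of the planted value. Monte-Carlo assertions (binomial intervals, 3-GSE
bands, correlation floors) use fixed seeds; their tolerances come from the
sampling distributions involved, not from tuning.

## Limitations

- The lexicon matcher is a transparent stand-in for learned entity
  extraction; it cannot find conditions phrased outside the lexicon.
- Stress scores, types, and associations are descriptive; the package
  deliberately offers only correlation utilities against external yearly
  series (`overlay_external_series()`) and makes no causal claims — in
  particular, growth differences across stress types are associations, not
  effects of stress on performance.
- All stages assume reviews are honestly dated and attributed; no
  de-duplication or astroturf detection is included.
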