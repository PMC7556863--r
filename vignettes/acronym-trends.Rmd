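---
title: "Measuring acronym use in scientific titles and abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acronym use in scientific titles and abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrotrend)
```

## The problem

Acronyms, initialisms and capitalized abbreviations are pervasive in
biomedical writing, and most newly coined ones are never picked up by other
authors. Quantifying that — how densely acronyms occur in titles and
abstracts, how the density has changed over decades, and how quickly a
newly coined acronym is re-used within its journal — requires an objective,
reproducible definition of "acronym" and careful accounting at every
filtering step. `acrotrend` implements that measurement pipeline end to
end, together with a synthetic-corpus generator so every stage can be
validated against known ground truth.

## The detection rule

A token is an acronym when it has **at least 2 characters** and **at least
half of its characters are upper-case letters**. All characters of the
token count toward the denominator: digits (`BRCA1`: 4/5 upper → acronym;
`N95`: 1/3 → not) and internal punctuation (`B-AE-D`: 4/6 → acronym;
`YST-adjusted`: 3/12 → not). The rule is deliberately crude — it needs no
dictionary, no parenthetical definitions, and behaves identically across 70
years of text — and its error rates are quantified by audit (below) rather
than assumed away.

Decisions pinned here because the rule alone does not determine them:

* **Minimum length 2.** Single capitals are initials or variable names, not
  acronyms; analyses stratify lengths 2, 3, 4 and 5+. The minimum is a
  parameter (`min_length`) for sensitivity work.
* **Tokenization.** Tokens are maximal non-whitespace runs with enclosing
  punctuation stripped; hyphenated forms are one token (there is no
  defensible splitting rule, and splitting would inflate word counts).
  Possessive `'s` is stripped as grammatical. A run that is punctuation
  only does not count as a word.
* **Denominator.** Every character of the stripped token counts. The
  alternative — letters and digits only — is exposed as
  `denominator = "alphanumeric"` because tokens like `HC-MVECs` show the
  choice matters at the margin.
* **Unicode.** Letters outside A–Z classify by their Unicode case property
  (an upper-case Greek letter is upper case). Bibliographic text contains
  them, and ignoring them would misclassify whole tokens.
* **Case-sensitive surfaces.** `mRNA` and `MRNA` are distinct acronyms
  everywhere (rankings, spectra, re-use).

## Exclusion filters

Records pass through per-field filters before any statistic is computed:
missing publication date, non-English language (taken from metadata, never
re-detected from text), publication year before the start year (default
1950), no article type (titles only), absent abstract, empty text, one-word
text, and text with ≥ 60% of its words entirely in capitals (acronyms
cannot be distinguished there). Exactly one reason is recorded per
(record, field), evaluated in that fixed precedence order — metadata
problems before content problems — so tallies are reproducible and
`included + Σ excluded = total` holds exactly. The start year and the
capitals threshold are configuration values with those defaults.

## Trend statistics

The annual **density** series is the mean over papers of the per-paper
ratio (acronym tokens / words × 100), not the pooled token ratio: the
estimand is the average paper, and the 95% interval
(mean ± 1.96·sd/√n) then refers to the annual mean. The pooled variant
remains available (`pooled = TRUE`) for sensitivity. Strata by length
(2/3/4/5+) and kind (letters-only vs letters-and-numbers) use the same
word-count denominator, so strata sum exactly to the total. Years with no
eligible records are omitted rather than zero-filled; single-paper years
carry a degenerate, flagged interval.

Rankings count token occurrences (not per-paper presence), pool titles and
abstracts by default, and break ties by descending count then
lexicographically, so outputs are deterministic. The frequency spectrum
reports the share of unique surfaces occurring once, 2–10 times, and more
than 10,000 times, plus coverage of the 26³ = 17,576 possible three-letter
all-capital forms. The popularity sensitivity analysis masks the k most
frequent surfaces (they stay words, stop being acronyms) and recomputes the
series; masking can only lower densities, which the tests check pointwise.

## Time to re-use

The unit of analysis is the (acronym surface, journal) pair: first use is
the earliest paper in that journal containing the surface in title or
abstract (same-day ties broken by paper id), re-use is the next distinct
paper in the same journal, and times are days/365.25. Keeping the analysis
within journals standardises by field and reduces sense collisions (ED in
emergency medicine vs psychology). A global-first-use variant exists behind
`global_first = TRUE`. Records without an observed re-use are censored at
the journal's last observed issue date in the corpus — a coining on that
date is censored at time zero.

Survival is estimated by the Kaplan–Meier product limit (via
`survival::survfit`, Greenwood variance, complementary log-log intervals —
standard and stable near the tail, where the estimand lives). **t10** is
the smallest time at which estimated survival reaches 0.90, and its
confidence bounds come from intersecting the confidence envelope with
0.90. This convention is pinned explicitly because off-the-shelf quantile
extractors return nothing when the curve sits exactly at 0.90 — with one
event among ten records the curve steps to 0.90 exactly and t10 must be
that event time.

The one-year re-use fraction uses an observable denominator: records
censored before the window are excluded, because their status at the
window is unknown. Counting them as failures would bias the fraction
downward in journals that stopped publishing; the convention is a flagged
parameter of the analysis, not a hidden constant.

## Audit error bounds

Because the detector is crude, its error rates are estimated by hand checks
of random samples: excluded titles, titles/abstracts with no detected
acronym, and titles/abstracts with at least one. With `x` errors in `n`
checks the error rate gets a Beta(x+1, n−x+1) posterior (uniform prior) and
the reported upper limit is 100× its 95th percentile. The uniform prior keeps
the bound strictly above the observed average for upper-tail quantiles and
gives the closed form 100·(1 − (1 − q)^(1/(n+1))) at zero errors; the
quantile is cross-checked in the tests against a Monte-Carlo posterior
sample. Title categories may be pooled across two 300-item samples
(n = 600) while abstract categories stay unpooled (n = 300); both
conventions are supported. Sampling
(`sample_for_check`) is seeded and without replacement.

## The synthetic corpus

The generator emulates exactly the structure the statistics consume:

* **Density ramps.** Expected acronyms per 100 words rise linearly from
  0.7 to 2.4 in titles and 0.4 to 4.1 in abstracts across 1950–2019 —
  endpoints chosen to match the literature-wide trends the pipeline is
  designed to measure. Per paper, the acronym count is binomial over words
  with the year's probability, so the mean-of-ratios estimator is unbiased
  for the ramp value.
* **Word-count ramps.** Mean title length 9.0 → 14.6 words and abstract
  length 128 → 220, as 2 + Poisson(mean − 2) so no clean text is empty or
  one word and the mean is exact.
* **Vocabulary.** Acronym surfaces follow a Zipf rank-frequency law
  (default exponent 1.2 over 5,000 surfaces), shared across journals, with
  three-letter forms modal and a 15% letters-and-numbers share. Lengths 2–3
  are sampled without replacement from the enumerable space of forms (there
  are only 936 possible 2-character surfaces under this scheme, so the
  default length mix keeps the 2-character demand safely inside it);
  longer surfaces are drawn freely and deduplicated.
* **Contamination.** Non-English records, all-capital titles and missing
  abstracts are injected at configured rates, constructed to trigger
  exactly one exclusion reason each; realized counts are recorded in the
  ground truth so filter accounting can be checked for exact equality.
  Clean texts are constrained below the 60% capitals threshold (a
  truncation with negligible probability mass at the default densities) so
  they can never trip a filter by chance.
* **What it does not model.** Real syntax, parenthetical definitions,
  acronym sense ambiguity, within-year seasonality, or journal growth.
  Passing recovery tests therefore demonstrates that the estimators are
  correct for data with the assumed statistical structure, not that the
  detector's linguistic error rates are negligible on real text — that is
  what the audit machinery is for.

Filler words come from a fixed 40-word lowercase lexicon; content is
irrelevant to every statistic computed. Dates are uniform within years and
journals uniform across papers, as none of the statistics use within-year
structure.

## Validation strategy and problem sizes

The test suite checks the detector exhaustively against a brute-force
character-counting oracle over all tokens of length ≤ 4 on a four-symbol
alphabet; the Kaplan–Meier implementation against a hand-rolled
product-limit computation on dozens of small random instances; the
Beta-posterior quantile against a 10⁶-draw Monte-Carlo posterior sample;
and end-to-end ramp recovery on a corpus of 5,000 papers per year for
1950–2019 (350,000 records, ~60 million abstract tokens), asserting the
recovered endpoints and fitted slopes fall within three standard errors of
the generator's truth. Re-use t10 recovery uses cohorts of 500 with the
closed-form exponential quantile −ln(0.9)/λ as oracle. One detector
invariant deserves a note: appending a lower-case letter can never turn a
token of length ≥ 2 into an acronym (it only dilutes the ratio), but a
single capital is a genuine exception — `A` is below the minimum length
while `Aa` is exactly half upper case — so the property is stated from
length 2.

## Known limitations

The detector misses acronyms dominated by lower-case letters (`circRNA`)
and wrongly includes words capitalized for emphasis; the audit bounds
quantify, not remove, those errors. Only titles and abstracts are analysed,
not full text. The re-use analysis does not disambiguate senses beyond the
journal constraint, and "last issue" is the last issue observed in the
corpus snapshot, which censors journals that merely paused. Trend series
are descriptive annual means; no model is fitted beyond the least-squares
slope used in recovery checks.
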