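---
title: "Methods: exact conditional placement of an answer profile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact conditional placement of an answer profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poibench)
```

## The model and its assumptions

A battery is `n` items with normative solution rates `p_1, ..., p_n`: the
probability that a random subject from the reference population answers
item `j` correctly. The whole analysis rests on two assumptions:

* **Independence across items.** A subject's answers are independent
  Bernoulli draws, `B_j ~ Bernoulli(p_j)`. Everything downstream — the
  product formula for a profile's occurrence probability, the
  Poisson-binomial score distribution, the conditional multiset — is exact
  *given* this assumption and meaningless without it. Real item responses
  are usually positively correlated through subject ability; see
  "Limitations" below.
* **Rates are known constants.** The `p_j` are treated as population
  parameters, not estimates. The built-in battery's rates come from a
  20-subject sample, so each carries sampling error of order 0.1 that the
  analysis deliberately ignores (benchmarking against the *recorded* norms
  is the point). Several built-in rates (e.g. 21.1%, 55.6%) are impossible
  for a uniform denominator of 20, implying non-uniform per-item
  denominators in the source; rates are therefore stored verbatim at
  printed precision and never re-derived from counts.

Under the model, three exact quantities characterize a profile `b` with
score `k`:

* `p(b) = prod_j p_j^{b_j} (1-p_j)^{1-b_j}` — its occurrence probability;
* `P(K = k) = sum over |A| = k of p(1_A)` — the Poisson-binomial PMF;
* the conditional multiset `{ p(1_A) : |A| = k }` of all `C(n, k)`
  same-score combinations, within which the profile is placed.

## Conventions that the printed reference values pin down

The placement statistics admit several textbook conventions; the package
fixes one of each, chosen (once, up front) because it reproduces the
reference values shipped with the built-in fixtures, and records the choice
in every report's provenance block:

* **Percentile rank** is *strict-less*: `100 × #{i : p_i < p(b)} / m`,
  with relative tolerance 1e-9 treating near-equal values as ties. On an
  exchangeable battery (all rates equal) every profile therefore has rank
  0, a deterministic and honest degenerate answer. Mid-rank tie handling
  was rejected: it turns exact ties into seed-dependent-looking halves.
* **Top-q threshold** is the nearest-rank upper quantile: the value at
  ascending rank `ceiling((1-q) m)`. No interpolation — every threshold is
  an actually attained combination probability.
* **Membership** above the threshold is non-strict (`>=`), so an all-tied
  distribution places every profile in the top q at any q. For the
  built-in practice set (profile probability 1.518e-4 vs threshold
  1.503e-4) either convention gives the same answer; non-strict is the
  conservative fixed choice.
* **Mode ties** break toward the smallest score and set a `tied` flag
  (tolerance 1e-12). The built-in batteries have unique modes; the flag
  exists so exchangeable batteries cannot silently pretend they do too.
* **Quantile summaries** use midpoint interpolation (`h = qn + 0.5`,
  R's type 5); it is the estimator under which the built-in rate vectors
  reproduce their recorded medians and IQRs — 0.55 (0.23–0.64) and
  0.35 (0.30–0.40) — where the more common types 6/7 do not.
* **Fisher's exact test** is two-sided by the probability-mass method
  (summing all margin-preserving tables no more likely than the observed
  one, relative tolerance 1e-7 on the comparison), the dominant convention
  and the one matching `stats::fisher.test`.
* **Wilcoxon rank-sum** uses midranks, the tie-corrected variance, no
  continuity correction, and a normal two-sided p. On the built-in rate
  vectors this gives z = 1.559; the fixtures' source reports two
  conflicting values (1.29 and 1.53) for the same comparison, so the
  package records z at full precision and the tests assert only
  non-significance.

## Numerical choices

* Profile probabilities are accumulated as sums of logs and exponentiated
  at the boundary, so behavior is uniform from 0.25 down to the 7.6e-9
  scale of the pooled analysis and far beyond. Rates exactly 0 or 1
  produce `-Inf` log terms and hence exact-zero probabilities; such
  combinations are still enumerated and participate in percentile counts.
* Score PMFs use plain double arithmetic. For `n = 30` the smallest PMF
  entries are ~1e-10 and the convolution is numerically benign
  (nonnegative terms only, no cancellation); tests hold it to the 2^n
  enumeration oracle at 1e-12 absolute.
* Combination counts come from `exact_choose()`, Pascal's rule carried in
  doubles, exact below 2^53; the enumerated vector length is checked
  against it, so a silent miscount is structurally impossible.
* The concatenation identity `p(b_pooled) = p(b_practice) p(b_transfer)`
  is exact mathematically but incurs ~1.5e-15 relative error from log-sum
  reordering (30-term vs 15+15-term accumulation); tests assert 4e-15.
* Meet-in-the-middle enumeration splits the battery at `ceiling(n/2)`,
  builds each half's 2^(n/2) subset products grouped by sub-score, and
  pairs all `(k1, k - k1)` lists through chunked outer products
  (`chunk_size` elements per temporary, default 5e6 ≈ 40 MB). For the
  pooled battery (`C(30,12) = 86,493,225`) the materialized multiset is
  ~0.7 GB and the whole placement runs in tens of seconds; the threshold
  is extracted by partial sorting, never a full sort.
* `placement()` auto-selects direct enumeration for `m <= 1e5` and
  meet-in-the-middle above; the two paths are proven equal (sorted
  multisets, 1e-12) on randomized batteries up to n = 16.

## The synthetic-cohort generator

`simulate_cohort()` draws the exact model the analysis assumes: an
`n_subjects × n_items` matrix of independent Bernoulli(p_j) bits.
`generate_battery()` draws rates i.i.d. uniform(lo, hi), Beta(α, β), or
fixed; the defaults (uniform on (0.1, 0.9), Beta(2, 2)) bracket the
built-in batteries' observed rate range (0.10–0.75) and central tendency.
A cohort of 2e5 subjects — ten thousand times the 20-subject normative
sample — makes the Monte-Carlo total-variation check against the analytic
PMF sharp (< 0.01) while keeping the suite fast. One root seed drives
everything through `derive_seed(seed, salt)` (salt 1 = battery, 2 =
cohort, 3 = validation), so any reported run is reproducible end to end;
stochastic tests use fixed seeds chosen with 3–4 SE margin and no retry
logic.

What the generator deliberately does **not** model: subject ability
heterogeneity (a 2-parameter IRT world where answers correlate through
ability), learning between sets, or item-order effects. A green Monte-Carlo
suite therefore establishes that the analytic machinery is correct *under
the independence model* — not that the model describes any particular human
cohort. Under ability heterogeneity the true score distribution is
overdispersed relative to the Poisson binomial, and conditional placements
would overstate how "atypical" a consistent-ability profile is.

## Degenerate inputs and edge policies

* `k = 0` or `k = n`: one combination; its probability is the whole
  conditional distribution, percentile 0, always in the top q.
* Exchangeable batteries: all `C(n,k)` probabilities tie; rank 0,
  threshold = the common value, every profile in the top q.
* Direct enumeration refuses above its cap (default 1e7 combinations) and
  names the meet-in-the-middle alternative; the brute-force score PMF
  refuses above n = 20 and names the convolution. The figure-4-style
  combination-matrix export refuses for the pooled set (86.5M rows) rather
  than materializing it.
* Empty batteries, mismatched profile lengths, rates outside [0, 1],
  duplicate item ids, and malformed CSV columns all fail fast with the
  offending row or column named, before any computation.

## Known limitations

* Reference values printed at 3 significant figures constrain but do not
  uniquely determine upstream conventions; two of the fixtures' recorded
  values (the pooled profile probability and pooled threshold) differ from
  the recomputed ones in the last printed digit (7.60e-9 vs 7.61e-9,
  7.357e-9 vs 7.35e-9), consistent with last-digit rounding in the source;
  the acceptance tests assert 0.2% relative agreement there and exact
  3-s.f. agreement everywhere else, and the transfer profile's percentile
  rank computes to 26.1 against a "near 27" reference.
* Memory, not time, bounds the meet-in-the-middle path: the conditional
  multiset is materialized (~8 bytes per combination). Around 1e9
  combinations a streamed two-pass (count, then select) variant would be
  needed; it is not implemented.
* The classical tests are the fixed conventions above, not a general
  toolbox: no exact (permutation) Wilcoxon p, no k×m contingency tables.
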