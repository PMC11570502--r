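---
title: "Methods: combinatorial analysis of Olive colobus call sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial analysis of Olive colobus call sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

The Olive colobus monkey (*Procolobus verus*) has a repertoire of only two
call types — a short, low-frequency "A" call (about 1.0 kHz, 0.12 s) and a
long, high-frequency "B" call (about 7.7 kHz, 0.58 s) — yet produces them in
structured sequences whose composition depends on the eliciting danger
(leopard, crowned eagle, falling tree). `callgram` implements the complete
analysis chain for such corpora: recovering the call types from acoustic
measurements, segmenting call trains into sequences, extracting the
combinatorial rules, and testing context specificity with mixed count
models. Because the raw field recordings are not required for any of this
machinery, the package ships a calibrated synthetic corpus generator so
every stage is testable end to end.

## The synthetic corpus generator

`generator_config()` encodes the study conditions as defaults:

* **Acoustic features.** Per-type normal distributions for duration and
  maximum frequency (A: 1.00 ± 0.16 kHz, 0.12 ± 0.12 s; B: 7.72 ± 1.73 kHz,
  0.58 ± 0.28 s), truncated at ±3 SD and floored at 0.01 s. Truncation makes
  the two frequency supports disjoint (A ≤ 1.48 kHz, B ≥ 2.53 kHz) and
  avoids negative durations. The floor (10 ms) is on the order of the
  shortest resolvable call at the 2 ms spectrogram hop used for the original
  measurements.
* **Inter-call intervals.** Log-normal distributions parameterised by
  moment matching so the *arithmetic* mean/SD equal the published values:
  within-sequence 0.12 ± 0.14 s (truncated above at 1 s), between-sequence
  22.8 ± 21.3 s (truncated below at 2 s). A log-scale model is the natural
  choice here: the interval histogram is displayed and clustered on a log
  axis downstream.
* **Sequence patterns.** Each responding trial draws its sequence patterns
  from a per-stimulus probability vector over the four classes
  (A-repetition, BA, A+BA, BA+A). The defaults are calibrated from the
  published per-context percentages (leopard → BA 0.72, eagle → A+BA 0.36,
  tree → BA+A 0.60) with the remaining mass allocated to respect the
  published initiation shares (e.g. ~85% A-initiation to eagles, ~90%
  B-initiation to leopards) and spread uniformly where nothing is printed.
  These remainders are conventions, clearly overridable in the config.
* **Counts.** The number of gram repetitions per segment is 1 + Geom(0.54)
  (A-repetitions: 2 + Geom, so every sequence has at least two calls); the
  geometric law is a convention — only the mean sequence length (≈ 4.2
  calls) is published — and p = 0.54 reproduces it. Sequences per responding
  trial are 1 + Pois(1.4), matching the observed ≈ 2.4 sequences per
  responding trial. Response probabilities per stimulus are the published
  response rates (leopard 61.4%, eagle 36.7%, tree 50.6%, chimpanzee 0%).
* **One caller per trial**, a 160 s analysis window, and a single integer
  seed through which all randomness flows.

What the generator does **not** emulate: acoustic gradation within call
types, multi-caller overlap, autocorrelation of patterns within a trial, and
any non-Gaussian shape of the real feature distributions. Consequences are
noted below where they matter.

## Call-type recovery

Calls are clustered on z-scored (duration, maximum frequency) with
Partitioning Around Medoids — the classic deterministic BUILD + SWAP
algorithm on Euclidean dissimilarities, with the first best exchange in scan
order on ties — and the number of clusters is chosen by the largest mean
silhouette width over k = 2..10 (ties toward the smaller k). Silhouette is
undefined at k = 1, so the candidate range starts at 2; a one-cluster
solution would in any case never attain the silhouette maximum here.
Z-scoring is our choice (the scales, seconds and kHz, are incommensurate)
and can be disabled.

A caveat that matters for interpretation: with *Gaussian* feature
distributions at the configured moments, the duration distributions of the
two types overlap (B: 0.58 ± 0.28 s can undercut A's range), so a small
fraction (~1%) of short-duration B calls sits nearer the A medoid in the
standardized plane. Synthetic recovery is therefore ≈ 99%, not exactly
100%: perfect classification of the field data tells us the real features
are better separated than independent Gaussians with these moments. The
tests assert near-perfect recovery, not perfection.

## Sequence segmentation

Inter-call intervals are silent gaps (next onset minus previous offset),
floored at 0.1 ms, never spanning trials. A K-component unequal-variance
Gaussian mixture is fitted to the natural-log intervals by EM (best of 10
deterministic quantile-spread initializations; convergence when the
log-likelihood gain drops below 1e-8, iteration cap 1000, SD floor 1e-4
log-s; the log-likelihood is asserted monotone at every step). The number
of modes is selected by sequential parametric-bootstrap likelihood-ratio
tests (K vs K+1 from K = 1, stop at the first non-rejection at α = 0.05);
the bootstrap p-value uses the add-one convention so it is never exactly
zero, and bootstrap refits run at a looser tolerance (1e-6, 300 iterations)
than the observed-data fits — ample for the test statistic. On corpora with
the configured interval structure this selects two modes, with the
posterior-0.5 boundary between 1 and 2 s.

Sequences are then maximal runs of calls separated by gaps *strictly* below
the 1 s bout criterion; a run of one call is a singleton, excluded from
grammar analysis but counted. The fixed 1 s threshold is the operative
definition; `threshold_s = "auto"` in the pipeline uses the data-derived
mixture boundary instead.

## Grammar

Patterns are full-string regex classes — `A{2,}`, `(BA)+`, `A+(BA)+`,
`(BA)+A+`, else *other* — which are mutually exclusive and exhaustive over
strings of length ≥ 2. The three combinatorial rules are evaluated per
sequence:

1. **A-Dominance** — the number of B calls never exceeds the number of A
   calls (#A ≥ #B). We use the non-strict inequality: the strict variant
   (2·#A > n) would fail every balanced even-length sequence, including the
   modal sequence "BA" itself.
2. **A-Suffixation** — the final call is an A.
3. **B-Singularity** — no B is immediately followed by a B.

A small observation falls out of the non-strict reading: rules 2 and 3
*imply* rule 1 (if no B is followed by a B and the last call is an A, every
B has an A successor of its own, so #A ≥ #B). The three rules are stated
separately for descriptive clarity, but dominance cannot be violated alone
— which is why the negative-control injector `inject_rule_violations()`
necessarily co-violates B-Singularity when asked to break dominance.

The trie is a prefix tree with per-node pass counts and terminal counts
(sequences ending exactly there); the conservation law *terminal + Σ child
passes = pass* holds at every node and is property-tested. Note that
distinct sequence *types* correspond to nodes with a terminal mark, not to
leaves: a type that is a proper prefix of another (e.g. "BA" beside "BAA")
ends at an internal node.

"Sequence type" (exact string identity, for the distinct/singleton counts)
and "pattern" (regex class) are deliberately kept as two different
summaries in `repertoire_summary()` — both senses are needed.

## Context-specificity models

For each sequence feature (initiation call, pattern, terminal bigram) the
per-trial count table has one row per feature level with an exposure offset
log(N_total_sequences + 1), and the model is a Poisson random-intercept
GLMM:

count ~ level * stimulus + group_location + offset + (1 | trial)

fitted by Laplace-approximate maximum likelihood. The random-intercept
modes are profiled out by a damped Newton solve — one-dimensional and
convex per trial, vectorized across trials — and the outer quasi-Newton
optimization runs on the fixed effects and log SD with an analytic
gradient that includes the dependence of the modes and of the Laplace
log-determinant on the parameters. One quadrature point (Laplace) matches
the standard default for Poisson mixed models; the fit agrees with
`lme4::glmer` to ~1e-4 on coefficients, SEs and log-likelihood in the
cross-check tests.

Design choices:

* **Poisson, not Conway–Maxwell–Poisson.** Mild underdispersion in count
  data of this kind motivates CMP elsewhere; its normalizing constant adds
  substantial cost without changing the estimands exercised here. We keep
  Poisson and guard validity with `dispersion_check()`, a simulation-based
  two-sided test of the Pearson-residual SD.
* **Separation.** Context specificity this strong produces cells with all
  zeros, sending ML estimates to infinity. `ridge_sd = 1` imposes
  independent zero-mean Gaussian priors (penalized likelihood) on the fixed
  effects; the intercept is unpenalized by default (`ridge_all = TRUE`
  penalizes it too). A ridge SD of 1e6 reproduces the unpenalized fit to
  1e-4, and the fit reduces to an ordinary Poisson GLM when the
  random-intercept SD is pinned near zero (`sd_fixed`).
* **Inference.** Full-vs-null and per-term LRTs (`drop1_interactions()`
  respects marginality and refits without non-significant interactions
  before testing main effects); Tukey-style pairwise contrasts of
  estimated marginal means with a single-step multivariate-normal
  adjustment (the exact studentized range is undefined for GLMM contrasts;
  Holm is the fallback); parametric-bootstrap percentile CIs (new random
  intercepts + Poisson noise, failed refits dropped and counted, more than
  20% is an error); and leave-one-trial-out stability (min/max estimate per
  coefficient). α = 0.05 throughout.
* **Offset.** Whether the exposure total should count unclassified
  sequences is ambiguous; we include all sequences in the window by default
  (`offset_all = FALSE` restricts to classified ones).

## Problem sizes and reproducibility

The test suite and the analysis scripts run everything at the study's own
scale: 1,246 calls (921 A + 325 B) for clustering, N = 1,119 intervals
(918 within + 201 between, the composition implied by the published call
and sequence totals) for the mixture, and ~100–200 trials for the count
models. Bootstrap LRTs in the scripted runs use 199 iterations and
bootstrap CIs 199 refits (a smoke profile of the 1,000-iteration
convention); calibration studies in the tests use 200 replicates (coverage)
and 500 replicates (test size). At N = 1,119 the sampling error of the
recovered between-sequence component mean is ≈ 1.8 s, so single-seed
estimates scatter visibly around 22.8 s — a property of the study size, not
of the estimator.

All stochastic stages consume a single integer seed; `run_pipeline()`
writes a manifest with the seed, the configuration and per-file checksums,
and reruns with the same configuration are bit-identical for the
deterministic stages.

## Known limitations

* The generator's independent-Gaussian features understate the separation
  of the real call types (see above); conversely its grammar is exact, so
  rule checks on synthetic corpora are clean by construction and say
  nothing about how noisy field annotations would behave.
* The mixture assumes log-normal interval components; heavy-tailed
  between-sequence gaps would bias the upper component's back-transformed
  mean.
* The GLMM uses a single Laplace quadrature point; for very small counts
  per trial, adaptive quadrature would be more accurate.
* Patterns within a trial are drawn independently; real callers are more
  repetitive (unique sequence types in ~72% of trials), so the synthetic
  random-intercept variance is conservative.
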