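# callgram

Combinatorial analysis of Olive colobus (*Procolobus verus*) alarm-call
sequences. This species has one of the smallest vocal repertoires among
primates — a short, low-frequency **A** call (≈ 1.0 kHz, 0.12 s) and a long,
high-frequency **B** call (≈ 7.7 kHz, 0.58 s) — yet it almost never calls in
isolation: responses to danger are loud, structured sequences whose
composition tracks the eliciting event. `callgram` is for bioacousticians
and students of animal communication who want to reproduce, probe, or
extend this style of call-sequence analysis without needing the original
field recordings.

The package implements the full chain as tested R functions, plus a
calibrated synthetic corpus generator so every stage runs end to end:

1. **Call types** — Partitioning Around Medoids (deterministic BUILD+SWAP)
   on z-scored (duration, max frequency), cluster count chosen by mean
   silhouette over k = 2..10.
2. **Sequence segmentation** — K-component Gaussian mixture on log
   inter-call intervals (EM), number of modes by sequential
   parametric-bootstrap likelihood-ratio tests, then the 1 s bout
   criterion: a sequence is ≥ 2 calls separated by gaps < 1 s.
3. **Grammar** — pattern classes `A{2,}`, `(BA)+`, `A+(BA)+`, `(BA)+A+`;
   the three combinatorial rules (A-Dominance: #A ≥ #B; A-Suffixation:
   sequences end in A; B-Singularity: no "BB"); prefix trie with terminal
   counts; repertoire summaries.
4. **Context specificity** — per-trial count tables with exposure offset
   log(N_sequences + 1) and Poisson random-intercept GLMMs
   (Laplace approximation, analytic gradient, optional Gaussian ridge on
   the fixed effects against complete separation), with LRTs, drop-one
   tests, Tukey-style marginal-means contrasts, parametric-bootstrap CIs,
   leave-one-trial-out stability and a simulation-based dispersion check.

## Worked example

```r
library(callgram)

cfg  <- generator_config(seed = 7)            # study-calibrated defaults
corp <- generate_corpus(cfg)                  # 201 trials, one caller each

feats <- standardize_features(corp$calls)
sel   <- select_k(feats$x, 2:10)
sel$best_k
#> [1] 2
calls <- label_clusters(sel$fits$k2, corp$calls)

iv  <- compute_intervals(calls)
fit <- fit_log_mixture(iv$interval, K = 2)
fit
#> Log-interval Gaussian mixture, K = 2
#>      weight     mean_s  mean_log    sd_log
#> 1 0.8526673  0.1229021 -2.536013 0.9377061
#> 2 0.1473327 23.6786764  2.863860 0.7755185
#> within/between boundary: 1.88 s

seg <- segment_sequences(calls, threshold_s = 1)
repertoire_summary(seg$sequences$symbols)
#> 208 sequences, 41 distinct types (19 singletons)
#> length 4.3 +/- 2.6 calls (max 17)
#> mixed 71.2% | A-repetition 28.8% | B-repetition 0.0%
#> four basic patterns 98.1% (4 unclassified)
```

The mixture's two components sit at ≈ 0.12 s (within-sequence gaps) and
≈ 24 s (between-sequence gaps) with the decision boundary between 1 and
2 s — which is what licenses the 1 s bout criterion. The repertoire shows
the grammar at work: no sequence ever repeats a B call, and the handful of
"unclassified" sequences are the footprint of the ~1% of calls the
clustering mislabels.

The scripted analysis in `analysis/01_simulate.R` …
`analysis/05_context_models.R` runs the same chain as a narrative workflow,
writing its tables under `results/` (corpus, silhouette curve, interval
mixture, annotated sequences, trie in DOT, count tables and model
summaries). Run them in order from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_types.R
...
```

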