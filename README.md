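# harmbind

Analysis toolkit for **coincidence-dependent integration of harmonic
sounds in auditory cortex**. Natural vocalizations are stacks of
harmonics — integer multiples of a fundamental frequency (F0) — and the
brain binds those components into one sound object only when their onsets
coincide within a few tens of milliseconds. harmbind implements, as
tested reusable R functions, the full computational chain used to study
this: harmonic/onset-shifted/jittered stimulus construction, F0
extraction from vocal audio by harmonic template matching, two-photon
calcium-imaging response statistics, population ensemble geometry and
clustering, noise-correlation subnetwork detection, spike-train and
optogenetic-suppression kinetics, and behavioral psychometrics — plus
ground-truthed synthetic generators for every stage.

## The statistics at the core

* **Harmonic template matching.** For observed component frequencies
  `F_i` with harmonic orders `k_i = max(1, round(F_i/F0))`, the
  evaluation function
  `EF(F0) = sqrt(mean(((k_i·F0 − F_i)/F_i)^2))`
  is minimized over an F0 grid; segments with `EF < 0.5` are judged
  harmonic. Ties across subharmonics break toward the largest F0.
* **Coincidence-preference index.** `CI = (C − S)/(C + S)` between
  responses to coincident (`C`) and onset-shifted (`S`) harmonics,
  negative amplitudes clipped to 0; `CI ∈ [−1, 1]`, +1 = responds only to
  coincident sounds.
* **Linearity index.** `LI = (H − S)/(H + S)` between the multi-tone
  response `H` and the linear sum `S` of component-tone responses;
  0 = linear, negative = sublinear summation.
* **Ensemble clustering.** Non-negative matrix factorization (k = 3, 100
  restarts) of normalized Δonset response profiles into negative-shift,
  positive-shift and coincidence-preferring clusters; dominant
  coefficient fraction < 0.5 ⇒ "others".
* **Noise correlation.** Pearson correlation of per-stimulus
  mean-subtracted trial amplitudes, concatenated across stimuli, with
  distance-, SD- and SNR-matched control pairs.
* **Psychometrics.** Logistic fits of lick rate on the log-modulus scale
  `x = sign(Δ)·log10(1 + |Δ|)`; behavioral threshold = half-max Δonset;
  `d′ = z(hit) − z(fa)`.

## Worked example

```r
library(harmbind)

## 1. vocal F0 extraction on synthetic audio with known F0s
audio    <- generate_vocal_audio(f0s = c(3000, 3200, 2500), snr_db = 20, seed = 7)
segments <- analyze_vocalization(audio)
summary  <- f0_usage_summary(segments)
cat(sprintf("harmonic segments: %d | median F0: %.2f kHz | central 80%%: %.2f-%.2f kHz\n",
            summary$n, summary$median / 1000, summary$q10 / 1000, summary$q90 / 1000))
#> harmonic segments: 122 | median F0: 3.00 kHz | central 80%: 2.50-3.20 kHz

## 2. coincidence preference in a synthetic imaging population
cfg <- population_config(
  n_cells = c(coincidence = 6, negative_shift = 6, positive_shift = 6,
              nonresponsive = 6),
  f0s = c(2800, 5700), seed = 42)
pop <- generate_population(cfg)
rt  <- response_table(pop$session)     # neuropil correction, dF/F, AUC, significance
ci  <- coincidence_indices(rt)         # CI pooled over +/-15 and 30 ms shifts
round(tapply(ci$ci, pop$truth$cells$archetype[ci$roi], mean), 3)
#>    coincidence negative_shift  nonresponsive positive_shift
#>          0.609          0.109          0.255          0.186

## 3. NMF clustering of onset-shift response profiles (one F0)
stim <- rt$stim_table
pm   <- build_population_matrix(rt$amplitude[, stim$f0 == 2800],
                                rt$significant[, stim$f0 == 2800])
cl   <- nmf_cluster_assign(pm$matrix, seq(-45, 45, by = 15), seed = 1)
table(cl$cluster)
#> negative_shift positive_shift    coincidence         others
#>             11              7              7              0
```

The three planted syllables are detected and every 1.4 ms segment is
matched to its true F0 (median 3.0 kHz). Planted coincidence cells show a
strongly positive mean CI (0.61) while shift-preferring cells sit near
zero, and the cluster assignment separates the three planted archetypes
(extra cluster members are nonresponsive cells whose noise crossed the
significance rule — the matrix includes every pair the pipeline itself
deems responsive, not the ground truth).

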