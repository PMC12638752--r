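---
title: "Microstate analysis of rodent EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of rodent EEG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratstates)
```

## The model

EEG microstates are brief (tens to hundreds of milliseconds) epochs during
which the multichannel voltage topography stays quasi-stable before
switching abruptly to a new configuration. `ratstates` implements the
classical analysis chain for such data, aimed at rodent recordings made
with a 10-20-homologous cortical montage:

1. **Preprocessing** — common average reference; zero-phase (two-way) FIR
   band-pass, default 1–40 Hz with 2000 taps; extraction of
   behavioural-inactivity segments of at least 2 s, concatenated and
   treated as one continuous series.
2. **Global field power (GFP)** — the population standard deviation of the
   topography at each sample. GFP peaks are moments of maximal
   signal-to-noise, and only peak topographies enter clustering.
3. **AAHC clustering** — atomize-and-agglomerate hierarchical clustering:
   every peak map starts as its own cluster; the cluster contributing
   least global explained variance is repeatedly dissolved and its members
   reassigned by absolute spatial correlation. One model is kept per
   candidate K. Polarity is ignored throughout: a map and its negation are
   the same microstate, and cluster templates are the first principal
   spatial component of their members.
4. **Backfitting** — every sample (not only peaks) is labelled with the
   template of highest `|r|`; zero-GFP samples stay unassigned.
5. **Parameters** — per class: mean GFP, mean duration (halfway-boundary
   convention), occurrence rate, coverage, and GEV
   (`GEV_k = Σ GFP_i² C_ik² δ(L_i = k) / Σ GFP_i²`); plus observed and
   occurrence-expected transition matrices.
6. **Validation** — per-channel temporal shuffling (one random cut, blocks
   swapped) destroys instantaneous topography while preserving each
   channel's sample multiset; real recordings must out-explain their
   surrogates.
7. **Source association** — per source and frequency band, the
   band-limited power envelope (order-3 two-pass Butterworth + Hilbert
   magnitude) is regressed on the microstate regressor
   `B_k(t) = |x_t · map_k|` with GFP and global map dissimilarity (GMD) as
   nuisance terms; group inference on `β₁` uses sign-flip permutations
   with TFCE correction over the source neighbourhood graph.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| band-pass | 1–40 | Hz | broadband microstate convention |
| FIR taps | 2000 | — | long filter for a sharp 1 Hz edge at 250 Hz |
| minimum segment | 2 | s | shorter inactivity epochs are discarded |
| K range | 2–10 (1–10 when dispersion feeds KL) | classes | candidate model sizes |
| GEV evaluation | GFP peaks | — | peaks carry the topographic signal; `on = "all"` available |
| surrogate repeats | 10 | — | per-recording surrogate sample |
| MAD screen | 3 × scaled MAD | — | robust outlier rule, scale 1.4826 |
| bands | δ 2–4, θ 4–8, α 8–12, β 12–20, broadband | Hz | human-convention bands applied homologously |
| TFCE | E = 0.5, H = 2, 100 steps | — | standard enhancement exponents |
| permutation test | α = 0.001 two-sided, 1000 flips | — | production default; seeded |

## The synthetic-data generator

Real rodent recordings of this kind are not publicly distributable, so the
package ships a generator that emulates their structure with known ground
truth: K unit-norm zero-mean template maps (orthogonalized by default,
with a controllable mutual correlation, since empirical microstate maps
are inter-correlated); a semi-Markov label sequence with gamma dwell times
(shape 2, mean 0.1 s — strictly positive and unimodal; the literature
reports only mean dwell times, so the family is a modelling choice); a
rectified 10 Hz amplitude envelope with slow modulation, guaranteeing the
dense GFP peaks the clustering stage needs; and i.i.d. sensor noise
re-centred per sample, parameterised by SNR. Default study conditions:
19 channels, 250 Hz, 5 states, SNR 5.

What the generator does **not** emulate: 1/f background spectra, volume
conduction, artifacts, non-stationarity across a session, or
inter-subject topographic variability. Passing tests therefore demonstrate
the correctness and sensitivity of the machinery under controlled
conditions, not the empirical claims one could only make on real data.

Toy source scenes place sources on a grid with 4-neighbour adjacency;
each source carries band-limited noise whose amplitude is modulated by
`1 + c · r(t)` with `r` the (rescaled) microstate regressor, so the
planted coupling `c` is recoverable through the BLP linear model. The
electromagnetic forward/inverse problem is out of scope by design; the
module consumes source series from any origin.

## Numerical choices and degenerate inputs

* **GFP** uses the population standard deviation (the channel set is the
  whole population).
* **Peak plateaus**: the first sample of a maximal plateau is the peak —
  deterministic and order-stable.
* **Backfit ties** break to the lowest class index; zero-GFP samples are
  unassigned and excluded from every denominator, which keeps
  `Σ coverage = 1` exact.
* **Durations**: a run of L samples spans L/fs seconds under the
  halfway-boundary convention (edge runs are measured from the recording
  edge). Durations are reported in both seconds and milliseconds.
* **No temporal smoothing** or minimum-duration rejection is applied to
  label sequences; the backfitted durations are therefore shorter than
  the planted dwell times whenever noise splits a dwell at low-GFP
  troughs — visible in the worked example, where planted 100 ms dwells
  backfit to ≈ 18 ms runs. This mirrors the tension between duration
  conventions in the rodent literature; both units are emitted so the
  reader can compare either way.
* **Expected transitions**: the occurrence-based formula
  `ExpTM(k1,k2) = (Occ(k1)/MeanOcc · Occ(k2)/MeanOcc)/(1 − Occ(k1)/MeanOcc)`
  is kept verbatim in `expected`. It is singular at `Occ = MeanOcc`
  (returned as `+Inf` with a warning, never silently patched) and turns
  negative for classes occurring more often than average; the
  `difference` matrix therefore uses the row-normalized variant, under
  which a uniformly negative row becomes a proper probability row.
* **CV criterion** is undefined for `K ≥ C−1` (its penalty blows up) and
  refuses such K.
* **KL criterion** uses `m =` channel count as the feature dimension and
  excludes the endpoints of the K range by construction.
* **Metacriterion** is a lower-median vote (ties to smaller K); the exact
  composition used in published supplements varies, so the voting set is
  configurable and KL alone is the preferred single criterion.
* **Surrogate policy**: the single-cut rotation is the most literal
  reading of "beginnings and ends of each electrode time series were
  swapped"; a multi-cut permutation is available behind
  `method = "multicut"`. Surrogate models are refitted per surrogate by
  default (`refit = FALSE` backfits the real model instead).
* **Envelope edges**: band-pass filtering and the Hilbert transform deform
  the first and last seconds of a BLP envelope, and because a group shares
  one regressor set this deformation is subject-consistent — in the lowest
  bands it can turn into a spurious whole-map group effect.
  `fit_source_glm(trim_s = …)` drops the transient; the drivers use 2 s.
* **TFCE** integrates with a midpoint rule over `n_steps` thresholds;
  two-sided maps are enhanced separately per sign. Enhancement parameters
  are standard but not dictated by the analysis itself — they are
  prominent arguments, not buried constants.
* **Permutation p-values** are computed as `(1 + #{null ≥ obs})/(B + 1)`,
  so the smallest attainable p is `1/(B+1)`; at α = 0.001 at least 999
  flips are required. Sign-flip tests need ≥ 6 subjects and refuse fewer.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at deliberately modest sizes
chosen to exercise the study conditions while staying quick on a single
CPU: one 120 s recording for map recovery; twenty 60 s datasets for the
KL selection rate; thirty 30 s recordings × 10 surrogates for the GEV
contrast; 200 sources × 20 subjects for GLM recovery; 50 repetitions of a
20-subject null at α = 0.05 with 199 flips for the family-wise error
calibration (a permutation null cannot resolve α = 0.001 within 50
repetitions; the production default stays 0.001 with ≥ 999 flips).

## A minimal session

```{r example, eval = FALSE}
rec <- simulate_dataset(n_channels = 19, n_states = 5, duration_s = 120,
                        fs = 250, snr = 5, seed = 1)
fit <- fit_microstates(rec, k_min = 1, k_max = 10)

# model selection
pk <- attr(fit, "gfp")$peak_indices
peaks <- t(average_reference(rec)$data[, pk])
tab <- criterion_table(peaks, fit)
attr(tab, "chosen_k")

# parameters of the 5-state model
model <- fit$models[["5"]]
lab <- backfit(average_reference(rec), model)
microstate_parameters(lab, compute_gfp(average_reference(rec)))
```

## Known limitations

* The AAHC dissolution is greedy; on adversarial inputs its final GEV can
  sit below the best partition (the shipped enumeration check documents
  exact agreement on well-separated instances only).
* The EDF writer/reader covers continuous 16-bit recordings with integer
  sampling rates; EDF+ annotations are not handled.
* Group-level analysis pools peaks or tests subject-level coefficients;
  a full two-stage subject→group map hierarchy is not implemented.
* Statistical-map summaries correlate enhancement-masked maps; with very
  small masks the correlation is reported as `NA` rather than invented.
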