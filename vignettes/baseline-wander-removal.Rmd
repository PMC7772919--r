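---
title: "Wavelet-based baseline-wander removal: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based baseline-wander removal: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(ecgbw)
```

## The problem

Baseline wander (BW) is the slow drift — respiration, electrode motion,
perspiration — superimposed on an ECG trace. It sits mostly below 0.5 Hz,
overlaps the ST segment's diagnostic content in time, and biases any
amplitude-based measurement. `ecgbw` implements and benchmarks a
frequency-selective remedy: decompose the contaminated signal with the
Maximal Overlap Discrete Wavelet Transform (MODWT), zero the coefficient
levels that carry the drift, and invert.

Because real recordings give no access to the "true" drift-free signal,
the benchmark is *semi-synthetic*: take an excerpt that is as clean as
possible, min-max normalize it to $[0,1]$,

$$x_N[t] = \frac{x[t] - x_{\min}}{x_{\max} - x_{\min}},$$

add a mathematically known artificial trend $w[t]$,

$$y[t] = x_N[t] + w[t],$$

detrend $y$ by level-selective reconstruction,

$$x'[t] = \mathrm{IWT}\big(\mathrm{WT}(y[t]),\ \text{coefficients at
selected levels} = 0\big),$$

and score the result against the known ground truth with the mean square
error over the $M$ compared samples,

$$\mathrm{MSE} = \frac{1}{M}\sum_{t=1}^{M}\big(x_N[t] - x'[t]\big)^2 .$$

Every (wavelet, preserved-level-range, trend, record) combination gets one
MSE; `run_grid()` tabulates the full Cartesian product and
`summarize_grid()` / `autoplot()` aggregate it.

## The transform

`modwt()` implements the undecimated pyramid: at level $j$ the base
filters (rescaled by $1/\sqrt2$) are upsampled by a stride of $2^{j-1}$
and applied by *circular* convolution, yielding same-length detail vectors
$W_1 \dots W_J$ and a final smooth $V_J$. Circular boundary handling is
the convention of the mainstream numerical toolboxes this benchmark
mirrors; its edge artifacts are exactly why the pipeline discards the
first and last 2 s afterwards. The MODWT (unlike the decimated DWT) is
defined for any sample count, is equivariant under circular shifts, and
satisfies the energy identity
$\sum_j \lVert W_j\rVert^2 + \lVert V_J\rVert^2 = \lVert x\rVert^2$ —
all three properties are tested, the last two to 1e-10 and 1e-8.

Internally each stage is evaluated in the frequency domain (the strided
kernels become pointwise DFT products), which is algebraically identical
to the time-domain pyramid; the unit tests verify agreement with a
literal gather-and-sum implementation of the defining formula to 1e-12.
Coefficient alignment follows from the kernel convention
$W_j[t] = \sum_l \tilde h_l\, V_{j-1}[(t - 2^{j-1} l) \bmod N]$: for the
Haar filter, level-1 details are backward differences, which the impulse
test pins down. A global reflection of the filters would shift
coefficient phase but, after trimming, not the MSE.

Detail level $j$ nominally passes $(f_s/2^{j+1},\, f_s/2^j]$
(`level_band()`). At $f_s = 250$ Hz, level 8 starts at
$250/2^9 \approx 0.49$ Hz and level 7 ends at $\approx 0.98$ Hz, so a
record decomposed to $J = 11$ and rebuilt from levels 1–7 ("lv1–7")
loses everything below about 1 Hz — the entire 0.05–0.5 Hz trend suite.

## The filter catalogue

Fourteen orthogonal wavelets in five families: db1–db4, sym3/4/6/10,
coif1–coif4, fk4, dmey. Taps are stored in the unit-energy convention
($\sum g = \sqrt2$, $\sum g^2 = 1$, ascending index order); each wavelet
filter is derived by the quadrature-mirror rule
$h[k] = (-1)^k g[L-1-k]$. Three catalogue decisions deserve a note:

* **db3 ≡ sym3.** The Daubechies and Symlet constructions coincide for
  three vanishing moments. The catalogue stores one tap vector for both
  names, so their detrending outputs and MSEs are *bit*-identical — a
  tie that the benchmark reports as a set rather than breaking. (Some
  published tables tabulate the two independently with ~1e-12
  discrepancies; storing them separately would turn an exact tie into a
  numerical accident.)
* **fk4.** The 4-tap Fejér–Korovkin scaling filter is published to about
  nine significant digits, which leaves identity residuals near 1e-9.
  Length-4 orthogonal filters with DC gain $\sqrt2$ form a one-parameter
  lattice family; the catalogue stores the lattice member nearest the
  published taps (within 4e-9 of them), so the filter identities hold to
  machine precision. The "4" in fk4 is the tap count, not a
  vanishing-moment order — the family trades moments for frequency
  localization, and vanishing-moment tests therefore cover only the
  dbN/symN families, whose index genuinely counts moments.
* **dmey.** The discrete Meyer wavelet is not FIR; the catalogue ships
  the standard 62-tap FIR approximation used by mainstream toolboxes.
  That filter is *close to* but not exactly orthogonal (unit energy off
  by 2.2e-3, even-shift orthonormality off by 1.4e-3). The consequence
  is inherited by any implementation using these taps: MODWT
  reconstruction and energy conservation hold only to roughly 1e-2 for
  dmey, versus 1e-12 for the other thirteen filters. Tests and the
  acceptance script state the exact identities for the thirteen
  orthogonal filters and the documented approximation bounds for dmey.

## The detrender

`detrend_ecg()` chains `modwt()` → `zero_levels()` → `imodwt()` → trim →
`minmax_normalize()`. Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `keep_lo:keep_hi` | 1:7 | preserved detail levels ("lvA–B") |
| `n_levels` | 11 | depth $J$; the maximum for 3500 samples |
| `trim_s` | 2 s | boundary discard per edge |
| `keep_smooth` | `FALSE` | preserve $V_J$? |
| `renormalize` | `TRUE` | min-max rescale of the trimmed window |

Two deliberate interpretation choices:

* **The smooth is zeroed with the high levels.** "Set levels 8–11 to
  zero" is read as including $V_{11}$: the smooth carries the DC level
  and the slowest trend content, and keeping it would let every baseline
  survive reconstruction, making all level ranges equivalent.
  `keep_smooth = TRUE` is available for inspection.
* **Trim, then renormalize.** Normalization of the detrended signal is
  computed over the retained 10-s window, not the full 14 s, since the
  discarded edges are exactly the samples known to be distorted. This
  choice perturbs MSEs in the third decimal relative to the alternative
  order.

`extract_trend()` rebuilds from the complementary coefficient set (the
zeroed levels plus the smooth), untrimmed; by linearity it sums with the
retained reconstruction back to the input exactly.

A deliberately reproduced pathology: when a residual *spike* is the
post-detrend maximum, the renormalization step compresses the whole ECG
into a fraction of $[0,1]$ and the MSE inflates. This is the documented
failure mode of normalization-based scoring in spike experiments, not a
defect of the detrender; `renormalize = FALSE` exposes the raw
reconstruction for users who want to avoid it. Spikes themselves are
high-frequency and are *not* removed by zeroing high levels — but
`locate_spike()` shows they are precisely *localized* by the level-1
reconstruction (the argmax of its absolute value, no threshold), which
is the practical takeaway for spike handling.

### Stability under re-application

Level-selective MODWT reconstruction multiplies the spectrum by a smooth
subband gain in $[0,1]$, not by a 0/1 indicator, so it is *not* a
projection: applying `detrend_ecg()` twice re-attenuates transition-band
energy. For a 60-bpm ECG the beat fundamental (~1 Hz) sits exactly in
the level-7/8 transition at 250 Hz, and trimming additionally breaks the
circular periodicity the second analysis assumes. Measured on synthetic
records the second pass changes the result by a few percent RMS; the
test suite asserts stability at the 15% level and no tighter, and exact
idempotence should not be expected of this (or any toolbox's)
level-selective detrender.

## The synthetic data

`synth_ecg()` emulates the benchmark's raw material: a 14-s, 250-Hz,
single-channel excerpt with identifiable P-QRS-T morphology (five
Gaussian bumps per beat, R dominant, T second), beat-to-beat R-R jitter
(uniform, ±2% by default), deterministic under a seed. The trend suite
(`trend_suite()`) is fixed at ten unit-amplitude zero-phase sinusoids on
the uniform grid 0.05–0.50 Hz in 0.05-Hz steps — ten waves matching the
stated frequency endpoints — plus one unit step and one unit
single-sample spike, both at mid-record onset (7 s). Trend amplitudes
are *unit on the normalized scale*: the benchmark adds a trend of the
same numeric size as the whole normalized ECG range, which is the
literal reading of the semi-synthesis equation and is reproduced as
such. All four step/spike parameters and the sinusoid grid are
config-overridable (`grid_config()`), but the defaults above define the
study conditions and the tests run against them.

What the generator does *not* emulate: broadband muscle noise, powerline
interference, electrode pops, respiratory amplitude modulation, morphology
pathology (arrhythmia, ST deviation). Passing grids on synthetic records
therefore demonstrates the *mechanism* — frequency separation between
ECG content and sub-1-Hz trends — and the correct rank ordering of level
ranges; absolute MSE values on real records differ (real excerpts carry
residual noise and their own faint wander). The WFDB reader
(`read_wfdb_excerpt()`, formats 212/16) runs the identical pipeline on a
local PhysioNet-style directory for users with the real data; the
package never downloads anything.

## Numerical policy

* Reconstruction/energy tolerances: 1e-9 / 1e-8 relative (orthogonal
  filters); dmey at its documented ~1e-2.
* Constant-annihilation and zero-sum checks at 1e-11–1e-10: several
  published tap tables (sym4, sym6) are themselves only 1e-12-accurate.
* Argmin ties in summaries are resolved at 1e-12 and reported as sets.
* Degenerate cells (a constant post-trim window cannot be renormalized)
  carry an error marker through `run_grid()` instead of aborting the
  grid; summaries exclude them with a warning.
* Grid problem sizes: the packaged studies use 10 seeded synthetic
  records, 14 wavelets, the 6 level ranges lv1–7, lv1–8, lv2–8, lv3–8,
  lv1–9, lv3–9, and the 12-trend suite (10 080 cells), a size chosen to
  keep a full run in the low minutes on one core while still averaging
  over morphology and jitter variation.

## Worked example

```{r example}
x_n <- minmax_normalize(synth_ecg(seed = 1))
y <- superimpose(x_n, make_trend(sinusoid_trend(0.3), 14, 250))
d <- detrend_ecg(y, "sym3", keep_lo = 1, keep_hi = 7)
mse(x_n$value[501:3000], d$value)
```

```{r grid, eval = FALSE}
g <- run_benchmark(grid_config(n_records = 10, seed = 1))
summarize_grid(g)
autoplot(g)
```

## Known limitations

* Absolute MSE levels depend on the excerpt's own sub-band content;
  only orderings and attenuation factors transfer to other data.
* dmey results carry the FIR approximation's ~1e-2 reconstruction
  floor (negligible next to trend-scale errors, visible in identity
  tests).
* Circular boundaries assume trimming; with `trim_s = 0` the first and
  last seconds are unreliable.
* Streaming/online operation and non-circular boundary modes are out of
  scope, as are biorthogonal or continuous wavelets.
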