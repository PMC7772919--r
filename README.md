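# ecgbw — wavelet-based baseline-wander removal benchmarks for ECG

Baseline wander is the sub-1-Hz drift (respiration, electrode motion)
that rides under an electrocardiogram and corrupts amplitude-based
measurements such as the ST segment. `ecgbw` removes it by
level-selective wavelet reconstruction and — its main purpose —
benchmarks *which* wavelet and *which* preserved-level range do this
best, on semi-synthetic data where the ground truth is known exactly.

The package is aimed at biomedical-signal engineers choosing a
detrending configuration, and provides:

* a self-contained **MODWT / inverse-MODWT** engine (undecimated pyramid,
  circular boundaries, any sample count, energy-conserving, shift-
  equivariant), plus level-selective reconstruction;
* a catalogue of **14 orthogonal wavelets** (db1–4, sym3/4/6/10,
  coif1–4, fk4, dmey) with their quadrature-mirror filter pairs;
* a seeded **synthetic ECG generator** (Gaussian P-QRS-T beats with R-R
  jitter) and the 12-trend suite: 10 sinusoids spanning 0.05–0.5 Hz, a
  step and a single-sample spike;
* the **benchmark grid**: tidy tables of MSE for every
  (record, wavelet, level range, trend) combination, with summaries,
  tie-aware argmin reporting and ggplot2 heatmaps;
* a **WFDB reader** (formats 212/16) to run the identical pipeline on a
  local PhysioNet-style directory, e.g. the QT Database.

## The method

Normalize an excerpt to $[0,1]$, add a known trend, detrend, score:

$$x_N = \frac{x - x_{\min}}{x_{\max} - x_{\min}}, \qquad
  y = x_N + w, \qquad
  x' = \mathrm{IWT}\big(\mathrm{WT}(y),\ \text{levels outside } [A,B] = 0\big),$$

$$\mathrm{MSE} = \frac{1}{M}\sum_{t=1}^{M}\left(x_N[t] - x'[t]\right)^2 .$$

At 250 Hz, MODWT detail level $j$ covers $(250/2^{j+1}, 250/2^j]$ Hz, so
preserving levels 1–7 of an 11-level decomposition (written "lv1–7")
removes everything below ~0.98 Hz — the whole trend suite — while keeping
the QRS band. The first and last 2 s are discarded (circular-boundary
artifacts) and the result is renormalized before scoring.

## Worked example

```r
library(ecgbw)

x_n <- minmax_normalize(synth_ecg(seed = 1))        # 14 s @ 250 Hz, [0,1]
w   <- make_trend(sinusoid_trend(0.3), 14, 250)     # 0.3 Hz unit sinusoid
y   <- superimpose(x_n, w)                          # semi-synthetic ECG
d   <- detrend_ecg(y, "sym3", keep_lo = 1, keep_hi = 7)

nrow(d)                                             # 2500  (10 s retained)
mse(x_n$value[501:3000], d$value)                   # 0.001268964
```

The detrended 10-s window differs from the clean excerpt by an MSE of
about 1.3e-3 — the 0.3 Hz wander (amplitude equal to the full ECG range)
is essentially gone; the residual is the ECG's own sub-1-Hz content that
was removed along with it. Keeping the trend's band instead
(`keep_hi = 9`) raises the MSE to ~8.4e-2, sixty-fold worse.

A full study over seeded synthetic records:

```r
g <- run_benchmark(grid_config(n_records = 10, seed = 1))  # 10,080 cells
summarize_grid(g)          # mean MSE per wavelet x level range
best_configs(g)            # argmin set (db3 and sym3 always tie exactly)
autoplot(g)                # heatmap, one facet per level range
```

A thin command-line front end wraps the same functions
(`exec/ecgbw list-wavelets | simulate | detrend | grid | report`).

## Real data

Point the benchmark at a local WFDB directory to use real excerpts
instead of synthetic ones (nothing is downloaded):

```r
cfg <- grid_config(qtdb_dir = "path/to/qtdb")
g <- run_benchmark(cfg)
```

Excerpt windows and channels are drawn reproducibly from the config
seed via `sample_excerpts()`.
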