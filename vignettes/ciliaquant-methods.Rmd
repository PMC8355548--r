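---
title: "Methods: how ciliaquant quantifies cilia beating, basal-body alignment and co-localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how ciliaquant quantifies cilia beating, basal-body alignment and co-localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaquant)
```

`ciliaquant` packages four image- and count-based assays used to
characterise multiciliated-cell (MCC) maturation. This vignette explains
the models behind each assay, the parameters that matter, what the
synthetic generators do and do not emulate, and the numerical decisions
a maintainer would want written down.

## 1. Cilia beat frequency from bead movies

### Model

A magnetic bead resting on beating cilia is carried back and forth at
the ciliary beat frequency. The estimator models the observable as a
quasi-stationary bright/dark blob whose centre oscillates about a rest
point; the only claim made is that the motion has a dominant temporal
frequency per axis. Accordingly the analysis chain is:

1. **Background removal.** The per-pixel temporal *median* over a
   uniform subsample of at most 200 frames is subtracted from every
   frame. The median rather than the mean is used because each bead
   occupies its own rest pixels for much of the movie; a mean would
   absorb more of the bead into the background. Static structures
   cancel exactly; a constant intensity offset cancels exactly.
2. **Detection.** Each residual frame is convolved with a Gaussian
   matched filter (`smooth_sigma`, default 1.5 px) and thresholded at
   `threshold_sd` (default 5) times the frame's robust noise scale
   σ̂ = 1.4826·MAD. The matched filter exists because a bead that
   oscillates by roughly its own radius never fully leaves the temporal
   median: the raw per-pixel residual of a bead with contrast C
   saturates near C/2 and, for small amplitudes, falls to a few σ.
   Filtering at the blob scale restores the contrast without changing
   the detection rule. Suprathreshold pixels are grouped by
   8-connectivity; components of at least `min_area` (default 4) px²
   become detections at their intensity-weighted centroid. Dark and
   bright components are labelled separately so that the bright
   "vacated" lobe a dark bead leaves in the residual can never merge
   with the bead itself.
3. **Linking.** Greedy nearest-neighbour linking accepts
   track–detection pairs in ascending distance order when the
   displacement is below `max_disp` (default 8) px per elapsed frame;
   gaps of up to 2 frames are bridged by linear interpolation; tracks
   observed in fewer than `min_coverage` (default 0.5) of the movie's
   frames are dropped. Beads in this assay are sparse and
   quasi-stationary, which is why a greedy linker suffices; dense
   scenes with fast crossings would need a global assignment solver.
4. **Spectral estimate.** Each axis series is linearly detrended (this
   is what makes the estimate robust to slow drift), Hann-windowed,
   zero-padded to 4× its length, and Fourier transformed. The per-axis
   frequency is the dominant periodogram peak in `[f_min, fps/2)`
   refined by 3-point parabolic interpolation; the reported beat
   frequency is the peak of the axis with larger peak power, and both
   axes are always reported so either convention can be recovered.
   `quality` = peak power / median band power; the movie summary is the
   median over beads with `quality ≥ quality_min` (default 5).

### Parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `fps` | frames/s | required | never read from metadata; f̂ scales linearly with it |
| `threshold_sd` | σ̂ multiples | 5 | ~0.01 expected false pixels/frame at 128² |
| `smooth_sigma` | px | 1.5 | matched to 2-px bead radius; 0 disables |
| `polarity` (pipeline) | — | `"dark"` | brightfield beads are dark; see below |
| `max_disp` | px/frame | 8 | > 2π·f·A/fps at the fastest plausible beat |
| `f_min` | Hz | 0.5 | excludes DC/drift leakage; well below the slowest beating of interest (~2 bps) |
| `quality_min` | ratio | 5 | rejects tracks without a clear spectral line |

### The polarity decision

With `polarity = "both"` a dark bead contributes two component
families: its own dark lobe (which oscillates at the true frequency f)
and the bright lobe of the background it has vacated. The bright lobe
is a function of |displacement| and therefore beats at *even harmonics*
of f; tracking it yields clean but wrong 2f/3f lines. `detect_beads()`
keeps `"both"` as its general-purpose default, but `cbf_pipeline()` and
the CLI default to `"dark"` because the assay's beads are imaged dark
in brightfield. Users with fluorescent tracers should pass
`polarity = "bright"`.

### Known limitations

- Localization on median-subtracted residual lobes carries a systematic
  outward bias of ~1–2 px at 3-px oscillation amplitude (the median
  smear cancels signal near the rest point). The bias distorts the
  waveform, not its period: frequency recovery in our tests is exact to
  ~1e-4 Hz while absolute positions should not be over-interpreted.
- Very slow beats at low amplitude fragment tracks: near each zero
  crossing the residual drops below threshold for longer than the
  2-frame gap budget. At the study conditions (amplitude 3 px, SNR 10)
  recovery is reliable across 2–29 Hz at 120 fps; at SNR 5 the floor
  rises to roughly amplitude ≥ 3 px and f ≥ 5 Hz.

## 2. Basal-body alignment

Basal bodies anchored in well-aligned rows produce elongated connected
components in a thresholded staining image; immature or misorganised
cells show compact clusters. The score is geometric:

1. ROIs are segmented per cell (within a user-supplied label mask,
   replacing interactive cell outlining) with a per-cell Otsu threshold
   by default — staining intensity varies between cells — or a fixed
   threshold for strict reproducibility. 8-connected components of at
   least `min_area` (default 3) px² survive; components are clipped at
   cell borders so each ROI belongs to one cell.
2. Each ROI's **pixel corners** (4 per pixel) are enclosed by the
   minimum-area (Löwner–John) ellipse. Corners rather than centres make
   a 1-pixel ROI a finite circle (Mm = 1) and a single pixel row a
   valid thin ellipse instead of a degenerate zero-area set.
3. With semi-axes a ≥ b: eccentricity = √(a²−b²)/a (focal-point
   distance over major-axis length) and Mm ratio = a/b. Per cell the
   unweighted means over its ROIs are reported (the per-ROI table is
   kept so any other weighting can be recomputed), and groups are
   compared with Welch's unequal-variance two-tailed t-test.

### Numerical notes on the ellipse solver

Khachiyan's barycentric ascent maximises log det of the weighted
scatter of the lifted points. Three implementation details matter:

- Points are centred and scaled before iterating: corner coordinates of
  order 10² make the lifted 3×3 system ill-conditioned enough to break
  naive inversion.
- Plain increase-only updates converge sublinearly and cannot reach the
  1e-7 dual-gap tolerance within the 10 000-iteration budget. The solver
  therefore takes Wolfe *away steps* (shrinking the weight of the
  worst interior support point); the away-step line-search formula is
  only valid for κ > 1, so deep-interior points are dropped outright.
- Even with away steps the final weight re-balancing among the ~3–6
  support points zig-zags. Every 100 iterations a Newton solve of the
  support's optimality system (κ_j = d+1, Σu = 1; the Jacobian
  ∂κ_j/∂u_k = −(q_jᵀX⁻¹q_k)² is closed-form) finishes the problem
  quadratically; the polished weights are accepted only if they reduce
  the dual gap. Typical ROIs converge in under 300 iterations.
- Truly collinear input (impossible for pixel-corner sets) is refused
  with an informative error rather than regularised silently.

The test suite checks the solver against closed forms (the minimal
ellipse of a w×h rectangle has semi-axes √2·w/2, √2·h/2), against an
independent D-optimal-design optimiser on random small point sets
(areas agree to 0.1%), and for containment of every input point.

## 3. Mander's co-localization with a displaced null

Thresholded Mander's coefficients measure intensity-weighted overlap:
M1 is the fraction of red signal (over red pixels above `t_red`) lying
where green exceeds `t_green`, M2 the converse. Conventions chosen:

- Thresholds default to per-channel Otsu and are always recorded in the
  output; fixed values can be supplied.
- Denominators are restricted to the own channel's above-threshold
  pixels (the JACoP-style thresholded convention);
  `thresholded_denominator = FALSE` switches to whole-channel sums.
  Note that only the unthresholded convention is monotone in the own
  threshold.
- The null control displaces the green channel 5 px along x and *crops
  both channels to the overlap* — wrap-around would fabricate overlap
  at the seam. Spot-scale co-localization collapses under the shift;
  spatially random overlap is unchanged in expectation, which is what
  makes the paired two-tailed t-test of M vs M_shift across images a
  calibrated test (type-I rate 0.05 ± 0.03 in the 200-set simulation
  run by the acceptance suite).

## 4. Gate-gene marker comparison

Cells are split at ≥ 1 read of the gate gene (default *Jam3*): a
deliberately simple, sequencing-depth-sensitive gate that mirrors how
such splits are made in practice. Marker panels are scored per cell as
the unweighted mean of CPM-normalised expression over the panel's genes
(CPM = counts·10⁶/cell depth); panels are compared between groups with
a two-sided Mann–Whitney test by default, because per-cell scores of
sparse counts are skewed and heteroscedastic; `test = "t"` restores a
Welch t-test. Marker lists are user input (shipped as editable
one-gene-per-line text files), since they come from the literature, and
the reference gene (default *Foxj1*) is scored alone as a
should-not-differ control.

## 5. What the synthetic generators emulate — and what they do not

The generators define the conditions under which the pipelines are
validated; passing tests demonstrate correct *method* behaviour under
these models, not performance on any specific real data set.

- `make_movie()`: sinusoidal bead motion (rest + drift + A·sin(2πft))
  rendered as Gaussian blobs on a constant background (optional linear
  gradient), i.i.d. Gaussian noise, dark beads by default, SNR defined
  as |contrast|/noise_sd. Defaults encode the assay's regime: 120 fps,
  20 s, amplitude 3 px (a free choice — the real waveform and amplitude
  are not characterised), SNR 10. Not emulated: metachronal waves,
  non-sinusoidal waveforms, motion blur, illumination flicker, bead
  detachment.
- `make_bb_image()`: aligned cells as parallel rows of overlapping
  blobs (row spacing 3·blob σ so a row fuses into one component after
  thresholding), non-aligned cells as the same number of blobs in
  compact ~3-blob clusters, cells as non-overlapping disks on a grid.
  Not emulated: anti-correlated staining backgrounds, touching cells,
  z-blur, rotational (basal-foot) polarity.
- `make_coloc_pair()`: red spots with a minimum separation; a chosen
  fraction of green spots centred exactly on red spots, the rest kept
  ≥ 4σ away, so ground-truth co-occupancy is structural. Not emulated:
  partial overlaps, chromatic aberration, intensity correlation without
  spatial overlap.
- `make_counts()`: negative-binomial counts (dispersion 0.3, a standard
  minimal scRNA-seq noise level), lognormal gene abundances and cell
  depths, gate-gene draw zero-truncated in positive cells and exactly
  zero in negative cells, deuterosomal markers scaled by the effect
  fold-change in negative cells only. Not emulated: batch effects,
  dropout beyond NB sampling, cell-cycle or contamination structure.

All generators are deterministic given their seed (bit-identical
outputs), which the test suite asserts.

## 6. Problem sizes and reproducibility

The unit suite validates frequency recovery on 10-s, 3-bead movies
across 2–29 Hz, alignment separation on 16–40-cell images, shift-null
calibration on 200 simulated 6-image sets at 128², and the marker
comparison at 500 cells × 2 000 genes — sizes chosen so the entire
suite runs in a few minutes on one core while keeping every statistical
check well-powered. `scripts/acceptance.R` re-runs the bead pipeline at
the full study conditions (10 beads, 20 s, 120 fps) for the 15 bps and
2 bps regimes. Every stochastic step flows from an explicit seed;
CLI runs additionally write a manifest (resolved configuration + input
digests) sufficient to reproduce the run.
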