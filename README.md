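# ciliaquant

Image quantification for multiciliated-cell (MCC) biology. Airway
epithelial MCCs carry hundreds of motile cilia whose coordinated beating
moves mucus; their maturation can be read out from how fast the cilia
beat, how well the basal bodies (the centriole-derived anchors of the
cilia) align into rows at the apical membrane, and how membrane proteins
traffic through apical endosomes. `ciliaquant` implements the
quantitative assays behind those readouts for people analysing
time-lapse and confocal images of cultured airway epithelium (e.g. mouse
tracheal epithelial cells at air–liquid interface), plus the single-cell
count-matrix comparison that links a gate gene to maturation stage.

The package covers four assays, each with a seeded synthetic-data
generator providing ground truth:

1. **Cilia beat frequency (CBF)** from movies of magnetic beads resting
   on the ciliated surface. Pipeline: per-pixel temporal-median
   background removal → per-frame bead detection at a robust threshold
   (|residual| > k·σ̂, σ̂ = 1.4826·MAD) → greedy nearest-neighbour
   trajectory linking → per-axis FFT. Each axis series is detrended,
   Hann-windowed and zero-padded 4×; the beat frequency f̂ (in beats per
   second ≡ Hz) is the parabolic-refined dominant periodogram peak of
   the stronger axis, and a movie is summarised by the quality-filtered
   median over beads.
2. **Basal-body alignment** per cell. Basal-body ROIs are segmented
   inside user-supplied cell masks (per-cell Otsu by default), each ROI
   is enclosed by its minimum-area (Löwner–John) ellipse computed with
   Khachiyan's algorithm on the ROI's pixel corners, and two elongation
   scores follow from the semi-axes a ≥ b: eccentricity
   e = √(a² − b²)/a and the major/minor "Mm" ratio a/b. Aligned rows
   of basal bodies produce elongated ROIs (large Mm ratio); scattered
   clusters stay round. Groups of cells are compared with Welch's
   t-test.
3. **Mander's co-localization** with a displaced-image null. Thresholded
   M1 = Σ R·[G > t_G]/Σ R (over red pixels above t_R) and the symmetric
   M2, recomputed after shifting the green channel 5 px along x
   (cropping the overlap) as a random-overlap control, with a paired
   t-test of M vs M_shift across images.
4. **Gate-gene marker comparison** for single-cell counts: cells split
   into positive (≥ 1 read of e.g. *Jam3*) and negative, per-cell
   CPM-mean scores for deuterosomal vs mature-MCC marker panels, and a
   Mann–Whitney test per panel.

## Worked example

```r
library(ciliaquant)

# a 20-s, 120-fps movie of 10 beads beating at 15 bps, SNR 10
sim <- make_movie(n_beads = 10, f_true = 15, fps = 120, duration = 20, seed = 1)
res <- cbf_pipeline(sim$movie)
res$summary
#> # A tibble: 1 × 4
#>   median_f_beat iqr_f_beat n_beads_used n_beads_total
#>           <dbl>      <dbl>        <int>         <int>
#> 1          15.0  0.0000749           10            10
```

All ten beads are tracked and the median recovered frequency matches the
simulated truth to well under the 0.05 Hz frequency resolution of a 20-s
recording.

```r
# basal-body alignment: half the cells have row-organised basal bodies
bb <- make_bb_image(n_cells = 16, frac_aligned = 0.5,
                    frame_shape = c(320, 320), seed = 7)
al <- bb_alignment(bb$image, bb$mask)
dplyr::left_join(al$cells, bb$ground_truth, by = "cell_id") |>
  dplyr::group_by(aligned) |>
  dplyr::summarise(mean_mm = mean(mean_mm_ratio), n = dplyr::n())
#> # A tibble: 2 × 3
#>   aligned mean_mm     n
#>   <lgl>     <dbl> <int>
#> 1 FALSE      1.35     8
#> 2 TRUE       4.67     8
```

Aligned cells sit far above the Mm ≈ 2 decision line, non-aligned cells
far below it.

```r
# co-localization with 30% true co-occupancy
cp <- make_coloc_pair(co_occupancy = 0.3, seed = 2)
coloc_pair(cp$red, cp$green)
#> # A tibble: 1 × 8
#>   image_id    M1    M2 M1_shift M2_shift shift_pixels t_red t_green
#>      <int> <dbl> <dbl>    <dbl>    <dbl>        <int> <dbl>   <dbl>
#> 1        1 0.292 0.290   0.0282   0.0285            5  34.8    35.9
```

M2 recovers the constructed 0.30 co-occupancy and collapses by an order
of magnitude under the 5-px displacement, as genuine spot-scale overlap
must.

## Command line

A thin wrapper at `inst/scripts/ciliaquant` exposes the same pipelines:

```sh
Rscript inst/scripts/ciliaquant simulate movie --seed 1 --out sim/
Rscript inst/scripts/ciliaquant cbf --movie sim/movie.tif --fps 120 --out results/
Rscript inst/scripts/ciliaquant bbalign --image bb.tif --mask cells.tif --out results/
Rscript inst/scripts/ciliaquant coloc --red r.tif --green g.tif --out results/
Rscript inst/scripts/ciliaquant scmarkers --counts m.mtx --deutero d.txt --mature m.txt --out results/
```

Every run writes a `run_manifest.json` with the tool version, the fully
resolved configuration and MD5 digests of all inputs, so results are
reproducible from the manifest alone. Frame rate is always an explicit
argument — camera metadata is never trusted, because the frequency
estimate scales linearly with it.

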