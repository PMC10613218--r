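# vesicoloc

Quantification of multivesicular endosomes (MVEs) and their molecular
markers in multi-channel fluorescence microscopy, for cell biologists
studying exosome biogenesis, endosomal phosphoinositide identity, and
organelle contact sites. The package re-implements, as tested and
reusable R functions, an image-quantification workflow built around four
measurements:

1. **Vesicle detection** — a scale-normalized Laplacian-of-Gaussian (LoG)
   blob detector with a quality threshold. For an estimated object
   diameter *d* (10 px for ~1 µm CD63-labeled MVEs, 6 px for EEA1-labeled
   endosomes), the filter scale is σ = *d* / (2√2) and the response is
   −σ² ∇²(G<sub>σ</sub> ∗ I), so a matched bright blob maximizes the
   response over scales. Detections are response local maxima above the
   quality threshold, with non-maximum suppression and a `merged_flag`
   for suspected unresolved doublets.
2. **Line-profile colocalization** — a 40-px intensity profile is drawn
   across each vesicle on the 8-bit converted images; a *signal* is a
   maximal run of samples strictly above 100 (8-bit units); the vesicle is
   **marker-positive** (e.g. exocyst- or PI(4)P-reporter-positive) when
   the overlap area, Σ min(vesicle, marker) over the intersection of the
   two peaks' supports, exceeds 50% of the marker peak area. The fraction
   of positive vesicles over all detected MVEs is the reported
   percentage. The same machinery quantifies reporter (phosphoinositide)
   intensity on vesicles.
3. **Contact sites (MMCS)** — 50-px profiles from each vesicle toward the
   closest mitochondrion; a mitochondrion–MVE contact site is called when
   the two channels' supra-background signal runs overlap. Contacts are
   assigned to the perinuclear region (a disk of twice the equivalent
   nuclear diameter centered on the nucleus) or the peripheral remainder
   of the cell. For electron-microscopy annotations, a direct contact is
   a MVE–mitochondrion pair whose boundary-to-boundary gap is less than
   the mean MVE radius in the image.
4. **3D localization rendering** — single-molecule localization tables
   (x/y/z in nm) are exported as uranium pseudo-atom XYZ files (scale
   factor 15), converted to density volumes as sums of unit-integral 3D
   Gaussians (σ = sigma_factor × resolution, defaults 1.5 × 1.4), and
   cleaned with a dust filter that removes localizations ≥ 60 nm from
   every other localization.

Because the underlying raw microscopy data are not public, the package
ships a **synthetic-scene generator** (`generate_scene()`) that renders
multi-channel cells — vesicle puncta, offset marker puncta at a known
true positive fraction, filamentous mitochondria, an elliptical nucleus,
Gaussian PSF blur, Poisson + read noise — together with a complete
ground-truth table, so every stage of the pipeline is testable end to
end. All quantification results are tibbles; fitted runs support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(vesicoloc)

cfg <- run_config(scene = scene_params(marker_positive_fraction = 0.45),
                  n_cells = 5, seed = 42)
run <- run_pipeline(cfg)
run
#> <vesicoloc_run> 5 cell(s), 250 detection(s)
#>   marker-positive: 40.4% (true 41.2%)
#>   contacts/cell: 13.8 (1.4 perinuclear, 12.4 peripheral)

glance(run)
#> # A tibble: 1 x 6
#>   n_cells n_detections pct_marker_positive true_pct_marker_positive ...
#> 1       5          250                40.4                     41.2

head(tidy(run)[, c("cell_id", "vesicle_id", "x", "y", "quality",
                   "is_positive", "overlap_share", "region")])
#> # A tibble: 6 x 8
#>   cell_id vesicle_id     x     y quality is_positive overlap_share region
#> 1       1          1   245   330    118. FALSE               0     peripheral
#> 2       1          2   250    31    117. FALSE               0     peripheral
#> 3       1          3   102   293    117. FALSE               0     peripheral
#> 4       1          4   131    45    117. TRUE                0.893 peripheral
#> 5       1          5    56   105    117. TRUE                1     peripheral
#> 6       1          6    43   245    115. FALSE               0     peripheral
```

Five synthetic cells of 50 vesicles each were generated with a true
marker-positive fraction of 45%; the realized truth over these particular
250 vesicles is 41.2% and the pipeline estimates 40.4% — detection,
8-bit conversion, profile extraction and the >50% overlap rule together
recover the planted fraction to within about a percentage point of the
realized truth. `autoplot(run)` shows the per-cell percentages against
the ground-truth line, and `autoplot(profile)` draws annotated intensity
profiles with the cutoff and peak supports.

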