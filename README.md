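# focikit

Quantification of DNA double-strand-break (DSB) repair foci and
repair-protein colocalization in multichannel fluorescence microscopy
images.

When cells suffer DSBs — from radiomimetic drugs such as bleomycin or from
ionizing radiation — the histone variant H2AX is phosphorylated (γH2AX)
around each break and repair proteins (53BP1, phosphorylated DNA-PK and
ATM) are recruited, forming discrete nuclear foci visible by
immunofluorescence. Counting these foci per nucleus over time measures
repair kinetics; the overlap between a repair-protein channel and the
γH2AX channel measures recruitment. focikit implements this whole
analysis for researchers studying DNA damage response, repair kinetics,
and cellular senescence:

* **Nucleus masking** from a DNA counterstain (DAPI): Otsu threshold on a
  lightly smoothed channel, hole filling, connected-component labeling,
  minimum-area filter. Every downstream measurement is restricted to
  these per-nucleus regions of interest.
* **Focus counting and projected-area measurement** inside each nucleus:
  relative-dynamic-range (or fixed series-wide) thresholding, 8-connected
  components, exclusion of blobs under 3 pixels as noise (0.24 µm² at the
  0.285 µm projection pixel), conversion of areas to µm² by the squared
  pixel size, and histograms of projected focus area (PAF) in 0.1 µm²
  bins. Nuclei with dense pan-nuclear staining (apoptotic type) are
  flagged and excluded automatically.
* **Difference-of-Gaussians (DoG) enhancement** of punctate signals:
  blur(σ=1 px) − blur(σ=30 px), negatives clipped, normalized to in-mask
  maximum 1 — the small radius matches pixel noise, the big radius the
  maximum focal-signal size. A plateau check verifies the coefficients
  are insensitive to the big radius over 30–55 px.
* **Colocalization per nucleus** on the DoG-enhanced channels: Pearson's

      Rr = Σ(aᵢ−ā)(bᵢ−b̄) / √(Σ(aᵢ−ā)² Σ(bᵢ−b̄)²)   ∈ [−1, 1]

  and Manders' overlap

      R = Σ aᵢbᵢ / √(Σ aᵢ² Σ bᵢ²)                  ∈ [0, 1]

  plus the split coefficients M1/M2, one value per cell, then group
  means ± SE (typically over 25 nuclei).
* **Repair kinetics**: per-group mean foci/nucleus ± SE by timepoint and
  the percentage of foci repaired relative to the post-treatment maximum;
  two-group comparisons with a pooled-variance Student's t-test gated by
  per-sample Shapiro–Wilk normality checks (flagged, not silently
  replaced), significance at p < 0.05.
* **A seeded synthetic-scene generator** — elliptical nuclei, planted
  Gaussian foci with a controllable truly-colocalized fraction,
  pan-nuclear cells, shot and read noise — with complete ground truth, so
  the entire pipeline can be validated end to end without real confocal
  data.

## Worked example

```r
library(focikit)

spec <- scene_spec(n_nuclei = 8, foci_per_nucleus = 12, coloc_fraction = 0.7,
                   independent_foci_B = 4, min_focus_spacing = 8, seed = 42)
sc   <- generate_scene(spec)                       # scene + ground truth
mask <- segment_nuclei(get_channel(sc$scene, "dna"))
mask
#> NucleusMask: 8 nuclei in 512 x 512 px; areas 1261-2060 px

det <- detect_foci(get_channel(sc$scene, "A"), mask, spec$pixel_size)
mf  <- mean_foci_per_nucleus(det$summaries)
#> foci per nucleus: 12.00 +/- 0.00 SE (n = 8)

h <- paf_histogram(det$records)
#> mean PAF: 0.73 um^2; peak bin [0.40, 0.50)

res <- coloc_per_nucleus(sc$scene, mask, c("A", "B"), dog_params(1, 30))
#> mean Rr = 0.655, mean R = 0.732 over 8 nuclei
```

All 12 planted foci per nucleus are recovered (SE 0 because the planted
count is fixed), the PAF distribution peaks in the 0.40–0.49 µm² bin with
a right skew — the shape expected of γH2AX foci at this pixel size — and
with 70 % of channel-A foci duplicated in channel B the per-nucleus
Pearson coefficient averages 0.66.

A command-line wrapper over the same functions ships at
`inst/cli/focikit.R` (`simulate`, `count-foci`, `coloc`, `plateau-check`,
`kinetics`, `recover` subcommands); every run writes its effective
configuration and a log next to its outputs.

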