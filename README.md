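# imdspatial

Spatial quantification of T-cell and metabolite responses around
implantable microdevices (IMDs) in tumors.

An IMD carries ~18 reservoirs that each release a microdose of a drug or
metabolite into the adjacent tumor tissue. `imdspatial` implements the
downstream analysis for this design:

* **ROI geometry** — the 1,200 µm drug-diffusion footprint around each
  reservoir, divided into four concentric 300 µm sub-ROIs; cells assigned
  by nearest reservoir with half-open rings.
* **Perturbation response** — per-tumor density log2 fold changes of
  marker-positive cells (CD3 / CD8 / FOXP3) in a condition footprint
  versus the *same tumor's* empty-reservoir internal control:

  $$\mathrm{log_2FC} = \log_2 \frac{n_\mathrm{ROI}/A_\mathrm{ROI}}
  {n_\mathrm{ctrl}/A_\mathrm{ctrl}}, \qquad
  \%\Delta = (2^{\overline{\mathrm{log_2FC}}} - 1)\cdot 100,$$

  aggregated across tumors as mean ± SEM with a two-tailed unpaired
  Student's t-test against control-vs-control fold changes.
* **Paired spatial metabolomics** — kernel density maps of marker-positive
  cells, hotspot detection (density-quantile threshold + connected
  components + fixed-area discs), greedy pairing of each hotspot with a
  nearby equal-area marker-low disc (count log2 fold change ≥ 0.5),
  per-metabolite paired t-tests on raw ion counts, hypergeometric pathway
  over-representation (BH-adjusted), correlation-based metabolic
  signatures, and opposite-trend calls between marker populations.
* **ST classification** — CD8 positive index (CD8+/nuclei) with the
  high (> 20%) / intermediate / low (< 5%) class bands, per-ROI
  geometric-mean normalization, and class-vs-class differential expression
  feeding the shared enrichment test.
* **Synthetic data** — generators for all four input modalities with
  *planted* effect sizes (inhomogeneous Poisson cell processes,
  negative-binomial ion images, class-banded ST ROIs), so every stage is
  testable end to end. Named presets encode the reported effects, e.g.
  `ARG_CD8` (+75% CD8), `LAC_CD8` (−50% CD8), `PYR_FOXP3` (+60% FOXP3),
  `ATP_FOXP3` (−70% FOXP3), `GLN_CD3` (+75% CD3).

See the methods vignette (`vignettes/imdspatial-methods.Rmd`) for the
models, assumptions, parameter defaults and design decisions.

## Worked example

Simulate the arginine-release scenario (planted +75% CD8 response, six
tumors) and run the perturbation pipeline:

```r
library(imdspatial)

scenario   <- perturbation_preset("ARG_CD8", seed = 42)
experiment <- gen_device_tumor(scenario)
run_perturbation(experiment)
#> Perturbation effect table (log2 FC vs same-tumor empty-reservoir control)
#>  condition marker mean_log2fc   sem n_tumors  p_value percent_change stars
#>    ARG_CD8    CD3      -0.006 0.042        6 9.16e-01           -0.4
#>    ARG_CD8    CD8       0.774 0.053        6 3.39e-07           71.0    **
#>    ARG_CD8  FOXP3       0.049 0.066        6 4.87e-01            3.5
```

The CD8 row recovers the planted +75% (here +71.0% for this seed, p ≈
3×10⁻⁷ against the internal-control null, `**` marking p < 0.005), while
the unperturbed CD3 and FOXP3 markers stay at their controls.

The metabolomics arm, on a synthetic section with CD8 hotspots and planted
glutathione / N-acetyl-cysteine enrichment:

```r
sim      <- gen_ion_image(metabolomics_preset("CD8_HOTSPOT", seed = 42))
map      <- density_map(sim$cells, "CD8", sim$image)
hotspots <- detect_hotspots(map, sim$cells)
pairs    <- pair_rois(hotspots, sim$cells, sim$image)
stats    <- paired_stats(pairs, sim$image)
head(stats[order(stats$p_value), ], 3)
#>         metabolite mean_log2fc      p_value   adjusted_p significant n_pairs
#>  N-acetyl-cysteine  0.94342472 1.798026e-05 0.0007192103        TRUE       6
#>        glutathione  0.97495761 1.703345e-04 0.0034066906        TRUE       6
#>           pyruvate -0.05104494 3.660518e-01 0.9879128113       FALSE       6
```

Both planted antioxidants are flagged significantly enriched in the
CD8-high ROIs at ~+1 log2, exactly as planted; unperturbed metabolites are
not. `run_pipeline()` ties the stages together from a YAML config and
writes tables, GeoJSON overlays and a reproducibility manifest
(`inst/scripts/imd_pipeline.R` is a thin command-line wrapper).

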