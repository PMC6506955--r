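# periplaque

Quantification of amyloid plaque pathology and the peri-plaque glial
response in multi-channel fluorescence microscopy of brain sections, for
researchers working with amyloid mouse models (5xFAD and similar) or human
AD tissue.

Reactive astrocytes and microglia organize into a glial net around amyloid
plaques; its integrity shapes plaque compaction and the exposure of nearby
neurons to Aβ. The package measures that organization from standard
immunofluorescence channels (Aβ, thioflavin S, GFAP, Iba1, NeuN,
synaptophysin, AQP4):

- **Plaque morphometry** — intensity thresholding, 8-connected labelling,
  strict > 50 µm² object filter; per image: plaque count, mean size,
  density per mm², and amyloid load (plaque area fraction).
- **Plaque classes** — dense-core / fibrillar / mixed from relative
  Aβ vs thioflavin S staining intensity.
- **Peri-plaque band metrics** — a band of fixed physical width
  (default 5 µm) built by exact Euclidean distance transform;
  GFAP enrichment
  `E = mean(GFAP | region) / mean(GFAP | non-plaque field)`
  for the plaque interior and the band.
- **Microglial coverage** — fraction of each plaque's boundary within
  2 µm of thresholded Iba1 signal, plus Iba1 cell density.
- **Neuropathology** — fraction of peri-plaque NeuN somata containing
  ≥ 3 intracellular Aβ puncta; fraction of plaques with ≥ 4 large
  (≥ 3 µm²) presynaptic dystrophies.
- **AQP4 polarization** — background-corrected AQP4 in perivascular or
  peri-plaque ROIs over non-plaque parenchyma.
- **Group statistics** — per-animal summaries, unpaired t-tests, two-way
  ANOVA (condition × class, type II) with Bonferroni post-tests, ECDFs.

Because the underlying study deposits no raw images, the package ships a
first-class synthetic scene generator (`generate_scene`, `generate_cohort`)
that renders all seven channels with planted ground truth — plaque
geometry and classes, stroke-density GFAP enrichment, angular coverage
arcs, puncta counts, dystrophy blobs, perivascular enrichment, PSF blur
and Poisson–Gaussian camera noise — so every measurement is validated
end-to-end against known truth. See `vignette("periplaque-methods")` for
the model, parameter rationale, and limitations.

## Worked example

```r
library(periplaque)

# render a synthetic cortical scene (256 x 256 px, 0.5 um/px) and measure it
sp  <- scene_spec(seed = 7)
sc  <- generate_scene(sp)
res <- analyze_scene(sc$stack, run_config(),
                     vessel_mask = sc$truth$vessel_mask)
res$summary
```

which prints (abridged):

```
plaques: 10   amyloid load: 0.1096   mean size: 179.6 um^2
class fractions (dense/fibrillar/mixed): 0.30 / 0.30 / 0.40
GFAP enrichment, interior: 1.11   periphery: 1.59
microglial coverage: 0.56   Abeta-positive neurons: 0.25
dystrophic plaques: 0.70   perivascular AQP4 ratio: 3.61
```

All ten planted plaques are recovered, each with its planted class; the
amyloid load is the summed plaque area over the analyzed area; peri-plaque
GFAP is 1.59× the non-plaque field; 56% of plaque boundary is within 2 µm
of microglial signal; a quarter of peri-plaque neurons carry ≥ 3 Aβ
puncta; and perivascular AQP4 runs 3.6× parenchymal levels (planted 4×,
attenuated by PSF bleed at the rim). Per-plaque and per-neuron tables sit
in `res$plaques` and `res$neurons`:

```
  label area_um2 plaque_class periphery_enrichment coverage_fraction dystrophy_count
1     1   115.00        mixed                 1.61              0.65               4
2     2   235.25   dense_core                 1.02              0.85               3
3     3    75.25    fibrillar                 1.42              0.35               2
4     4   101.75        mixed                 2.00              0.51               4
```

Cohorts with condition effects (e.g. a knockout that doubles plaque area
and weakens the glial net) are generated with `generate_cohort()`,
aggregated per animal with `summarize_cohort()`, and compared with
`compare_groups()` / `compare_class_fractions()`.

A thin command-line front end is installed as `periplaque`
(`simulate`, `segment`, `quantify`, `stats`); see the header of
`exec/periplaque`.

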