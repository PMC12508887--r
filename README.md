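# ramanMQA

Multivariate semi-quantitative analysis of single-cell confocal Raman
hyperspectral images.

Confocal Raman microscopy resolves the vibrational fingerprint of a
cell at sub-micron scan steps, but raw band intensity cannot be read as
abundance: it is confounded by scattering cross-sections, focus and
instrument drift.  ramanMQA implements the full pipeline that turns a
raw spectral cube into comparable subcellular metabolite maps:

1. **Preprocessing** — wavenumber calibration against the silicon
   520 cm⁻¹ band, cosmic-ray removal, asymmetric-least-squares baseline
   correction, Savitzky–Golay smoothing, optional PCA denoising.
2. **Compartmentalization** — K-means clustering of vector-normalized
   spectra on PCA scores, endmember extraction with non-negative
   least-squares unmixing, difference-peak attribution of clusters to
   compartments (nucleus, lipid droplets, symbiont strains, cytoplasm).
3. **Semi-quantification** — per-pixel band-area integration over
   ±8 cm⁻¹ peak windows and normalization by an internal-standard band,

   &nbsp;&nbsp;&nbsp;&nbsp;ΔA = A_metabolite / A_internal standard,

   which cancels the per-pixel gain exactly.  ΔA is proportional to
   concentration per metabolite (semi-quantitative), so compartments,
   cells and treatment groups can be compared.  The internal standard
   ships as the 1341 cm⁻¹ band (tentatively threonine) and can be
   re-derived on any cube by spatial-uniformity ranking.
4. **Validation** — a synthetic bacteriocyte phantom generator with
   exact ground truth (compartment masks, concentration fields, gain,
   noise, spikes, seed), a de-symbiosis series, and a mock calibration
   series, all bit-reproducible from a seed.

The package is aimed at microbiologists and spectroscopists working on
host–symbiont systems and other single-cell metabolic mapping problems
where labeling or extraction-based assays are impractical.

## Worked example

```r
library(ramanMQA)

ph <- makeCellPhantom(seed = 42)        # cube + ground truth
ph$cube
#> RamanCube: 48 x 48 pixels (450 nm), 1351 channels 400.0..3100.0 cm^-1, 1280/2304 valid

lib  <- libraryEntries(defaultLibrary())
wins <- list(glycogen    = lib$glycogen$windows[[1]],
             cholesterol = lib$cholesterol$windows[[1]],
             tryptophan  = lib$tryptophan$windows[[1]])
bundle <- runMQA(ph$cube, list(windows = wins, k = 5, seed = 42))

bundle$clusters
#> ClusterResult: k = 5 on 48 x 48 grid (seed 42)
#>   pixels per cluster: 116, 613, 39, 300, 212

annotateClusters(differencePeaks(bundle$clusters))
#>    cluster         class                            bands
#> 1 cluster0       nucleus         nucleic acid;deoxyribose
#> 2 cluster1     cytoplasm phenylalanine;tryptophan;glucose
#> 3 cluster2 lipid droplet    triglyceride;palmitoleic acid
#> 4 cluster3      symbiont           glycogen;NADH;squalene
#> 5 cluster4      symbiont              squalene;lanosterol

subset(bundle$stats, metabolite == "glycogen")
#>   group label   n       mean          sd metabolite
#> 1           0 116 0.02475805 0.005602434   glycogen
#> 2           1 613 0.02359231 0.005385103   glycogen
#> 3           2  39 0.02550570 0.005913478   glycogen
#> 4           3 300 1.10422300 0.028926928   glycogen
#> 5           4 212 0.31764495 0.013487398   glycogen
```

The glycogen table reads directly against the annotation above: the
two symbiont clusters (labels 3 and 4) carry mean ΔA 1.10 and 0.32 —
the outer strain stores roughly 3.5× the glycogen of the inner strain,
matching the phantom's construction — while nucleus, cytoplasm and
lipid droplets sit at the ~0.02 background of the 484 cm⁻¹ window.
Every map can be exported (`exportMap()`: float TIFF, palette PNG with
a JSON color-scale sidecar, lossless CSV), and `reportBundle()` writes
a self-contained markdown summary.

A thin command-line front end ships in `inst/scripts/mqa`
(`mqa phantom | preprocess | cluster | unmix | quantify | calibrate |
pipeline`), writing maps, tables and a provenance JSON next to its
outputs.

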