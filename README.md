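# qdepth

Quantifies how deep fluorescently labelled nanoparticles (for example
CdSe/ZnS quantum dots) penetrate past the apical membrane of an
epithelial cell monolayer, from two-channel 3D confocal / two-photon
z-stacks. Written for cell-biology and nanotoxicology groups who image a
membrane label and a particle label and need a number — not a visual
impression — for "are the particles on the cells or in them?".

## The measurement

For each stack the pipeline segments the apical membrane and the
particles, then measures, per particle, the signed axial distance from
its intensity-weighted centre of mass to the nearest point of the apical
membrane surface (z grows apical → basal, so penetration is negative).
Distances pooled across stacks are histogrammed and fitted with a
Gaussian

    A · exp( −(x − x_c)² / (2σ²) )

whose peak position `x_c` is the penetration-depth statistic: `x_c` near
zero means the particle population is membrane-associated, a clearly
negative `x_c` (beyond the axial-resolution allowance) means it has
penetrated into the cells.

The processing chain is the classical object-analyzer recipe: optional
Richardson–Lucy deconvolution (theoretical Gaussian PSF); lateral
Gaussian smoothing of 2 px (particle channel) and 30 px (membrane
channel), no axial filtering; membrane thinning by subtracting a copy
axially shifted 2 px; Otsu thresholds on 256-bin histograms; 26-connected
labelling; a 10⁵-voxel membrane volume filter; particle filters at 450
voxels (minimal single-particle volume) and 5 % of the
threshold-to-maximum intensity range; and marker-based watershed
splitting of small agglomerates (pre-smoothing σ = 0.1 µm).

A synthetic scene generator (`scene_spec()` / `render_scene()`) renders
monolayer stacks with exact ground truth — membrane sheet, PSF-shaped
spots at known signed offsets, agglomerates, organelle spheres, Poisson +
Gaussian noise — so the entire chain is testable without any microscopy
data. Organelle compartments (endosome / lysosome scale) can be sized via
`measure_organelles()` / `equivalent_diameter()`.

## Worked example

```r
library(qdepth)

shape <- c(64L, 256L, 256L)
inputs <- lapply(1:4, function(s) {
  spec <- scene_spec(shape = shape,
                     spots = spot_grid(25, -1.3, shape),  # 1.3 µm inside the cell
                     seed = 100 + s)
  sc <- render_scene(spec)
  list(membrane = sc$membrane, particles = sc$particles, id = paste0("s", s))
})
report <- run_pipeline(pipeline_config(), inputs)
print(report)
```

```
penetration_report: 4 stack(s), 100 particle record(s)
depth_fit: n = 100 object(s) from 4 stack(s), bin width 0.2 um
  x_c = -1.500 +/- 0.001 um, sigma = 0.006 +/- 0.000 um (sample fit)
  verdict: penetrating
```

`x_c = −1.50 µm` is the true −1.3 µm offset plus the known one-voxel
(−0.2 µm) surface-quantization offset of the voxel-based surface
estimate; the verdict rule accounts for it via an axial-resolution
allowance (`min_depth_um`, default 0.4 µm = two axial sections). The same
scenes rendered with spots at offset 0 give `x_c ≈ −0.20 µm` and verdict
`membrane-associated`. The methods vignette
(`vignettes/penetration-depth.Rmd`) explains each stage, the defaults and
their units, and the generator's scope.

Real stacks enter through `read_stack()` (TIFF with voxel spacing from a
JSON sidecar or ImageJ-style metadata; spacing can also be supplied
explicitly — it is never guessed) and `run_pipeline(config, paths)` with
membrane in channel 1 and particles in channel 2. Every run can write
`records.csv`, `histogram.csv`, `fit.json` and its fully resolved
`config.yaml` for provenance.

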