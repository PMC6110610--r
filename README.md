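# centriotome

A desk-scale cryo-electron-tomography workbench for the 9-fold centriole,
written as a Bioconductor-style R package. It reproduces, on fully synthetic
data with known ground truth, the analysis chain used to solve centriole
microtubule-blade structures by subtomogram averaging: parametric centriole
models, single-axis tilt-series simulation with a missing wedge, weighted
back-projection, rod tracing and 24 nm disc sub-volume extraction,
missing-wedge-aware alignment and averaging with gold-standard FSC, axial
and partial-B-tubule classification, and geometric reconstruction
(flattening quantification, 9-fold symmetrization, diameter and blade-tilt
measurement).

## The science

Centrioles are cylindrical organelles built from nine microtubule blades
arranged with 9-fold symmetry. In mammalian (CHO) centrioles each blade is
a triplet microtubule (TMT): a complete 13-protofilament A-tubule plus
incomplete 10-protofilament B- and C-tubules sharing walls, decorated by a
pinhead on protofilament A03, an A-C linker bridging A09 to the
neighbouring blade's C08/C09, and microtubule inner proteins (MIPs) with 8
or 16 nm axial periods, one of which straddles the lattice seam between
A09 and A10. The proximal ~200 nm and distal ~200 nm of the centriole are
structurally distinct domains; *Drosophila* S2 centrioles are shorter
(~175 nm) doublets (A13 + B10) linked blade-to-blade through A-A
contacts. Purified centrioles flatten in the thin ice sheet used for
cryo-EM, so the 9-fold geometry must be restored by imposing externally
known symmetry parameters before ensemble measurements.

The analysis core is subtomogram averaging under a missing wedge. A
single-axis tilt series covering +60° to −60° at 1° sampling leaves a
wedge of Fourier space unmeasured; all similarity scores are therefore
*constrained cross-correlations* — normalized correlations evaluated only
on the Fourier region jointly sampled by both volumes:

    CCC(a, b) = Re ⟨ FA, FB ⟩_Ω / ( ‖FA‖_Ω · ‖FB‖_Ω ),
    Ω = wedge(a) ∩ wedge(b) ∩ lowpass, DC excluded

and averages are wedge-weighted Fourier sums divided by the accumulated
per-voxel coverage. Resolution is assessed by Fourier shell correlation
between independently refined half-sets at the 0.143 criterion.

## Worked example

Simulate a flattened CHO centriole, reconstruct and trace it, average the
segments and measure the restored geometry:

```r
library(centriotome)

cfg <- pipelineConfig(preset = "cho", flatten = 0.2, snr = 0.5,
                      seeds = list(model = 1L, noise = 2L,
                                   halves = 3L, classify = 4L))
run <- runPipeline(cfg)
run$report$geometry[c("ellipticity_percent", "diameter_proximal_nm",
                      "diameter_distal_nm", "tilt_change_deg")]
#> $ellipticity_percent
#> [1] 29.68782
#> $diameter_proximal_nm
#> [1] 225.4938
#> $diameter_distal_nm
#> [1] 217.1026
#> $tilt_change_deg
#> [1] 15.60388
```

The report reads: the refit blade-centre ring is strongly elliptical
(~30%, the signature of the e = 0.2 ice-sheet flattening applied by the
generator, since the semi-axis ratio is (1+e)² = 1.44); after
symmetrizing the proximal and distal domain averages with the true
9-fold parameters, the ensemble diameters come back within a few percent
of the nominal 235 nm (proximal) and 220 nm (distal), and the blades
rotate ~15° inward between the domains — the geometry the generator put
in. Protofilament architecture is read
off the average with `countProtofilaments()` (13/10/10 for the CHO
triplet), and `computeFSC()` gives the gold-standard resolution of the
run (4.47 nm at these settings).

A thin command-line front end is installed with the package:

```sh
Rscript inst/exec/centriotome simulate --preset cho --flatten 0.2 --snr 0.5 --seed 7 --out sim/
Rscript inst/exec/centriotome run --config run.yaml --out results/
```

## Package layout

| area | contents |
|---|---|
| `R/model.R`, `R/presets.R`, `R/assemble.R` | protofilament lattices, blades, decorations, whole-centriole assembly and flattening |
| `R/tomo.R`, `R/io.R` | rasterization, tilt projection, WBP reconstruction, wedge masks; MRC/STAR/TSV/tlt I/O |
| `R/picking.R` | rod tracing, segment sampling, sub-volume extraction, consistency curation |
| `R/sta.R` | constrained CC, alignment, wedge-weighted averaging, FSC, periodicity, protofilament counting |
| `R/classify.R` | axial binning, proximal/distal split, masked classification |
| `R/geometry.R` | pose refit, ellipse fitting, symmetrization, diameter and tilt measurement, composite rebuild |
| `R/simulate.R`, `R/pipeline.R` | segment simulator, end-to-end pipeline and fixtures |
| `vignettes/centriole-averaging.Rmd` | the methods vignette |
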