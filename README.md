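# voxelFD

Per-region 3D box-counting fractal dimension for segmented brain MRI.

Structural brain change during neurodegeneration is usually tracked through
region volumes, but volumetry is noisy across scanners, sessions and
protocols. The fractal dimension (FD) of a segmented structure summarises
its space-filling complexity instead of its size, and has been proposed as
a more stable morphometric marker of cognitive decline. `voxelFD`
implements the full desk-side workflow around that idea, for image analysts
working with FreeSurfer/VoxelMorph-style integer label volumes:

* the **Minkowski–Bouligand (box-counting) dimension** of any 3D voxel
  mask,

  D_box(S) = lim_{ε→0} log N(ε) / log(1/ε),  ε = 1/s,

  estimated as the negated slope of the ordinary least-squares fit of
  log10 N on log10 s over a 20-point logarithmic box-edge schedule
  (edges ≈ 1.02–8.92 voxels), with the fit RMSE kept as a linearity
  (mono- vs multi-fractal) diagnostic;
* **I/O** for NIfTI (`.nii`, `.nii.gz`) and compressed-array (`.npz`)
  label volumes, OASIS-style session ids (`OAS30001_MR_d0129`), YAML/JSON
  region label maps, and centered cropping to segmentation grids such as
  (160, 192, 224);
* **synthetic phantoms** of known dimension (filled cube, slab, line,
  Menger sponge, seeded random blobs) so the estimator is testable without
  any MRI data;
* **per-region morphometry**: volume + FD per region per session, wide
  multi-session comparison tables with repeat-scan relative variation;
* **CDR cohort labeling**: windowing rules that attach a Clinical Dementia
  Rating to each MRI session (45-day window by default), one session per
  subject, explicit control/dementia class policy;
* **SVM classification** of (volume, FD) features with stratified
  cross-validation and the recall-weighted F-beta score (β = 8.25 by
  default).

## Worked example

Build a level-3 Menger sponge phantom, embed it as region label 26
(third ventricle in the default label map) in a 64-cube volume, and measure
it like an MRI session:

```r
library(voxelFD)

sponge <- makePhantom("menger_sponge", level = 3)   # 27^3 grid, 20^3 voxels
vol    <- embedPhantom(sponge, c(64, 64, 64), label = 26)

est <- estimateFD(extractRegion(vol, 26))
est
#> FDResult: fd = 2.490627 (rmse 0.1050, r2 0.9787, 20 points) [multifractal_suspect]

meas <- measureSession(vol, parseSessionId("OAS30001_MR_d0129"), labels = 26)
meas[, c("session_id", "region_name", "voxel_count", "fd", "rmse")]
#>          session_id     region_name voxel_count       fd      rmse
#> 1 OAS30001_MR_d0129    whole_volume        8000 2.490627 0.1049776
#> 2 OAS30001_MR_d0129 third_ventricle        8000 2.490627 0.1049776
```

Reading the output: the sponge's similarity dimension is
log 20 / log 3 ≈ 2.7268. At box edges aligned with its base-3 construction
the counts are exact — `estimateFD(sponge, scaleSchedule(scales = c(3, 9, 27)))`
returns 2.726833 — but the default schedule's misaligned edges straddle the
sponge's holes and flatten the fitted slope to 2.49 here (the phantom is
also shifted off the grid origin by the centered embedding). The RMSE
diagnostic reports exactly this: 0.105 > 0.05 flags the log–log curvature,
so the single-dimension summary is marked `multifractal_suspect`. On
well-filled masks the flag stays `fractal_ok` and the estimate lands near
the analytic value (filled 64-cube: 2.939; slab: 1.960; line: 0.980). The
two rows agree because the volume contains a single region, so the
whole-volume mask coincides with it.

The same operations are scriptable from a shell through the thin CLI
installed with the package:

```sh
voxelfd=$(Rscript -e 'cat(system.file("exec", "voxelfd", package = "voxelFD"))')
Rscript "$voxelfd" phantom --kind menger_sponge --level 3 --label 26 \
        --shape 64,64,64 --out sponge.nii.gz
Rscript "$voxelfd" fd --in sponge.nii.gz --labels 26 \
        --session OAS30001_MR_d0129 --out fd.csv
```

Other entry points: `compareSessions()` (multi-session wide tables with
(max−min)/mean variation), `labelSessions()`/`buildCohort()` (CDR
windowing and the cross-sectional cohort), `crossvalClassify()` and
`decisionBoundaryGrid()` (SVM reports). The methods vignette
(`vignettes/boxcounting-brain-morphometry.Rmd`) documents the estimator's
numerical behaviour — lattice misalignment, translation sensitivity,
finite-size bias — and every design default.

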