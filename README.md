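# ciliapol

Quantification of planar cell polarity (PCP) and ciliary beat frequency
for multiciliated epithelia such as the brain-ventricle ependyma.

Ependymal cells carry a patch of motile cilia whose coordinated placement
and beating drive cerebrospinal-fluid flow. Two aspects of that
coordination are measured from traced immunofluorescence data:

- **Translational polarity** — the ciliary patch sits off-centre on the
  apical surface, displaced in a common tissue direction.
- **Rotational polarity** — individual cilia beat in a common direction,
  read out from the basal-body→basal-foot axis (e.g. FOP→γ-tubulin
  immunosignals) of each cilium.

`ciliapol` takes traced cell contours, patch contours and per-cilium
marker point pairs (JSON), and computes, per cell *i* with cilium angles
θ₁…θₙ:

- the displacement vector from the cell centroid to the patch centroid,
  and its angle relative to the field mean displacement direction
  (**VpatchD**);
- the circular mean beating angle (mean **vCil**), its angle relative to
  the field mean orientation (**VpatchO**), and the within-cell circular
  standard deviation CSD = (180/π)·√(−2 ln R), where
  R = |Σⱼ e^(iθⱼ)|/n is the mean resultant length — cells with
  CSD > 45° carry no defined beating orientation;
- the angle between displacement and beating orientation (**VpatchD&O**);
- displacement **strength** = |displacement| / √(A/π) (dimensionless,
  normalised by the equivalent cell radius), areas in µm² (pixel size
  0.09 µm by default) and cilia counts.

Groups are compared with Watson's two-sample U² test (rotation-invariant,
permutation p-values) for the angle families and the classical
pooled-variance two-tailed t test for linear quantities.

A second pipeline estimates **ciliary beat frequency (CBF)** from
fluorescence time-lapse stacks (default 600 frames at 21 frames/s):
background subtraction, mono-exponential bleach correction, smoothing,
kymogram extraction along user polylines, reduction to an intensity
trace, and the dominant FFT peak above a robust median + 4·MAD threshold.

Because such microscopy data are rarely shareable, the package ships
ground-truth generators: Voronoi-tessellated epithelial fields with von
Mises-distributed polarity angles of controllable concentration, and
synthetic beating-cilium traces/videos with photobleaching and noise.
Every pipeline stage is tested against these generators.

## Worked example

```r
library(ciliapol)

## a two-group study: 5 coordinated ("control") and 5 dispersed
## ("mutant") synthetic fields of ~50 cells
st <- generate_study(n_fields = 5, seed = 1)
fa <- lapply(st$control, function(s) field_polarity(s$field))
fb <- lapply(st$mutant,  function(s) field_polarity(s$field))

summary(fa[[1]])
#> Polarity summary for field 'control-f01-seed2' (control), 50 cells
#>   vpatchD   n =  50  circ. mean    0.00 deg  CSD  23.59 deg
#>   vpatchO   n =  50  circ. mean    0.00 deg  CSD  24.09 deg
#>   vpatchDO  n =  50  circ. mean   -0.42 deg  CSD  30.25 deg
#>   csd            n =  50  mean    20.515  sd    3.301
#>   strength       n =  50  mean     0.316  sd    0.075
#>   cell_area_um2  n =  50  mean   169.869  sd   45.978
#>   patch_area_um2 n =  50  mean    19.871  sd    5.378
#>   n_cilia        n =  50  mean    28.720  sd    6.421

compare_groups(fa, fb, n_permutations = 999, seed = 1)
#> Group comparison (250 vs 250 cells pooled)
#> Circular metrics (Watson U2, permutation p):
#>   vpatchD   U2 =  2.97679  p = 0.001  (n = 250 vs 250)
#>   vpatchO   U2 =  1.51819  p = 0.001  (n = 250 vs 95)
#>   vpatchDO  U2 =  2.41020  p = 0.001  (n = 250 vs 95)
#> Linear metrics (pooled-variance t, two-tailed p):
#>   csd        t =  -48.797  p = 7.055e-192  (n = 250 vs 250)
#>   strength   t =   -0.961  p = 0.3368  (n = 250 vs 250)
#>   cell_area  t =    0.000  p = 1  (n = 250 vs 250)
#>   patch_area t =   -0.000  p = 1  (n = 250 vs 250)
#>   n_cilia    t =   -0.505  p = 0.6136  (n = 250 vs 250)
```

Reading this: the per-cell vpatchD/vpatchO angles of the dispersed group
spread far more widely than the coordinated group's, so all three Watson
U² tests reject; within-cell beating dispersion (CSD) is much higher in
the dispersed group (negative t: control minus mutant), while patch
displacement strength, areas and cilia numbers do not differ. Note the
smaller vpatchO/vpatchD&O n in the second group — cells whose CSD
exceeds 45° carry no defined beating orientation and are excluded, never
imputed.

Beat frequency from a synthetic trace:

```r
tr <- generate_trace(video_params(seed = 1), 1)
estimate_cbf(tr$trace)
#> CBF estimate: 5.460 Hz (peak 1.37e+04 > threshold 1.57e+03; resolution 0.0350 Hz)
tr$true_freq_hz
#> [1] 5.470536
```

## Command line

A thin wrapper (installed at `inst/cli/ciliapol`, or call
`ciliapol::cli_main()` directly) exposes the pipeline as subcommands:

```sh
ciliapol simulate-tissue --preset control --fields 2 --seed 1 --out ctrl/
ciliapol quantify --out ctrl/metrics.csv ctrl/field-01.json ctrl/field-02.json
ciliapol compare --a ctrl/metrics.csv --b mut/metrics.csv --out report.json
ciliapol simulate-video --cilia 5 --seed 1 --out vid/
ciliapol cbf --stack vid/stack.tif --polylines vid/polylines.json --out est.csv
ciliapol report --metrics ctrl/metrics.csv --out plots/
```

Every output gets a `.config.json` sidecar with the effective
configuration, and identical seeds give byte-identical outputs.

## Vignette

`vignettes/ciliary-polarity.Rmd` documents the statistical model, every
tunable parameter, the generators' scope, and the numerical choices.
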