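# ranvier3d

3D reconstruction and morphometry of nodes of Ranvier from multi-channel
confocal z-stacks, with a ground-truth synthetic-stack simulator and nested
mixed-effects group statistics.

## The problem

Nodes of Ranvier — the unmyelinated gaps where action potentials regenerate —
are flanked by two CASPR-labeled paranodes whose geometry tunes conduction
velocity. Group differences reported in this literature are single-digit
percentages of structures 1–2 µm long, imaged at 0.04 × 0.04 × 0.10 µm
voxels, with axons oriented arbitrarily in 3D. A 2D maximum-projection
measurement foreshortens a paranode tilted by θ out of the imaging plane by
roughly cos θ, a distortion far larger than the effects of interest, so the
measurement has to be genuinely three-dimensional.

`ranvier3d` provides the full chain:

- **Simulator** (`sim_config()`, `sample_geometry()`, `render_stack()`,
  `generate_cohort()`): hierarchical cohorts (groups → mice → nodes → two
  collinear paranodes), capsule-shaped paranodes at arbitrary 3D
  orientations, anisotropic Gaussian PSF, Poisson + read noise,
  staining-batch intensity factors, optional node-marker (Nav1.6) and
  axon-label (mCherry) channels — with a complete ground-truth table.
- **Stack IO** (`read_stack()`, `write_stack()`, `crop_um()`): OME-TIFF with
  `PhysicalSizeX/Y/Z` metadata; all geometry in physical micrometres.
- **Segmentation** (`segment_paranodes()`, `segment_node_marker()`):
  per-field Otsu threshold, 3D connected components on anisotropic voxels,
  volume and blur-corrected elongation filters, optional distance-transform
  watershed splitting of touching capsules.
- **Morphometry** (`paranode_length()`, `project2d_length()`,
  `pair_paranodes()`, `node_width()`, `total_region_length()`): sub-voxel
  half-maximum endpoints along the principal axis with phantom-calibrated
  tip correction; greedy score-based pairing of flanking paranodes; node
  width = inner-endpoint distance, total nodal region = outer-endpoint
  distance.
- **Axon classification** (`assign_axon_status()`): labeled/non-labeled by
  line-overlap of the paranode axis with the thresholded axon channel.
- **Statistics** (`fit_mixed()`, `fit_interaction()`,
  `pairwise_contrasts()`, `percent_difference()`): `value ~ group + batch`
  with mouse and node-in-mouse random intercepts (REML via `lmerTest`),
  Satterthwaite degrees of freedom, unadjusted pairwise contrasts reported
  as `"Con vs. Res, t(13.5) = -2.356, p = 0.034"`, and percent differences
  of batch-adjusted marginal means.
- **Pipeline** (`simulate_measure_cohort()`, `run_full()`,
  `validate_recovery()`) and a CLI (`exec/ranvier3d
  simulate|convert|crop|segment|measure|stats|run|validate`).

The mixed model, in the field's notation: for measurement $y_{ijk}$
(paranode $k$ of node $j$ in mouse $i$),

$$y_{ijk} = \beta_{g(i)} + \gamma_{b(i)} + a_i + n_{ij} + e_{ijk},\qquad
a_i \sim N(0,\sigma^2_m),\; n_{ij} \sim N(0,\sigma^2_n),\; e_{ijk} \sim N(0,\sigma^2),$$

with group and staining batch fixed; contrasts $t = \hat\Delta/SE$ with
Satterthwaite df. Group effects are reported as
$100\,(\bar y_{g} - \bar y_{ref})/\bar y_{ref}$ on adjusted means.

## Worked example

Simulate a small two-group cohort in which the treatment group's true
paranode lengths are 10.3% shorter, run the full segment → measure → model
pipeline in memory, and compare groups:

```r
library(ranvier3d)

cfg <- sim_config(n_groups = 2, n_mice_per_group = 4, n_nodes_per_mouse = 15,
                  group_names = c("control", "resilient"),
                  group_length_ratios = c(1, 0.897), seed = 7)
res <- simulate_measure_cohort(cfg)
fit <- fit_mixed(res$records, "paranode_length")
print(fit)
pairwise_contrasts(fit)$report
percent_difference(fit, "control", "resilient")
validate_recovery(res)
```

```
<ranvier_fit> measure = paranode_length, n = 240
 group     emmean     SE df lower.CL upper.CL
 control     1.69 0.0326  5     1.60     1.77
 resilient   1.45 0.0326  5     1.37     1.53

Results are averaged over the levels of: batch 
Degrees-of-freedom method: satterthwaite 
Confidence level used: 0.95 
random-effect SDs:
mouse_id:node_id         mouse_id         Residual 
          0.0694           0.0442           0.2434 
[1] "control vs. resilient, t(5.0) = 5.168, p = 0.004"
[1] -14.12036
<recovery_report>
         measure   n      bias_um    rmse_um
 paranode_length 240 -0.004831143 0.01789670
      node_width 110  0.022858254 0.02844907
    total_region 110 -0.010018632 0.01758451
recall 1.000, precision 1.000
 reference comparison  true_pct measured_pct
   control  resilient -14.61607    -14.12036
```

Reading the output: the batch-adjusted marginal means are 1.69 and 1.45 µm;
the pairwise contrast is reported in the conventional legend format with
Satterthwaite df; per-measure bias is below ~0.02 µm, RMSE ≈ 0.02–0.03 µm,
and every true paranode was detected. The recovered percent difference
(−14.1%) tracks this cohort's *realized* ground-truth difference (−14.6%)
to half a percentage point — note that the realized difference of a small
4-mouse cohort deviates from the injected −10.3% population effect simply
by mouse sampling, which is exactly the distinction `validate_recovery()`
makes visible.

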