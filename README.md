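# ribmap

Population-level mapping of rib fracture lines in chest-trauma cohorts.

In high-energy chest trauma, patients typically sustain many rib
fractures, and *where* the fracture lines sit along the ribs — and how
associated fractures of the clavicle, scapula, thoracic vertebrae or
sternum move them — matters for surgical planning. `ribmap` is for
trauma researchers who have per-fracture measurements (from CT
reconstructions or registries) and want reproducible fracture-frequency
maps and the statistics that go with them.

The core normalization reduces each fracture site to a dimensionless
coordinate along its rib,

```
p = 100 · d1 / (d1 + d2)
```

where `d1` is the along-rib distance from the costovertebral joint
(posterior, 0%) to the fracture site and `d2` the distance onward to the
costochondral junction (anterior, 100%). On top of it the package
provides:

* **Geometry** — a parametric 24-curve thorax template with arc-length
  parameterization (`default_template()`, `point_at_percent()`), plus CSV
  import of real centerlines;
* **Mapping** — cohort validation, sector (posterior/lateral/anterior)
  and position-bin classification (`validate_cohort()`,
  `classify_sector()`, `bin_index()`);
* **Aggregation** — rib × position-bin frequency matrices, boundary-
  corrected Gaussian density profiles, and 3D heat maps painted onto the
  template and exported as colored PLY (`frequency_matrix()`,
  `density_profile()`, `paint_heatmap()`, `write_heatmap_ply()`);
* **Statistics** — per-rib count tables, Mann–Whitney U comparisons of
  fracture positions by associated-fracture flags (exact enumeration for
  small samples, tie-corrected normal approximation otherwise), and
  chi-square / Fisher tests of upper-rib involvement
  (`position_comparison()`, `upper_rib_association()`);
* **Simulation** — a seeded synthetic-cohort generator with known effect
  sizes for parameter-recovery and null-calibration studies
  (`generate_cohort()`, `recover_effects()`);
* **Pipeline** — `run_pipeline()` ties everything together and writes
  `matrix.csv`, `density.csv`, `heatmap.ply`, `report.json`,
  `report.txt`; a thin CLI wrapper lives in `inst/scripts/ribmap.R`.

## Worked example

```r
library(ribmap)

percent_position(266.10, 36.80)
#> [1] 87.85078
```

A fracture measured 266.10 mm from the spine end and 36.80 mm from the
anterior end sits 87.85% of the way along its rib — deep in the anterior
sector.

```r
sim <- generate_cohort(sim_params(n_patients = 300, seed = 42))
sim$cohort
#> <rib_cohort> 300 patients, 2067 fracture lines
#>   mean position 41.82% (SD 25.05), left share 50.4%

position_comparison(sim$cohort, "scapula")
#> <group_comparison> scapula (record level)
#>   yes: n = 423, 34.62% (SD 24.66)
#>   no:  n = 1644, 43.67% (SD 24.82)
#>   shift -9.05 points, U = 275024.5, p = 3.15e-11
```

Fracture lines of scapula-fracture patients sit about 9 percentage
points more posterior (closer to the spine) than those of other patients
— the generator's true shift is −7.5, and the rank-sum test detects it.

```r
upper_rib_association(sim$cohort, "clavicle")
#> <contingency_result> method = chi_square
#>      involved
#> flag  yes no
#>   yes  78  2
#>   no  177 43
#> chi-square = 13.369, p = 0.0002558; rates = 97.50% vs 80.45%
```

Clavicle-fracture patients almost always carry an upper-rib (1–3)
fracture; the unflagged baseline is lower. Finally, the 3D map:

```r
tpl <- default_template()
profiles <- lapply(1:12, function(r) density_profile(sim$cohort, r))
painted <- paint_heatmap(tpl, profiles)
write_heatmap_ply(painted, "heatmap.ply")   # view in MeshLab etc.
```

or in one call, reading/writing files:

```r
run_pipeline(run_config(patients = "patients.csv",
                        fractures = "fractures.csv",
                        out_dir = "out"))
```

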