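# mandimorph

Longitudinal micro-CT morphometry of continuously erupting (elodont)
dentition in rodent and lagomorph mandibles.

Rodent incisors grow continuously and are worn back by gnawing; because
the two hemi-mandibles articulate through a non-bony symphysis, an animal
can unload one side. A unilateral mandible defect that degrades
load-bearing therefore shows up as *ipsilateral neglect* — most visibly a
longer erupted incisor crown on the defect side. mandimorph provides the
quantitative pipeline for studies built on this readout:

* **Registration** — rigid co-registration of follow-up scans to baseline
  by maximizing mutual information over all voxels (no landmarks),
  `MI = Σ p(f,m) log2[p(f,m)/(p(f)p(m))]`, with in-package Nelder–Mead
  simplex optimization over the six rigid parameters.
* **Reorientation** — the total-least-squares plane through the molar
  buccal cusp tips becomes the horizontal (occlusal) plane.
* **Morphometry** — in the incisor's mid-sagittal slice: labial path
  length (alveolar bone edge → tip), lingual path length (alveolar edge →
  gnaw ridge), occlusal path length (gnaw ridge → tip), the occlusal
  inclination angle of the erupted crown against the horizontal, and
  cheek-tooth heights (alveolar edge → highest buccal cusp).
* **Symmetry statistics** — per-animal left−right differences with 90%
  confidence intervals (paired *t* and bootstrap), and Z scores
  `z = (observed − baseline mean)/baseline SD` describing how far a
  post-defect measure sits from its baseline cohort.
* **Phantoms** — a voxel hemi-mandible generator with closed-form incisor
  geometry (arc centerline, bevelled crown, molar row, symphysis gap),
  surgical defect modes (critical-size defect, intermediate defect,
  complete ramus osteotomy with 1/3 mm gap, body defect), pose
  perturbation, and a parametric cohort simulator — so every stage is
  verifiable without animal data.

## Worked example

Generate a rat-like phantom at 0.1 mm voxels and measure the left incisor:

```r
library(mandimorph)
ph <- make_phantom(phantom_spec("rat", voxel_mm = 0.1))
ph$volume
#> <mct_volume> 98 x 296 x 142 voxels
#>   spacing (mm): 0.1 x 0.1 x 0.1
#>   origin  (mm): -4.85, -6.75, -0.75
#>   intensity:    [0, 1400]

pr <- extract_sagittal_profile(ph$volume, "left")
path_length(pr, "labial")    # 12.56 mm   (analytic truth 12.66)
path_length(pr, "lingual")   #  7.84 mm   (truth 7.88)
path_length(pr, "occlusal")  #  3.02 mm   (truth 3.06)
occlusal_angle(pr)           #  46.3 deg  (truth 46.0)
```

Every measurement lands within two voxel edge-lengths (0.2 mm) / 1° of
the phantom's closed-form ground truth; errors shrink as the voxel size
halves (tested down to 0.05 mm).

Simulate a baseline-symmetric cohort of 8 animals with a 2.3 mm labial
defect effect at the follow-up, and summarize symmetry:

```r
tab <- simulate_cohort(cohort_params("rat", n = 8, seed = 9))
rep <- symmetry_report(tab, level = 0.90, B = 10000, seed = 9)
rep$symmetry[, c("metric", "mean_diff", "t_ci_low", "t_ci_high",
                 "boot_ci_low", "boot_ci_high")]
#>     metric mean_diff t_ci_low t_ci_high boot_ci_low boot_ci_high
#> 1   labial   0.07564   -0.300    0.4509      -0.256       0.4815
#> 2  lingual  -0.09897   -0.253    0.0546      -0.241       0.0685
#> 3 occlusal   0.00275   -0.221    0.2264      -0.206       0.2332
```

Every baseline 90% CI contains 0 (left–right symmetry), while the
follow-up labial differences score far outside the baseline cohort:

```r
subset(rep$zscores, timepoint == "wk3" & metric == "labial")$z
#> 3.2 6.8 4.2 3.2 4.4 4.4 3.0 3.6     # defect side clearly flagged
```

`rep$plot` is the corresponding dot plot (per-animal differences with
both CIs). A full demo — phantom cohort, pose perturbation, registration,
measurement, statistics, ground-truth comparison — is

```r
run_end_to_end("demo_out")
```

## Command line

```sh
inst/cli/mandimorph phantom --preset rat --defect cro_wide --noise 0.05 --seed 7 --out dir/
inst/cli/mandimorph register --fixed a.nii.gz --moving b.nii.gz --out t.json --bins 64
inst/cli/mandimorph measure --manifest manifest.csv --out results/
inst/cli/mandimorph stats --metrics results/metrics.csv --out results/
inst/cli/mandimorph demo --out demo/
```

Manifests are CSVs with columns `animal_id, species, timepoint, path`;
every run writes `run.json` with the resolved configuration, and rerunning
with the same seeds reproduces outputs byte-for-byte.

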