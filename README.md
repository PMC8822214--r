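# rbcmorph

Automated morphometry of red blood cells (RBCs) in Wright-Giemsa-stained
peripheral-blood-smear micrographs, for hematology labs and image-analysis
researchers who want the mean RBC area per subject — a marker that helps
separate megaloblastic anemia (MA) from aplastic anemia (AA),
myelodysplastic syndromes (MDS) and normal blood — together with the
cohort statistics used to evaluate it against the standard
complete-blood-count indices (MCV, MCH, MCHC, RDW).

## Method

From a 1000x RGB field of view with calibration `c` (um/px):

1. **Segmentation** — Otsu's threshold on the HSV *saturation* channel
   (stained cells are saturated, background pale), plus an optional
   gray-level edge refinement.
2. **Single-cell location** — outer contours of 8-connected components
   (central pallor holes filled); contours under 0.5 um^2 are noise, in
   [0.5, 10) um^2 "pending" debris. With `S_mean` the mean area of the
   remaining contours, an effective single cell must satisfy
   `a * S_mean < area < b * S_mean` (defaults `a = 0.3`, `b = 5`) and be
   convex (contour area / hull area >= 0.9); areas at or above
   `b * S_mean` are merged clumps and excluded.
3. **Classification** — per-cell mean gray `G` vs image mean `Mg` over
   all located cells: `G / Mg >= 0.8` is an RBC, below nucleated.
4. **Area** — with `r` the exact minimum-enclosing-circle radius and
   `Pmean` the mean ratio of contour-point distances to `r`,

   ```
   Si = pi * (r * c)^2        # enclosing-circle area, um^2
   Sr = Si * Pmean^2          # reported (roundness-corrected) cell area
   ```

   A cell is a *recall RBC* — the only kind averaged — when every radial
   ratio exceeds 0.85 and `Si` lies in `(a * S_mean, b * S_mean)`.

Per subject the mean, SD and CV (`100 * SD / mean`) of `Sr` are reported;
`analyze_cohort()` then runs normality-dispatched group comparisons
(Shapiro-Wilk, Levene; pooled t / Welch t / Wilcoxon rank-sum),
area-vs-CBC correlations (Pearson or Spearman by normality), and ROC
analyses of area, MCV and their logistic-combined predicted probability.

A synthetic smear generator (`generate_scene()`, `generate_cohort()`)
provides ground-truth fields and cohorts with the published group
moments, so the whole pipeline is testable without clinical data.

## Worked example

```r
library(rbcmorph)

scene <- generate_scene(scene_spec(seed = 7))   # known ground truth
meas  <- measure_smear(scene$image)
meas
#> <smear_measurement> 'synthetic-seed7': 14 contours (14 effective, 0 merged, 0 pending, 0 rejected)
#>   S_mean = 49.22 um^2, Mg = 172.6
#>   12 recall RBCs: mean Sr = 44.70 um^2, SD = 6.63, CV = 14.83%
```

The 12 generated RBCs (true mean area 46.03 um^2) are all recalled and
measured at 44.70 um^2 (−2.9%); the two nucleated cells are recognized by
their low gray ratio (~0.60) and kept out of the average.

```r
cohort <- generate_cohort(seed = 1)   # 25/25/68/64 subjects, published moments
analyze_cohort(cohort)
#> Group summaries:
#>   group  n mean_area_um2 sd_area_um2 ... cv_percent
#>  normal 25          44.8        3.69 ...       8.22
#>      AA 25          41.7        4.08 ...       9.80
#>     MDS 68          46.7        6.23 ...      13.34
#>      MA 64          51.6        8.29 ...      16.05
#>
#> Pairwise comparisons:
#>  group_1 group_2 test_used statistic  p_value
#>   normal      MA   welch_t     -5.34 7.64e-07
#>       AA      MA   welch_t     -7.53 5.78e-11
#>      MDS      MA    t_test     -3.86 1.77e-04
#>  ...
#>
#> ROC (disease vs normal):
#>  disease                marker   auc  p_value
#>       MA                  area 0.781 3.99e-05
#>       MA                   mcv 0.973 5.15e-12
#>       MA predicted_probability 0.981 2.22e-12
#>  ...
```

MA stands out from every other group at p < 0.001 and the combined
area+MCV marker dominates each single one — the qualitative pattern the
measurement is meant to expose. A thin command-line wrapper with
subcommands `measure`, `stats`, `synth-scene` and `synth-cohort` is
installed at `inst/cli/rbcmorph.R`.

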