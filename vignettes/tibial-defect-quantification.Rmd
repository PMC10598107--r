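---
title: "Quantifying periprosthetic tibial bone defects from CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying periprosthetic tibial bone defects from CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(tibialCT)
```

## The problem

Before revision total knee arthroplasty (rTKA) the surgeon needs to know how
much tibial bone will remain once the failed component, its cement mantle and
any osteolytic voids are removed. Plain radiographs systematically understate
this loss — metal obscures lucencies — while a 3D segmentation of the
preoperative CT can measure it volumetrically and grade it on the AORI
(Anderson Orthopaedic Research Institute) scale. `tibialCT` implements that
measurement chain: Hounsfield-unit (HU) threshold segmentation, partition of
the proximal tibia into the three zonal-fixation zones, per-zone volume
accounting, automatic AORI grading, and the ordinal agreement statistics used
to compare grading methods. Because no patient CTs accompany the published
cohort, the package also ships a digital phantom generator that synthesizes
periprosthetic tibial CT volumes with exact voxel-level ground truth; every
pipeline stage is validated against that truth.

## Segmentation model

Each voxel is assigned one of six classes by its HU value:

| class   | HU interval      | rule |
|---------|------------------|------|
| implant | [2000, 3071]     | threshold |
| cement  | [300, 1400]      | threshold *and* within `cement_adjacency_mm` (default 3 mm, Euclidean) of the implant |
| bone    | [200, 1800]      | threshold, minus voxels claimed by cement |
| defect  | [-1024, 200)     | threshold *and* inside the bone envelope |
| background | —             | everything else |

Two HU ranges are ambiguous and get explicit rules. Cement overlaps
cancellous bone (both fall in 300–1400 HU); a cement mantle is by definition
at the bone–implant interface, so cement wins only inside the adjacency
shell, computed with an exact Euclidean distance transform. The gap
1800–2000 HU (above bone, below implant) is a partial-volume rim at the
bone–metal interface: it goes to implant within one voxel of the implant
mask, else to bone. A voxel at exactly 200 HU — shared by the defect and
bone intervals — is bone: the conservative choice, since interface artifacts
read as osteolysis and would otherwise inflate defect volumes.

The *bone envelope* that contains defects is the morphological closing of
bone ∪ cement ∪ implant with a ball of radius `closing_radius_voxels`
(default 3), plus any fully enclosed air cavity (hole filling). Closing
bridges narrow surface openings — the computational stand-in for the manual
refinement a human segmenter performs — while hole filling guarantees that an
osteolytic void deeper than the closing ball still counts as defect rather
than background. Defect-range voxels outside the envelope are exterior air.

Bone is then split into tibia and fibula by 26-connectivity connected
components: the largest component is the tibia, the largest remaining
component lateral to it the fibula; stray fragments within 2 voxels of the
tibia are merged back, others dropped. Ties in component size are broken
toward the proximal half of the volume.

## Zones and the rule of the square

The region of interest runs from the tibial cut (the most proximal implant
slice, or the most proximal bone slice without an implant) to the most
distal depicted tibial slice. Along this axis:

* **epiphysis**: cut plane to the widest mediolateral level of the fibular
  head;
* **metaphysis**: from there to the metaphyseal–diaphyseal junction given by
  the *rule of the square* — a depth below the cut equal to the widest
  epiphyseal width W;
* **diaphysis**: the remainder.

W is measured as the maximal mediolateral extent of the tibial foreground
over the epiphyseal slices. Where to anchor the square's top edge is not
uniquely defined by the rule; we anchor it at the tibial cut, the joint-line
surrogate available in every scan. Zone boundaries are full transverse
planes (slice indices), because volumes are reported per zone along the
length of the bone, not inside the square's lateral silhouette. Slice
coordinates in the public API are 0-based with half-open ranges, so with W =
80 mm at 0.625 mm slices a cut at slice 10 puts the junction at slice
10 + 128 = 138.

Two distinct fibular landmarks are deliberate: the zone partition uses the
*widest* fibular-head level, while AORI type-II grading uses the fibular
*tip* plane — the classification's original criterion. The tibial tubercle
level cannot be recognized in image content by this pipeline and is a
supplied landmark (`tubercle_below_cut_mm`, default 40 mm below the cut, in
the anatomical range for an average-height adult).

## Volume accounting

Per scope (total ROI and each zone), class volumes are voxel counts times
the voxel volume. Derived quantities follow the identities

* total defect = implant + cement + defect (implant counted only inside the
  ROI),
* total tibial volume = bone + total defect,
* remaining-bone ratio = bone / total tibial volume,

held exactly at voxel resolution, so zone rows sum to the ROI row to the
last voxel. Fibular bone is excluded from every tibial tally. Ratios of
empty scopes are `NA` and are dropped (with a message) from cohort
summaries. Stored values are unrounded; displays round volumes to 3
decimals and ratios to 4, since sub-voxel precision is spurious.

## AORI grading

Grades are coded I = 1, IIa = 2, IIb = 3, III = 4 and decided purely from
defect geometry against two transverse planes: a defect is type III when its
volume distal to the tubercle plane exceeds `min_involvement_cm3`, type II
when its volume distal to the fibular-tip plane does (IIb when both condyles
are involved past that plane, IIa otherwise), else type I. The involvement
threshold defaults to 0.5 cm^3: the classification's verbal criteria
("crossing", "involving a condyle") carry no number, and a small positive
volume suppresses single-voxel noise while staying far below any surgically
relevant defect. The condylar split is the sagittal plane through the
mediolateral centroid of the diaphyseal tibial shaft, which is robust to
plateau defects. Component subsidence and ligament damage — clinical type-III
criteria — are not inferable from a static preoperative image and are out of
scope. When a central defect crosses the type-II plane but neither condyle
alone exceeds the threshold, the grade is IIa (one-condyle equivalent), the
less severe reading.

## The phantom generator

The phantom is the package's ground-truth instrument, not a physics
simulation. A tibia is stacked elliptical cross-sections: a flare of the
given epiphyseal width (default 70 mm) held for 12 mm below the cut, then
tapering quadratically to a 12 mm-radius shaft over 75% of the 95 mm bone
length; anterior–posterior axes are 0.8 of mediolateral. The fibula is a
separate 5 mm-radius cylinder with an 8 × 8 × 10 mm ellipsoidal head whose
centre (the widest level, 22 mm below the cut) and top (the tip plane) are
known landmarks; it never touches the tibia. The implant is a tray covering
the resection surface plus a cemented stem; the cement mantle is defined as
bone within `cement_thickness_mm` (default 3 mm) of implant voxels *using the
same distance-transform semantics as the segmentation*, so a noise-free
phantom re-segments to its own truth up to a one-voxel boundary shell — this
consistency is what makes the phantom a usable oracle. Defects are
ellipsoids carved from bone, placed by zone and side or at explicit
coordinates, with optional rescaling to an exact analytic target volume
(4/3 π abc); specs whose defects poke out of the bone envelope are rejected.
Noise is additive Gaussian HU (the seed feeds *only* noise and streak phase),
and optional radial streaks emulate the residual metal artifacts of MAR
reconstructions without modelling their physics. Default grids are
152 × 112 × 176 voxels at 0.7 × 0.7 × 0.625 mm — the study's slice thickness
with a typical in-plane resolution; tests that need exact isotropy use
0.625 mm cubed.

What the phantom does *not* emulate: cortical/cancellous HU texture,
beam-hardening, motion artifacts, anatomical variation beyond the
parameterized geometry, and soft tissue. Passing phantom tests therefore
demonstrates the pipeline's geometric and numerical correctness, not its
robustness to real scanner data; the published agreement statistics enter
through the recorded cohort tables instead.

The 12-scenario grid (`aori_scenarios()`) covers the grade space — for each
zone a medial, lateral, bicondylar and "deep" (distal-to-tubercle) defect
pattern — and every scenario's truth grade and pipeline grade must coincide.

## Cohort simulation

`simulate_cohort()` draws an intraoperative grade per knee from the recorded
cohort margins (21/29/35/14 over 99) and then CT and X-ray grades from the
row-normalized recorded contingency tables, independently given the
intraoperative grade. The expected contingency table of a large simulated
cohort is then exactly the recorded table, so empirical kappas converge to
the published 0.663 (CT) and 0.304 (X-ray) — a consistency check of the
whole ordinal-statistics stack. Conditional independence of CT and X-ray
errors given the intraoperative grade is an assumption; the published
pairwise tables cannot identify the three-way dependence.

## Statistical conventions

* **Cohen's kappa** is unweighted — the published values are reproduced by
  the unweighted statistic on the recorded tables — with linear/quadratic
  weighting available but not default. The null-hypothesis p-value uses the
  large-sample normal approximation. Landis–Koch bands are applied with
  inclusive upper edges ((0.60, 0.80] substantial, etc.).
* **Spearman correlation** uses midranks for ties (product-moment
  correlation of midrank vectors) and a two-sided t approximation with
  n − 2 degrees of freedom.
* **Ordinal median/IQR** uses nearest-rank quantiles (R type 3), which
  return observed grade values and reproduce all three recorded median/IQR
  triples — X-ray 1 [1–2], intraoperative 2 [2–3], CT 2 [1–3]. The
  inverse-ECDF convention (type 1) does not: it yields an X-ray upper
  quartile of 3.
* **Friedman test** uses within-row midranks with tie correction; post-hoc
  comparisons are pairwise Wilcoxon signed-rank (normal approximation) with
  Bonferroni adjustment, the common companion in clinical statistics
  software; the choice is an assumption, as the original analysis does not
  name its procedure.
* **Kruskal–Wallis** is tie-corrected, with Dunn post-hoc z tests and
  Bonferroni adjustment.
* **Power analysis** uses the Fisher z approximation:
  sensitivity = tanh((z₁₋α/₂ + z_power)/√(n−3)); at n = 99, α = 0.05 and 80%
  power this gives 0.28. The Monte-Carlo check simulates bivariate-normal
  samples at the latent correlation whose Spearman value equals the target
  (ρ_s = 6/π·asin(ρ/2)), since the Spearman statistic is slightly attenuated
  on normal data.
* Exact small-sample p-values are out of scope; all p-values are
  large-sample approximations.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_spec(defects = list(defect_spec("metaphysis", "medial")))
ph <- generate_phantom(spec)
res <- analyze_ct(ph$ct)
res$grade          # AORI IIa (2)
res$volumes        # per-zone volume report
autoplot(res$volumes)

stats <- reproduce_agreement_stats()
stats$kappa        # 0.663 "substantial" (CT), 0.304 "fair" (X-ray)
```

## Numerical choices and limitations

Problem sizes in the test-suite phantoms (about 0.9–3.5 million voxels) were
chosen to exercise every landmark and zone at realistic anatomy while
generating in seconds; the geometry, not the grid, carries the validity of
the checks. Distances use an exact separable Euclidean transform
(anisotropic-aware); connected components use 26-connectivity; closing-based
envelopes can add a fillet of exterior air in sharp concave corners, which
stays within one voxel of the surface for right-angle geometry and is the
reason re-segmentation fidelity is stated up to a one-voxel shell.
Determinism is end-to-end for a fixed seed and configuration. Known
limitations: single bone class (no cortical/cancellous distinction), no
automatic tubercle detection, no DICOM ingestion (NIfTI-1 only), and no
claim of reproducing the real cohort's absolute zone-defect shares or
zonal correlations, which depend on the unreleased patient scans.
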