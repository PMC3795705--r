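# discdiff

Quantification of gadolinium contrast agent transport into lumbar
intervertebral discs from serial post-contrast T1-weighted MRI — with a
synthetic spine phantom so the whole pipeline is testable without patient
data.

The intervertebral disc is avascular: its cells depend on small solutes
diffusing in from endplate capillaries, and failure of that route is a
candidate trigger of disc degeneration. Post-contrast MRI probes the route
in vivo: after injection of a gadolinium agent, T1-weighted scans at
5 min, 10 min, 2 h, 4 h and 6 h trace the agent from the vascularized
subchondral bone through the endplate zone into the disc centre. The
package is written for researchers analysing such serial acquisitions and
for methodologists who need a ground-truthed phantom to validate every
stage of the analysis.

## What it implements

* **Landmark-based layered segmentation** — from six operator points per
  disc (A, B, C on each endplate border): piecewise-linear borders, five
  depth-proportional disc layers (endplate zone, peripheral, central:
  each EPZ/peripheral band is 1/5 of the local disc thickness), a 6-pixel
  subchondral bone band (4.98 mm at 0.83 mm pixels) with a 1-pixel gap,
  disc height as the mean of |A1A2| and |C1C2|, and the exclusion rules
  (height ≤ 3 mm, severe spondylolisthesis; defect/Modic-free subset for
  time curves).
* **Enhancement quantification** — per ROI and post-contrast time point,
  `enhancement = mean(post) − mean(pre)` (no PRE normalization), plus the
  CSF-adjusted T2-weighted signal intensity (disc mean over a 3×5-pixel
  CSF reference mean) as a continuous hydration index.
* **Cohort statistics** — two-sided rank-sum (exact tie-aware permutation
  for small samples), Kruskal–Wallis with Dunn's multiple comparisons
  gated on the omnibus test, Spearman correlations, partial-SS univariate
  ANOVA covariate sets, one-sample t noise check, Shapiro–Wilk gate, and
  the Modic-change grouping rule (I + II or any I/II ⇒ MCI/II).
* **Synthetic phantom** — stacked-disc sagittal slices with a
  difference-of-exponentials blood pool, Crank–Nicolson solution of
  1-D diffusion with permeable (Robin) endplate boundaries, an optional
  delayed perfusion exchange term for vascularized (Modic/irregular)
  discs, hydration-driven T2 rendering with a bright CSF band, additive
  Gaussian noise, and exact ground-truth landmarks, masks and
  concentration fields.
* **Pipeline + I/O** — `run_pipeline()` executes
  simulate → segment → quantify → analyze into a run directory with
  NIfTI images and label maps, landmark JSON, tidy CSVs, a text report
  and a checksummed manifest; reruns with the same seed are
  byte-identical.

The transport model, in the field's standard notation: blood pool
`C_b(t) = A (e^{−t/τ_e} − e^{−t/τ_a})`; disc concentration
`∂c/∂t = D ∂²c/∂x² + v (C_s(t) − c)` on `x ∈ [0, h]` with endplate flux
`−D ∂c/∂x|₀ = P (C_b − c(0))` (and symmetrically at `x = h`), where `C_s`
is the blood curve through a two-stage extravasation lag. Enhancement is
modelled as linear in concentration.

## Worked example

```r
library(discdiff)

co  <- generate_cohort(phantom_config(), n_discs = 60, seed = 1)
q   <- quantify_cohort(co)
ex  <- apply_exclusions(co$metadata, q$heights)
res <- run_paper_analyses(q$enhancement, q$quant, ex$retained, q$heights)

subset <- select_timecurve_subset(ex$retained)
tc <- assemble_timecurves(q$enhancement, subset)
tc[tc$roi == "Central", c("time", "n", "q25", "median", "q75")]
#>          time  n     q25 median    q75
#> 1   POST_5MIN 24 -10.998 -3.737  2.665
#> 8  POST_10MIN 24  -6.245 -2.516  5.283
#> 15    POST_2H 24  -7.709 -1.498  4.418
#> 22    POST_4H 24   2.476  9.068 16.656
#> 29    POST_6H 24   4.189 14.989 20.643
```

The medians show the canonical transport signature: central enhancement
indistinguishable from zero at 5 min through 2 h (in this 24-disc subset
the agent has not yet crossed the endplates), rising by 4 h, and peaking
at 6 h. The quartile spread (~±7 signal units at the ROI level) is the
design noise floor — per-pixel σ = 80 averaged over a ~100–200-pixel ROI
and differenced against PRE; larger cohorts tighten the medians toward
the noise-free curve. Heights estimated from the landmarks reproduce the generating
heights exactly, and `res$results` contains one row per statistical test
(analysis, time, item, statistic, p, significance at 0.05).

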