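# cranmorph

Geometric morphometrics for skeletal-ancestry questions: given 3D
landmark configurations of crania from two candidate source populations
and one or more later target populations, `cranmorph` estimates what
fraction of each target population derives from each source.

It is written for bioarchaeologists and biological anthropologists
working with landmark data (34 basicranial landmarks in the reference
design, but any k ≥ 3 with a bilateral pairing), and implements the full
chain:

* **Generalized Procrustes analysis** — remove translation, size
  (unit centroid size, CS = √Σᵢ‖xᵢ − x̄‖²), and orientation (SVD/Kabsch
  rotations, reflections excluded), with a reproducible principal-axis
  output frame.
* **Object-symmetry symmetrization** — mirror and relabel each
  configuration, joint GPA of originals + mirror images, and per-specimen
  averaging of the two aligned copies, discarding bilateral asymmetry.
* **Ordination** — PCA of the symmetrized Procrustes coordinates and
  canonical variates analysis (g − 1 canonical axes maximizing
  between- to pooled within-group variance).
* **Stepwise cross-validated PC reduction** — PCs are added in variance
  order to a leave-one-out cross-validated LDA until the
  cross-validation percentage first drops below its running maximum;
  the maximizing prefix is retained.
* **MANOVA** — Wilks' Λ = det(W)/det(W + B), Rao's F approximation, and
  multivariate partial η² = 1 − Λ^(1/s), overall and pairwise.
* **Two-source LDA attribution** — pooled-covariance linear discriminant
  on the retained PCs (equal priors), with a posterior threshold:
  an individual is attributed to the arg-max source only if its winning
  posterior is ≥ 0.55, otherwise it is reported as unattributable.
  Group summaries report both hard-attribution percentages and the
  mean-posterior variant, which treats posteriors as fractional ancestry
  and so allows admixed individuals.
* **Intra-observer error protocol** — greatest Procrustes distance among
  repeated digitizations of one cranium vs the smallest distance between
  distinct crania.
* **Synthetic-study generator** — four-group studies at the reference
  design sizes (236 specimens) with known per-specimen origins, for
  validation and power exploration.

Landmark files are read and written in CSV, whitespace-table, TPS, and
Morphologika dialects (`read_landmarks` / `write_landmarks`).

## A worked example

```r
library(cranmorph)

params <- simulation_params(seed = 1)   # reference design, known truth
sim    <- simulate_study(params)
report <- run_study(sim$dataset, params$scheme, per_sex = FALSE)
print(report)
```

```
Cranial shape ancestry study

== Chain mixed (n = 236) ==
  CV variance fractions: 80% 12% 8%
  retained PCs: 1 (8% of shape variance)
Wilks MANOVA: lambda = 0.477, F(3, 232.0) = 84.679, p = 4.897e-37, partial eta^2 = 0.52
  source LDA leave-one-out accuracy: 96.6%
Attribution summary for EARLY_AS (n = 47):
  DANISH            61.7%
  PREMED_BRITISH    38.3%
  UNATTRIBUTABLE     0.0%
  mean posteriors: DANISH 0.59, PREMED_BRITISH 0.41
Attribution summary for MIDDLE_AS (n = 42):
  DANISH            40.5%
  PREMED_BRITISH    59.5%
  UNATTRIBUTABLE     0.0%
  mean posteriors: DANISH 0.40, PREMED_BRITISH 0.60
```

Reading this: the four groups differ strongly in basicranial shape
(Λ = 0.477, p ≪ 0.001), the two sources are highly separable
(leave-one-out accuracy 96.6%), and the attribution recovers the
generating mixture — this dataset was simulated with a Danish-origin
fraction of 0.65 for the Early group and 0.35 for the Middle group, and
the realized Early fraction for this seed was 0.617; the hard-attribution
estimate is 61.7% and the mean-posterior estimate 0.59.  The Early
group is Danish-majority and the Middle group British-majority, the
qualitative reversal the design encodes.

Per-sex chains (`per_sex = TRUE`, the default) repeat the whole analysis
independently for females and males, as recommended when sexual
dimorphism would otherwise confound group differences.
`write_study_report(report, dir)` exports the CVA, MANOVA, and
attribution tables as CSV; `plot(report$chains$mixed$cva)` draws the
canonical-variates scatter.

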