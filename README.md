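# renalmps

Kidney organ-on-chip perfusion data to human renal clearance and
whole-body pharmacokinetics.

## The problem

Renal drug excretion combines glomerular filtration, transporter-mediated
tubular secretion and passive, pH-dependent reabsorption. Secretion is
hard to measure in vitro: static monolayers lose transporter expression,
and extrapolation from transfected cell lines assumes a single transporter
family. A vascularized proximal-tubule microphysiological system (MPS) — a
dual-channel chip with an endothelial vessel and a primary-epithelium
tubule perfused at 1 uL/min — retains secretory function, and its effluent
time courses can be reduced to transport clearances. `renalmps` implements
the full translation from those device readouts to human predictions, for
morphine and its active, renally cleared metabolite
morphine-6-glucuronide (M6G), in healthy kidneys and across chronic
kidney disease (CKD). Its audience is DMPK/pharmacometrics scientists
working with organ-on-chip data.

## The models at its core

**Device reduction.** At steady state, apparent clearance is efflux rate
over vascular concentration, per arm (control → transport; transporter
inhibitors → passive diffusion); their difference is active secretion.
Flow correction gives intrinsic values, `CL_int = Q·CL_app/(Q − CL_app)`,
and permeability `Papp = CL_int,passive / SA`.

**In vitro–in vivo extrapolation.** Secretion scales by cell number
(5000 cells/device, 60e6 cells/g kidney, 300 g kidney), split equally
over the proximal subsegments S1–S3.

**Mechanistic kidney model.** Six filtrate compartments in series (S1–S3,
loop, distal tubule, collecting duct) with water reabsorption from
120 mL/min (GFR) down to 1.2 mL/min urine flow and filtrate pH falling to
6.3. Unbound filtration (`GFR·fu_p·C_p`), segmental secretion, and
bidirectional passive permeation of the unionized species
(Henderson–Hasselbalch; measured permeability corrected to the unionized
fraction at the assay pH). The whole-kidney exchange area is calibrated
once against the morphine population clearance (8.24 L/h) and then
frozen; M6G, per-donor, and CKD predictions are out-of-sample. CKD is the
intact-nephron rule: flows and secretion scale with GFR.

**Whole-body PBPK.** Twelve perfusion-limited tissues, lung in series,
portal drainage into a well-stirred liver (morphine intrinsic clearance
back-calculated from `CL_h = CL_total,iv − CL_r`), 10% of hepatic
elimination forming M6G in the liver, and the mechanistic kidney embedded
for both analytes. Sampling defaults to a peripheral arm vein.

**Evaluation.** Absolute average fold error
`AAFE = 10^(mean |log10(sim/obs)|)` with a twofold acceptance rule, plus
non-compartmental utilities (AUC, MRT, Vss) used as internal oracles.

## Worked example

```r
library(renalmps)

# one synthetic device with known truth: 3 uL/h transport, 1 uL/h passive
truth <- mps_ground_truth(cl_app_transport = 3, cl_app_passive = 1,
                          noise_cv = 0.15, seed = 7)
arms <- generate_effluent_series(truth)      # control + inhibitor, 2-24 h
cs <- reduce_donor(arms$control, arms$inhibitor, nominal_conc = 1000)
cs
#> <clearance_set> donor synthetic (synthetic)
#>   CL_app  transport 3.14, passive 0.97, active 2.17 uL/h
#>   CL_int  transport 3.31, passive 0.985, active 2.32 uL/h
#>   Papp    5.54 x 1e-6 cm/s
```

The apparent clearances recover the generating truth (3 and 1 uL/h) within
the 15% measurement noise. Scaling to the whole kidney and predicting
renal clearance:

```r
cl_sec <- scale_secretion(cs$cl_int_active)   # 8.36 L/h whole-kidney secretion
drug <- morphine_renal_params(secretion_total = cl_sec, papp = cs$papp)
simulate_renal_clearance(drug)                # 8.21 L/h
```

Whole-body simulation and scoring against (here synthetic) observations:

```r
parent <- morphine_model(clr = 8.24)   # derives CL_h = 75.3, CL_int = 518 L/h
sim <- simulate_parent_metabolite(parent, m6g_model(),
                                  dose = dose_regimen(10, duration_h = 1/12),
                                  horizon = 24)
sim
#> <pbpk_sim> morphine -> M6G, 482 output times to 24 h, max |mass error| 6.8e-08%

obs <- generate_clinical_pk(sim$parent,
                            obs_noise_model(0.2, c(0.5, 1, 2, 4, 8, 12, 24),
                                            seed = 9))
aafe(sim$parent, obs)
#> AAFE = 1.114 over 5 points (2 excluded): within the twofold criterion
```

The two excluded points fell below the 3.5 nM quantification limit. A CKD
sweep is one call:

```r
clr_vs_gfr_profile(list(morphine_renal_params(), m6g_renal_params()),
                   gfr_grid = c(3, seq(10, 120, by = 10)))
```

`run_full_pipeline()` chains all stages (generate → reduce → scale →
kidney model → PBPK → AAFE) and writes per-stage CSV/JSON artifacts with a
YAML manifest.

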