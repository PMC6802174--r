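# polyamineMC

Coarse-grained Monte Carlo analysis of how trivalent polyamines bind
double-stranded DNA, plus slope-based binding-constant estimation from NMR
titration series.

## The scientific problem

Spermidine (SPD, [N-3-N-4-N]) and norspermidine (NSPD, [N-3-N-3-N]) differ
by one methylene between their second and third amine, yet they differ
markedly in how they compact DNA and modulate gene expression, and NMR
titrations show NSPD binding DNA several-fold more strongly when polyamine
is scarce relative to phosphate. This package implements a minimal
statistical-mechanical model to isolate the mechanism: a rigid bead-rod
polyamine (+1 on each ammonium; SPD: 10 beads, charges at 1/5/10; NSPD: 9
beads, charges at 1/5/9) sampled by Metropolis Monte Carlo around a
soft-cylinder DNA segment (10 diametric phosphate pairs, charge −1,
σ = 0.476 nm, on a 1 nm cylinder, 0.34 nm apart, axially periodic cell of
height 3.4 nm) with screened-Coulomb electrostatics

    u_ij / kBT = Γ z_i z_j exp(−r/λ_D) / r        (Γ = 1.36 kBT·nm, T = 298 K)

From the sampled configurations the package computes:

* the conditional free-energy landscape `F(r, cos θ)/kBT = −ln ρ5(r, cos θ)`
  of the central ammonium (radial distance `r`, orientation cosine of the
  #1→#5 vector), Jacobian-normalised so a non-interacting rod is flat;
* the species difference ΔF = F_SPD − F_NSPD;
* binding constants from the criterion that **all three ammoniums
  simultaneously** sit within 0.453 nm of phosphates (the 105° hydrogen-bond
  contact geometry), converted via bound/free phase-space volumes split at
  R_cut = 1.3 nm and |cos θ| = 0.5:

      K = (N_b/V_b) / (N_f/V_f) / [Phosphate]

* two-regime titration fits: under fast binding with an NMR-invisible bound
  fraction, `1/I_rel = 1 + K·[DNA]`, with slopes K2 below and K1 above a
  0.5 mM breakpoint, plus residual-bootstrap confidence intervals and a
  seeded synthetic-titration generator.

## Worked example

```r
library(polyamineMC)

dna  <- build_dna()                 # 10 phosphate pairs, R_DNA = 1 nm
cell <- build_cell()                # R_cyl = 2.591 nm, H = 3.4 nm

for (sp in c("SPD", "NSPD")) {
  tr <- run_mc(build_polyamine(sp), dna, cell, energy_params(), seed = 1)
  print(binding_K(tr))
}
```

```
<binding_result> SPD: N(binding) = 0.003695, K = 1.955e-05 mM^-1 (se 1e-06)
<binding_result> NSPD: N(binding) = 0.00583, K = 3.091e-05 mM^-1 (se 1.4e-06)
```

With 2×10⁶ Metropolis moves per run (seconds of compute), 0.37% of SPD
samples but 0.58% of NSPD samples have all three ammoniums in contact with
phosphates — the single extra methylene of SPD prevents its #10 ammonium
from reaching a phosphate while #1 and #5 are engaged. The resulting
binding-constant ratio K_NSPD/K_SPD ≈ 1.58 (the absolute K values are
model-scale quantities; the ratio is the physical result). The landscape
side:

```r
tr <- run_mc(build_polyamine("NSPD"), dna, cell, energy_params(), seed = 1)
g  <- accumulate_rho5(tr, seq(0, cell$R_cyl + 0.05, 0.05),
                      seq(-1, 1, 0.1), cell)
locate_minimum(g, r_max = 1.3)
```

```
$r 0.925   $mu 0.95   $theta_deg 18.2   $F 0.483
```

The free-energy minimum sits just inside the soft DNA boundary at
near-axial orientation. And the titration estimator on synthetic data
(true slopes 0.36 / 0.18 mM⁻¹, 2% intensity noise):

```r
d   <- generate_titration(titration_spec(noise_sd = 0.02, seed = 1))
fit <- fit_two_regime(invert_normalize(d))
ci  <- bootstrap_ci(invert_normalize(d), n_boot = 999, seed = 1)
```

```
<titration_fit> K2 (low) = 0.3206 mM^-1, K1 (high) = 0.1945 mM^-1, break = 0.5 mM
K2 95% CI [0.218, 0.423]; K1 95% CI [0.142, 0.251]
```

`run_pipeline(default_config(out_prefix = "out/run"))` chains the whole
analysis (both species, landscapes, ΔF, K ratio, titration fit) and writes
CSV/JSON/XYZ artifacts with a manifest.

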