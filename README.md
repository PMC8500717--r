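# tmfret

Analysis of **time-resolved transition metal ion FRET (tmFRET)**
experiments measured in the frequency domain.

tmFRET pairs a small fluorescent noncanonical amino acid donor (Acd or
Anap, incorporated by amber-codon suppression) with a nonfluorescent
transition-metal acceptor — Cu²⁺ carried by a cysteine-reactive TETAC
chelator or bound to an engineered di-histidine motif. Energy transfer
quenches the donor with efficiency E(r) = 1/(1 + (r/R₀)⁶), steeply
distance-dependent over ~10–25 Å, so the donor fluorescence **lifetime**
encodes the *distribution* of donor–acceptor distances: the structural
heterogeneity within a conformational state and the occupancies of
distinct states. That turns a lifetime measurement into a measurement of
conformational energetics — from the occupancy A₂ of a ligand-bound state,
K = A₂/(1−A₂) and ΔG = −ln K (kT).

The package is aimed at spectroscopists analyzing frequency-domain
(FastFLIM-style) lifetime data of conformationally heterogeneous proteins,
and at method developers who need a fully synthetic, ground-truth-known
test bed for such analyses.

## What it implements

* **Forward model** (`forward_response()`): donor decays with one or two
  exponential components; one- or two-Gaussian distance distributions
  P(r) with a donor-only fraction f_D; FRET-quenched time constants
  τ_DA(r) = τ_D / (1 + (R₀/r)⁶); phase delay φ_ω = arctan(N_ω/D_ω) + ωt₀
  and modulation ratio m_ω = √(N_ω² + D_ω²) with background mixing via a
  measured background phasor; apparent quenching efficiency
  E = 1 − J/Σαᵢτ_Dᵢ. Background/IRF correction by `correct_response()`.
* **Staged χ² fitting** (`fit_condition()`, `fit_protocol()`): bounded
  Levenberg–Marquardt with Latin-hypercube multi-starts over the
  12-parameter vector (f_D, τ_D1, α₁, τ_D2, R₀, r̄₁, σ₁, A₂, r̄₂, σ₂, t₀,
  f_B), with the parameter-freezing protocol across a donor-only →
  +acceptor → +ligand → reversal sequence.
* **Phasor analysis** (`to_phasor()`, `universal_circle_residual()`,
  `chord_fraction()`): model-independent single-exponential tests against
  the universal circle and two-state mixing by chord projection, with a
  brightness correction from intensity to population fractions.
* **Steady-state quenching** (`fraction_unquenched()`,
  `fret_efficiency_corrected()` with Monte-Carlo uncertainty,
  `forster_invert()`, photobleaching `exp_decay_fit()`, `hill_fit()`).
* **Förster distance machinery** (`overlap_integral()`,
  `forster_radius()`, `relative_quantum_yield()`).
* **Structure-based predictions** (`beta_carbon_distance()`, a simplified
  rotamer-cloud sampler `sample_rotamers()`,
  `cloud_distance_distribution()`), on standard PDB input via bio3d.
* **Synthetic data with known ground truth** for every input the pipeline
  consumes (`generate_fd_dataset()`, `generate_experiment_sequence()`,
  `generate_timecourse()`, `generate_spectra()`,
  `generate_toy_structure()`), all pure seeded functions.
* **Pipeline driver** (`run_pipeline()`) reading/writing CSV + JSON.

## A worked example

Simulate a full five-condition di-histidine experiment (two-state
maltose-binding-protein-like ground truth: apo Gaussian 18.3 ± 2.5 Å, holo
12.7 ± 1.3 Å, τ_D = 15.5 ns, R₀ = 12.2 Å), then run the staged fit:

```r
library(tmfret)
truth <- fd_parameters(tau_d1 = 15.5, r0 = 12.2,
                       rbar1 = 18.3, sigma1 = 2.5,
                       rbar2 = 12.7, sigma2 = 1.3, f_b = 0.05)
conds <- generate_experiment_sequence(truth,
                                      a2_subsaturating = c(0.38, 0.60),
                                      seed = 7)
fit <- fit_protocol(conds, r0 = 12.2, acceptor = "cu_dihis", seed = 11)
fit$acceptor
#> tmFRET fit: acceptor
#>   free: rbar1, sigma1, t0, f_b
#>   chi2 = 46.461 over 41 observations
#>   rbar1  sigma1      t0     f_b
#> 18.2720  2.4991 -0.2955  0.0830
```

The stage-2 fit recovers the apo distance distribution (truth 18.3 ± 2.5 Å)
from the noisy data. The stage-4 fit at the first subsaturating ligand
concentration recovers the closed-state occupancy and hence the state
energetics:

```r
a2 <- fit$subsaturating1$parameters[["a2"]]
round(a2, 3)
#> [1] 0.404
eq <- occupancy_to_equilibrium(a2)
sprintf("K = %.3f, dG = %+.3f kT", eq$k, eq$dg_kt)
#> [1] "K = 0.677, dG = +0.390 kT"
```

(the generating occupancy was 0.38; a single noisy replicate lands within
a few percent, and the replicate average converges on the truth). A
phasor check of the same acceptor condition confirms the decay is *not*
single-exponential — its phasor falls inside the universal circle:

```r
pt <- to_phasor(correct_response(conds[[2]]$response,
                                 instrument_model()), 10)
round(universal_circle_residual(pt), 4)
#> [1] -0.0322
```

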