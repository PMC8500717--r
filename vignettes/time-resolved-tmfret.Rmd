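---
title: "Time-resolved tmFRET: model, fitting protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved tmFRET: model, fitting protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmfret)
```

## The measurement and the model

Transition metal ion FRET (tmFRET) pairs a small fluorescent noncanonical
amino acid donor (Acd, or previously Anap) with a nonfluorescent
transition-metal acceptor (Cu²⁺ chelated by cysteine-reactive TETAC, or
Cu²⁺ bound to an engineered di-histidine site). Because the metal quenches
the donor with a steep $1/(1+(r/R_0)^6)$ distance dependence over
10–25 Å, the donor fluorescence lifetime carries information not just about
a mean donor–acceptor distance but about the *distribution* of distances —
the structural heterogeneity within a conformational state and the
occupancies of distinct states.

The package models frequency-domain lifetime data: phase delay
$\varphi_\omega$ and modulation ratio $m_\omega$ of the emission relative
to sinusoidally modulated excitation, measured across modulation
frequencies (default 10–200 MHz, harmonics of a 10 MHz pulse train). For a
donor with intrinsic decay components $\tau_{Di}$ (amplitudes $\alpha_i$,
one or two components) and a distance distribution $P(r)$, each distance
quenches the donor to

$$\tau_{DAi}(r) = \frac{\tau_{Di}}{1 + (R_0/r)^6},$$

and the predicted response is assembled from the Cartesian components

$$N_\omega = (1-f_B)\,\frac{1}{J}\int_0^\infty \sum_i P(r)\,\alpha_i
\frac{\omega \tau_{DAi}^2}{1+\omega^2\tau_{DAi}^2}\,dr
 + f_B\, m_{\omega B}\sin\varphi_{\omega B},$$

$$D_\omega = (1-f_B)\,\frac{1}{J}\int_0^\infty \sum_i P(r)\,\alpha_i
\frac{\tau_{DAi}}{1+\omega^2\tau_{DAi}^2}\,dr
 + f_B\, m_{\omega B}\cos\varphi_{\omega B},$$

with normalization $J = \int_0^\infty \sum_i P(r)\,\alpha_i\,\tau_{DAi}\,dr$
(the relative steady-state intensity), background fraction $f_B$ with the
measured background phasor $(\varphi_{\omega B}, m_{\omega B})$, and
finally $\varphi_\omega = \arctan(N_\omega/D_\omega) + \omega t_0$,
$m_\omega = \sqrt{N_\omega^2 + D_\omega^2}$, where $t_0$ is the IRF time
shift. $P(r)$ is a sum of one or two Gaussians (means $\bar r_i$, widths
$\sigma_i$, occupancy $A_2$ of the second component) plus a donor-only
fraction $f_D$ of molecules carrying no acceptor. The model predicts the
steady-state quenching efficiency as $E = 1 - J / \sum_i \alpha_i\tau_{Di}$.

All twelve parameters live in one vector (`fd_parameters()`):
$f_D,\ \tau_{D1},\ \alpha_1,\ \tau_{D2},\ R_0,\ \bar r_1,\ \sigma_1,\ A_2,\
\bar r_2,\ \sigma_2,\ t_0,\ f_B$. Units: lifetimes and $t_0$ in ns,
distances in Å, frequencies in MHz ($\omega = 2\pi f$ in rad/ns
internally), phase in degrees.

### A note on the efficiency denominator

Written with $\tau_{DAi}$ in the denominator, the efficiency expression
would be identically degenerate (the numerator *is* the quenched
intensity). The only reading under which $E$ is a well-defined donor
quenching efficiency uses the *unquenched* intensity
$\sum_i \alpha_i \tau_{Di}$ in the denominator, and that is what
`apparent_efficiency()` computes: $E = 0$ when nothing transfers, and for a
narrow single Gaussian it converges to the discrete Förster value
$1/(1+(\bar r/R_0)^6)$.

### Donor-only population

Physically, donors without an acceptor simply do not transfer. The
conventional representation places them as a very narrow Gaussian at
150 Å ($\sigma$ = 0.1 Å), far beyond any realistic $R_0$. The forward
model treats the donor-only fraction analytically as an exact zero-FRET
component, which is numerically identical (FRET at 150 Å with
$R_0 \approx 15$ Å is below $10^{-6}$) and avoids integrating a needlessly
stiff term; `donor_only = "gaussian150"` switches to the literal narrow
Gaussian for comparison. The evaluated density `distance_density()` always
shows the 150 Å spike so that $\int P(r)\,dr = 1$ including $f_D$.

## Numerical choices

* **Quadrature.** Each Gaussian component is integrated by fixed
  Gauss–Legendre quadrature (257 nodes, cached) on
  $[\max(0.01\,\text{Å}, \bar r - 6\sigma),\ \bar r + 6\sigma]$, with the
  truncated component renormalized to unit mass. Tails beyond $6\sigma$
  are negligible at measurement precision, and truncation at $r > 0$
  removes the unphysical negative-distance mass a literal Gaussian would
  carry. The forward model agrees with an independent time-domain
  simulate-and-Fourier-transform oracle to < 0.1° in phase and < 0.002 in
  modulation across 10–200 MHz (tested).
* **Angles and units.** Phase is stored in degrees and converted
  internally; the $\omega t_0$ term multiplies rad/ns by ns.
* **Degenerate widths.** Optimizer bounds keep $\sigma \ge 0.1$ Å; below
  instrument precision a distribution is indistinguishable from a discrete
  distance.

## The staged fitting protocol

`fit_protocol()` reproduces the parameter-freezing scheme used across a
measurement sequence, with values flowing forward between stages and
$t_0, f_B$ refit per condition (they absorb instrument drift):

| stage | condition            | free parameters                         | fixed |
|-------|----------------------|-----------------------------------------|-------|
| 1     | donor only           | $\tau_{D1}, t_0, f_B$                   | $f_D = 1$, $\alpha_1 = 1$ |
| 2     | + acceptor           | $\bar r_1, \sigma_1, t_0, f_B$          | $A_2 = 0$; $f_D$ per chemistry |
| 3     | + saturating ligand  | $\bar r_2, \sigma_2, t_0, f_B$          | $A_2 = 1$ |
| 4     | subsaturating ligand | $A_2, t_0, f_B$                         | both Gaussians frozen |
| 5     | reversal             | $f_D, t_0, f_B$                         | |

The donor-only fraction at stage 2 defaults to 0.08 for Cu²⁺-TETAC
(labeling incompleteness calibrated with a long-$R_0$ cysteine-reactive
quencher) and 0 for di-histidine sites labeled with 100 µM Cu²⁺; both are
overridable. Stage 3 inherits the stage-2 $f_D$. The recovered $A_2$ maps
to an equilibrium constant $K = A_2/(1-A_2)$ and free energy difference
$\Delta G = -\ln K$ (kT) via `occupancy_to_equilibrium()`.

**Objective and weights.** Each stage minimizes
$\chi^2 = \sum_\omega \frac{(\varphi^{obs}-\varphi^{pred})^2}{s_\varphi^2}
 + \sum_\omega \frac{(m^{obs}-m^{pred})^2}{s_m^2}
 + \frac{(E^{obs}-E^{pred})^2}{s_E^2}$
over the free parameters. Measurement variances are not part of the
datasets, so the defaults are stated, typical frequency-domain precisions —
$s_\varphi = 0.2°$, $s_m = 0.004$, $s_E = 0.01$ — all configurable through
`chi_weights()`. Relative weighting shifts the $\chi^2$ scale, not the
location of the noiseless minimum.

**Optimizer.** Bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) on the free subset, optionally multi-started from
Latin-hypercube draws within the box bounds (fixed seed, default 1234);
the best start is reported and non-convergence is flagged. On noiseless
synthetic sequences every staged fit recovers its generating parameters to
better than $10^{-4}$ relative error (tested).

**Identifiability of the background fraction.** Freeing $f_B$ is sound
when the donor lifetime (~16 ns for Acd) is well separated from the
background lifetime (~2–3 ns autofluorescence). For free-dye
characterization of a short multi-exponential decay (Anap, 1.3/3.3 ns) a
free background component of similar lifetime is *not* identifiable — it
trades against the decay parameters — so free-dye datasets are modeled as
background-free cuvette measurements and fit with
$(\tau_{D1}, \alpha_1, \tau_{D2}, t_0)$ free. This is why the package's
two-exponential examples fix $f_B = 0$.

## Phasor analysis

`to_phasor()` maps a (corrected) response at one frequency (default
10 MHz) to $(D, N) = (m\cos\varphi, m\sin\varphi)$. Single-exponential
decays fall on the universal circle $(D-\tfrac12)^2 + N^2 = \tfrac14$;
mixtures fall inside, and any two-population intensity mixture falls on
the chord between the parent phasors. `chord_fraction()` projects a point
onto that chord; the fraction along the chord is the **intensity**
fraction of the second population, which is only equal to the mole
fraction when the two populations are equally bright. Since FRET dims the
quenched population, `phasor_population_fraction()` applies the
brightness correction using the relative $J$ (or $1-E$) of the two
parents from a fitted model. Both numbers are reported rather than
asserting which convention an external analysis used; off-chord distance
is attached as a quality metric instead of being silently discarded.
Group centroids of per-pixel clouds are arithmetic means of $(D, N)$.

## What the synthetic-data generator does (and does not) emulate

`generate_fd_dataset()` evaluates the forward model and adds independent
Gaussian noise to phase and modulation; `generate_experiment_sequence()`
emits the full five-epoch protocol with per-condition $(t_0, f_B)$ drift
(defaults: $t_0 \sim \mathcal N(0, 0.2\,\text{ns})$,
$f_B \sim U(0.02, 0.1)$), a 2.5 ns single-exponential background phasor
(the autofluorescence lifetime range), and optional steady-state
efficiency observations (s.d. = `noise_model()$s_intensity`). Default
noise magnitudes equal the fitting weights, so reduced $\chi^2 \approx 1$
on defaults. Every generator is a pure, seeded function of its parameters:
regeneration is bit-identical and the caller's RNG stream is untouched.

Not emulated: photon-counting (Poisson) statistics, phase–modulation noise
covariance (independence is assumed and stated), detector saturation, and
full-frame imaging (phasor emulation uses modest per-condition pixel
counts). Passing recovery tests on this generator therefore demonstrates
correctness of the estimation machinery under the stated noise model, not
robustness to every instrument artifact in real data.

Recovery test problem sizes: 20 modulation frequencies per condition,
five-condition sequences, 20 replicate sequences for the occupancy
recovery checks — sizes chosen so the whole suite exercises every stage
while remaining comfortably reproducible on a laptop.

## Structure-based distance predictions

`beta_carbon_distance()` measures CB–CB separations from PDB coordinates
(CA fallback for glycine, flagged). `sample_rotamers()` is a deliberately
*simplified* rotamer-cloud sampler: idealized coarse heavy-atom probe
templates (Acd's acridone ring as a planar pseudo-atom scaffold with two
rotatable bonds; Cu²⁺-TETAC as a five-torsion disulfide tether ending in
the chelated Cu²⁺; Cu²⁺–histidine with the Cu bound to NE2 at 2.03 Å)
grafted onto the site backbone by natural-extension geometry, sampled by
uniform torsion draws and filtered by hard-sphere clash rejection (tight:
3.4 Å cutoff, no clashes; loose: 2.5 Å, ≤ 5 clashes; hydrogens ignored —
crystal structures lack them). Di-histidine sampling keeps only rotamer
pairs whose Cu positions nearly coincide, mimicking the shared ion. It is
not a re-implementation of a published rotamer library tool: rotamer-set
identity is not claimed, only distributional behavior
(`cloud_distance_distribution()` histograms and centroid distances), and
the test suite validates it on ideal-helix fixtures generated by
`generate_toy_structure()`.

## Known limitations

* Parameter pairs such as $(\bar r, \sigma)$ are correlated; the
  least-squares machinery reports point estimates and flags
  non-convergence but does not sample posteriors or compare models.
* $R_0$ enters as an input (from `forster_radius()` with
  $\kappa^2 = 2/3$, the standard assumption for a metal-ion acceptor;
  $\kappa^2 \in [1/3, 4/3]$ would move $R_0$ by about ±11%).
* Time-domain (TCSPC) fitting, anisotropy, and pixel-level image
  processing are out of scope.
* The Förster-convolved-Gaussian steady-state distance model is not
  implemented; steady-state efficiencies are used directly or as one
  weighted observation in the lifetime fits.

## A worked pass through the machinery

```{r example, eval = FALSE}
# ground truth: di-histidine acceptor construct, two conformational states
truth <- fd_parameters(tau_d1 = 15.5, r0 = 12.2,
                       rbar1 = 18.3, sigma1 = 2.5,
                       rbar2 = 12.7, sigma2 = 1.3, f_b = 0.05)
conds <- generate_experiment_sequence(truth,
                                      a2_subsaturating = c(0.38, 0.60),
                                      seed = 7)
fit <- fit_protocol(conds, r0 = 12.2, acceptor = "cu_dihis", seed = 11)
fit$subsaturating1$parameters[["a2"]]   # occupancy near 0.38
occupancy_to_equilibrium(fit$subsaturating1$parameters[["a2"]])
```
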