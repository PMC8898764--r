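---
title: "Spin-state analysis of mixed-valent dimers with hdespin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin-state analysis of mixed-valent dimers with hdespin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdespin)
```

## The model

A reduced iron–chalcogenide dimer [Fe₂Q₂]⁺ is a mixed-valent d⁵–d⁶ pair:
a locally high-spin ferric site (s = 5/2) exchange-coupled to a ferrous
site (s = 2), with one itinerant electron resonating between them. Two
interactions set the spin ladder:

* **Heisenberg exchange** `J` (cm⁻¹, −2J S₁·S₂ convention; J < 0
  antiferromagnetic), which orders the total-spin levels as −J·S(S+1);
* **double exchange** `B` (cm⁻¹, ≥ 0), the resonance delocalization of
  the itinerant electron, which splits every Heisenberg level into a
  symmetric/antisymmetric pair:

$$E_\pm(S) \;=\; -J\,S(S+1) \;\pm\; B\,(S+\tfrac12).$$

For the (5/2, 2) pair the allowed total spins are S = 1/2 … 9/2 (five
values, ten levels, sixty magnetic states). With J < 0 the ground spin is
a non-decreasing step function of the ratio |B/J|, with analytic
crossings at |B/J| = 2(S+1): the S = 1/2 region ends at 3, and the
maximal S = 9/2 takes over at 9, so discrete intermediate spin states
S = 3/2, 5/2, 7/2 occupy the window 3 ≤ |B/J| ≤ 9.

```{r}
crossing_ratios(local_spin_pair())
phase_diagram(ratios = c(1, 4, 6, 8, 10))
```

At an exact crossing two spins are degenerate; `ground_spin()` reports
the **lower** spin and flags the degeneracy, so phase boundaries are
assigned reproducibly. Energies are reported exactly as the eigenvalue
expression gives them (no global shift): every downstream Boltzmann
average is shift-invariant, so a reference offset would only obscure
comparisons.

## Vibronic (PKS) coupling

The out-of-phase breathing mode of the bridge — the PKS vibration —
traps the itinerant electron on one site and competes with double
exchange. In the dimensionless coordinate y the adiabatic surfaces are

$$E_\pm(S, y) = -J\,S(S+1) + \tfrac{\Lambda}{2}y^2
  \pm \sqrt{\Lambda^2 y^2 + B^2 (S+\tfrac12)^2},$$

with a single coupling energy Λ = λ²/k₋ (cm⁻¹); λ and k₋ are never
identifiable separately in this form and are not stored. This
normalization is fixed by two requirements: the y = 0 splitting must be
the bare double-exchange splitting 2B(S+½), and in the B = 0 limit the
lower surface must be trapped at y = ±1 with depth Λ/2. Typeset versions
of the vibronic expression differ in how the radical term is
parenthesized, so `adiabatic_surfaces()` exposes the alternative
rendering (Λ²/2 inside the radical) behind `form = "as_printed"`; the
standard form is the default and is used everywhere else in the package.

Writing b = B(S+½), the lower surface of a spin state is a **single
well** (fully delocalized, Robin–Day class III) iff b ≥ Λ — the
curvature at the origin is Λ − Λ²/b — and otherwise a **double well**
(partially delocalized, class II) with minima at y₀ = ±√(1 − b²/Λ²) and
barrier (Λ − b)²/(2Λ). The vibronically relaxed energy of each spin is
therefore E₋(S, 0) − max(0, (Λ − b)²/(2Λ)) *when trapped* (and the
unrelaxed minimum otherwise): relaxation is largest for the states with
the smallest double-exchange splitting, which is what destabilizes the
intermediate spins.

### Study fixtures

`vibronic_fixtures()` encodes the chalcogenide series: Λ = 2200, 1400
and 1650 cm⁻¹ for Q = S, Se, Te (DFT-derived values; upper bounds, since
the same displacements were assumed across the series) combined with the
susceptibility-fitted ratios |B/J| = 2.0, 2.9, 3.7. Only the ratio is
published, so an absolute exchange scale must be chosen: the fixtures
use J = −300 cm⁻¹, a typical antiferromagnetic [Fe₂S₂]⁺ magnitude, which
puts B on the same 10³ cm⁻¹ scale as Λ — the regime in which the
class II/III competition is physically meaningful. With these values the
disulfide fixture keeps a double-well S = 1/2 ground surface (class II),
the ditelluride fixture a single-well S = 3/2 ground surface (class III),
and the diselenide fixture a condensed low-energy ladder with S = 1/2,
3/2, 5/2 lowest:

```{r}
fx <- vibronic_fixtures()
sapply(fx, function(p) vibronic_spin_ladder(p)$ground_S)
classify_ground_surface(fx$complex3, 3/2)
```

## Susceptibility: simulation and fitting

`chi_t()` evaluates the van Vleck / Boltzmann average over the full
ladder, treating each level as an isotropic spin-only paramagnet (the
dimer Bleaney–Bowers expression generalized to include double exchange):

$$\chi_M T = C\,g^2\,
  \frac{\sum_{S,\pm}(2S+1)\,S(S+1)\,e^{-E_\pm(S)/k_BT}}
       {\sum_{S,\pm}(2S+1)\,e^{-E_\pm(S)/k_BT}},
  \qquad C = \frac{N_A\mu_B^2}{3k_B} = 0.125049\ \mathrm{cm^3\,K\,mol^{-1}}.$$

Constants: k_B = 0.6950348 cm⁻¹ K⁻¹ and μ_B = 0.46686 cm⁻¹ T⁻¹.
Boltzmann weights are computed after subtracting the ladder minimum, so
arbitrarily large |J|, B never overflow. Two limits anchor the scale:
χT → C g² ⟨S(S+1)⟩ = C g² · 14.75 at high temperature, and the Curie
constant of the ground level at low temperature.

`fit_chi_t()` design choices:

* **Parameterization (J, r)** with B = r|J|. Over a finite temperature
  window the curve shape constrains the ratio r = |B/J| far more
  robustly than J and B separately; the fit reports the residual-norm
  profile over its multi-start grid of r values (default 0.5 … 9.5) and
  warns when J is not pinned down.
* **T > 50 K only, by default.** The vibronic-free ladder is knowingly
  wrong at low temperature (vibronic relaxation, ZFS and intermolecular
  effects dominate there), so points below `T_min` are excluded unless
  `allow_low_T = TRUE` is set deliberately.
* **g fixed by default** (it is strongly correlated with the overall
  scale); pass `g = NA` to free it.
* Levenberg–Marquardt refinement (minpack.lm) from each start; the best
  run is returned with an asymptotic standard error on r.

## Magnetization with zero-field splitting

`zeeman_magnetization()` diagonalizes H = D[S_z² − S(S+1)/3] +
E(S_x² − S_y²) + μ_B Σ g_k B_k S_k on the (2S+1)-dimensional spin space
and Boltzmann-averages the **expectation of the moment operator**
−Σ g_k u_k S_k (Hellmann–Feynman), not a finite difference of energies;
the finite-difference derivative of the free energy is kept as an
independent oracle in the test suite and agrees to 10⁻⁶ relative.
`powder_moment()` averages over a Fibonacci sphere grid (default 500
orientations; self-convergence is below 0.5% already at 200) and also
reports the maximum single-orientation moment — the moment along the
main magnetization axis. The exact crystallite-orientation correction
used to reduce experimental powder data to that axis is not reproducible
from published information, so measured saturation moments are only
qualitatively comparable to these simulations.

## EPR machinery

For half-integer S each zero-field level is a Kramers doublet (for
S = 3/2: two doublets split by 2√(D² + 3E²)). `doublet_effective_g()`
computes the fictitious-S′ = 1/2 g′ values of a doublet as the
first-order Zeeman splitting slope along each principal axis in the
B → 0 limit, the appropriate description when |D| ≫ hν (X-band quanta
are ≈ 0.3 cm⁻¹ against |D| ≈ 11 cm⁻¹ here); a `finite_field` mode is
provided for comparison and matches to better than 0.1% at |D| ≥ 10
cm⁻¹. The axial S = 3/2 limit reproduces the closed form (2g, 2g, g);
the fully rhombic limit with g = gₑ gives g′ ≈ (5.47, 2.00, 1.47), and
E/D = 0.115 with g_iso = 1.925 gives the low-field features at
g′ ≈ 4.46 and 3.16. Rhombicity is restricted to the canonical η ∈
[0, 1/3]; g′ values are reported per axis and sorted descending. Both
signs of D are accepted — for fully rhombic tensors the sign cannot be
inferred from the g′ values, so both doublets are always available.
`doublet_population()` gives the Boltzmann fractions of the zero-field
doublets (degeneracy 2), the quantity behind the temperature broadening
of the S = 3/2 signals, and `nutation_frequency()` implements the
√(S(S+1)) law used to assign spin quantum numbers from transient
nutation.

## Synthetic data

`generate_chit()` / `generate_magnetization()` emulate the SQUID
observables under the study conditions: temperatures 2–290 K (2 K
steps), fields 0.1–7 T at 2 K, and 1% multiplicative Gaussian noise —
the relative-error regime of a SQUID magnetometer; true per-point
uncertainties are not published, so σ is adjustable. Fixtures:

| fixture  | r = \|B/J\| | g    | extras                                    |
|----------|-------------|------|-------------------------------------------|
| complex1 | 2.0         | 1.90 | S = 1/2 powder for M(H)                    |
| complex2 | 2.9         | 1.92 | 50:50 S = 1/2 + S = 3/2 (D = +11, E/D = 0.12) spin-isomer mixture |
| complex3 | 3.7         | 2.00 | S = 3/2, D = +11 cm⁻¹, E/D = 1/3 for M(H)  |

The magnetometry fixtures adopt J = −40 cm⁻¹ (B = r|J|): only the ratio
is published, and a modest |J| keeps the 2–290 K window informative
about the ladder. Data are generated already corrected (no diamagnetic
or TIP terms), and the generator makes no attempt at instrument
systematics (field offsets, drift) — passing recovery tests therefore
demonstrates statistical identifiability of r under honest noise, not
robustness to every experimental artifact.

## Numerical choices and problem sizes

* Ratio scans use a 10⁻³ grid in |B/J| (resolves crossings to the third
  decimal); `phase_diagram()` is vectorized over the grid.
* The PKS coordinate grid is −3 … 3 with 601 points (minima lie at
  |y| ≤ 1); well geometry is computed analytically and the grid is only
  a cross-check.
* Degeneracy tie-breaks always report the lower spin, with a flag.
* The recovery study runs 20 replicates at 1% noise with seeded
  generation; the median recovered ratio sits within ±0.01 of the truth,
  comfortably inside the ±0.1 experimental uncertainty.
* Powder averages in examples and tests use 80–500 orientations; the
  Fibonacci grid makes the average deterministic.

## Limitations

* Two-site dimers only: no cubane or higher-nuclearity double-exchange
  ladders, no anisotropic or biquadratic exchange.
* The susceptibility model shares one isotropic g across all ladder
  states and ignores intermolecular coupling and field-dependent
  corrections.
* Vibronic treatment is adiabatic and single-mode; no tunneling
  splittings or solvent/H-bond trapping terms.
* No field-swept EPR lineshape simulation (strain, hyperfine, ENDOR):
  the package stops at effective g values, populations and nutation
  ratios.
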