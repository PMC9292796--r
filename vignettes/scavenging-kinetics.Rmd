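---
title: "From free-energy tables to radical-scavenging rate constants"
author: "qmorsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From free-energy tables to radical-scavenging rate constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmorsa)
```

## The problem

An *in silico* antioxidant study produces, for each candidate scavenger and
each reactive oxygen species (ROS), a table of Gibbs free energies of
reaction and activation for every elementary quenching channel. Four
mechanisms cover the chemistry of tricyclic chalcogen scaffolds such as
phenothiazine and its Se/Te analogues:

* **HAT** — the radical abstracts H• (the amino N–H and four aromatic C–H
  sites);
* **RAF** — the radical adds to an aromatic or ring-junction carbon (six
  sites);
* **SET** — one-electron oxidation of the scaffold, feasible only where the
  solvent stabilizes the resulting ion pair;
* **OX** — oxygen-atom transfer from a peroxyl radical to the chalcogen,
  forming the chalcogenoxide.

`qmorsa` converts such tables into apparent rate constants, branching
ratios and an overall scavenging activity per (antioxidant, radical,
medium) context. This vignette explains the model, the tunable parameters,
the design choices that were genuinely open, and what the shipped tests do
and do not demonstrate.

## Rate model

### Solution-phase corrections

Tabulated barriers referenced to the 1 atm gas-phase standard state are
converted to the 1 M solution convention and corrected for the solvent
cage. For a step of molecularity $n$:

$$\Delta G^{\ddagger}_{\mathrm{corr}} \;=\; \Delta G^{\ddagger}
  \;-\;(n-1)\,RT\ln V_M
  \;-\;RT\!\left[\ln\!\big(n\cdot 10^{2(n-1)}\big)-(n-1)\right]$$

with $V_M = RT/P$ the molar volume at 1 atm (24.465 L mol⁻¹ at 298.15 K).
Both terms vanish for $n = 1$ and total −4.441 kcal mol⁻¹ for $n = 2$ at
298.15 K, i.e. a rate factor $V_M \cdot 200/e \approx 1800$. The cage term
is written here in the form whose bimolecular limit reproduces that
canonical 1800-fold factor; `correction_rate_factor()` recomputes it and
the test suite pins it to three significant figures. Both corrections can
be disabled (`rate_options(apply_standard_state=, apply_cage=)`) to
quantify their effect.

A corrected barrier below zero is clamped to zero: the TST prefactor
$k_BT/h$ is the physical ceiling of the thermal model, and the diffusion
cap governs everything faster. Clamping is flagged per channel and can be
disabled.

### Thermal rates, tunneling, Marcus barriers

The thermal rate constant is Eyring–Polanyi TST,
$k = \kappa\,(k_BT/h)\,e^{-\Delta G^{\ddagger}_{\mathrm{corr}}/RT}$, in
M⁻¹ s⁻¹ for bimolecular channels under the 1 M convention. The
transmission coefficient is the Wigner one-dimensional correction
$\kappa = 1 + \tfrac{1}{24}\big(hc\nu^{\ddagger}/k_BT\big)^2$ from the
magnitude of the transition-state imaginary frequency (stored unsigned,
because sign conventions differ across quantum-chemistry codes). Tunneling
matters mainly for hydrogen transfer; when no frequency is supplied the
default is $\kappa = 1$ — absent data must not invent tunneling. A
`kappa_map` option injects frequencies per channel without editing the
table.

SET has no nuclear saddle point, so its barrier comes from Marcus theory,
$\Delta G^{\ddagger} = (\lambda/4)(1+\Delta G_r/\lambda)^2$. When only
$(\Delta G_r, \Delta G^{\ddagger})$ are known, `infer_lambda()` solves the
inverse quadratic $\lambda^2 + (2\Delta G_r - 4\Delta G^{\ddagger})\lambda
+ \Delta G_r^2 = 0$ (stable large-root/product form), yielding up to two
admissible reorganization energies, one on the normal and one on the
inverted branch. Both reproduce the same barrier, so the choice affects
only the region label; without a hint the normal branch is chosen, and the
packaged dataset ships inverted-region hints for the two aqueous hydroxyl
cases where the reorganization energy is smaller than $|\Delta G_r|$. The
activationless boundary $|\Delta G_r| = \lambda$ is classified normal.

### Diffusion cap

Fast channels are limited by encounter frequency. The pipeline uses the
steady-state Smoluchowski rate $k_D = 4\pi R_{AB} D_{AB} N_A$ with mutual
diffusion coefficient from Stokes–Einstein,
$D_X = k_BT/(6\pi\eta a_X)$, computed in SI and reported in M⁻¹ s⁻¹, and
couples thermal and diffusion rates by Collins–Kimball,
$k_{\mathrm{app}} = k_D k/(k_D+k)$. A channel is flagged
diffusion-controlled when $k \ge k_D$ (threshold configurable).

Parameters with units and defaults:

| parameter | unit | default | note |
|---|---|---|---|
| temperature | K | 298.15 | per medium, overridable |
| viscosity η | Pa s | water 8.91e-4; pentyl ethanoate 8.62e-4 | literature values; neither is printed in the source tables |
| Stokes radius a | m | scaffolds 3.6e-10; HO 2.2e-10; HOO 2.46e-10; CH₃OO 2.9e-10 | sphere-equivalent defaults, flagged non-authoritative |
| reaction distance R_AB | m | a_A + a_B | overridable per (antioxidant, radical, mechanism, medium) |

### Why encounter distances are calibrated

With Stokes–Einstein and the contact distance $R_{AB}=a_A+a_B$, the
diffusion rate $k_D = \tfrac{8k_BTN_A}{3\eta}\,\tfrac{(a_A+a_B)^2}{4a_Aa_B}$
is bounded below by $8k_BTN_A/3\eta \approx 7.4\times10^9$ M⁻¹ s⁻¹ in
water — yet published diffusion-controlled entries for these systems reach
down to $1.7\times10^9$. Such values are only attainable with effective
encounter distances below contact, plausibly pair-specific distances taken
from transition-state geometries that are never printed. The package
therefore treats every diffusion-controlled entry as *calibrated*, not
predicted: `calibrate_reaction_distances()` solves, per (antioxidant,
radical, mechanism, medium), for the single $R_{AB}$ that makes the
recomputed mechanism sum equal the published value (a monotone
one-dimensional root find). Validation consequently does not reject
sub-contact distances; it rejects only non-positive ones. The calibrated
distances are reported alongside the reproduction diff so nothing about
them is hidden.

### Degeneracy convention

Symmetric ring sites come in pairs, so those channels default to path
degeneracy $\sigma = 2$ (amino site and site-free mechanisms
$\sigma = 1$). Where $\sigma$ enters is genuinely ambiguous in standard
practice: the branching formula shows it only in the mechanism sums, but
published mechanism totals are consistent with degeneracy-weighted site
sums. The default multiplies the *thermal* rate before Collins–Kimball
coupling — each symmetric site is an independent reactive funnel sharing
one encounter pair, so a pair of sites cannot jointly exceed $k_D$ —
and `rate_options(sigma_convention = "post")` moves it outside the
coupling instead. Both conventions agree in the activation-controlled
regime.

### Aggregation

Mechanism sums add the degeneracy-weighted channel rates; branching
ratios $\Gamma_i = 100\,k_i^{\mathrm{app}}/\sum_j k_j^{\mathrm{app}}$ are
kept exact internally and rounded half-away-from-zero to integers in
reports. Direct chalcogen oxidation is computed and reported but excluded
from $\Gamma$ and the overall sum by default, mirroring how such channels
are usually treated once shown negligible (`include_ox = TRUE` includes
them); in the packaged dataset its best case (PTE + HOO• in water) sits
more than two orders of magnitude below the competing barrierless
hydrogen transfer.

## The packaged dataset and its reproduction classes

The fixture encodes 228 channels (HAT at sites 1–5, with barriers only for
the amino site, matching the source's kinetic treatment; RAF at the six
ring sites; SET and OX site-free) for PS/PSE/PTE × {HO•, HOO•, CH₃OO•} ×
{water, pentyl ethanoate}, with per-value table provenance, a pinned
checksum, and two curation notes: one garbled reaction energy (PTE, RAF
site 5a, water) encoded as −38.7 kcal mol⁻¹ as the evident reading, and
ring-opening flags on the PTE site-5a adducts, whose products are not
recoverable antioxidants.

`reproduce_tables()` recomputes every published mechanism-level entry and
classifies it:

* **robust** — activation-controlled SET entries. These follow from the
  printed barriers alone ($\kappa = 1$, corrections on). All 13 reproduce
  within ±12 %, inside the honest error budget: inputs printed at 0.1
  kcal mol⁻¹ imply ±0.05 rounding, i.e. ±9 % per Boltzmann factor, plus a
  few percent from the diffusion-coupling convention.
* **calibrated** — diffusion-controlled entries; they match by
  construction and validate only internal consistency.
* **not-reproducible** — activation-controlled HAT/RAF entries. The
  published lipid HAT values imply $\kappa \approx 7$ from unprinted
  imaginary frequencies, and RAF rows show an analogous factor 2–3 gap;
  with the no-data default $\kappa = 1$ these recompute at 0.11–0.45 of
  the published values. They are reported, classified, and excluded from
  quantitative assertions.

The qualitative conclusions are insensitive to all of this and are
asserted on recomputed output: in water RAF dominates HO• scavenging for
all three scaffolds, barrierless amino-site HAT dominates the peroxyl
radicals for PS and PSE, SET dominates them for PTE, and SET contributes
0 % everywhere in the lipid medium.

## Synthetic data and testing strategy

The generator (`generate_channels()`) draws channel tables uniformly
within ranges spanning the curated data — a modeling choice, not an
inference; no distributional information exists in the source — while
preserving its structure: exergonic amino-site HAT, endergonic aromatic
HAT for peroxyl radicals, degeneracy 2 on ring sites, lipid SET barriers
in the 40–66 kcal mol⁻¹ range, and a reorganization energy consistent
with each drawn (ΔG_r, ΔG‡) pair. A single integer seed determines the
dataset bit-for-bit and the global RNG state is left untouched.

Every generated channel carries ground truth computed by
`oracle_rate()`, the whole chain written as one closed-form expression
with no intermediate types. The staged pipeline must match it to 1e-12
relative on 1080 seeded channels — this catches unit slips, misplaced
corrections and convention drift, which is precisely where a staged
implementation can silently diverge. Property tests further pin: Eyring
log-linearity (slope −1/RT to 1e-9), Marcus/inverse round-trips,
Collins–Kimball bounds and monotonicity, branching sums of exactly 100
pre-rounding, and the ±0.05 kcal mol⁻¹ perturbation bound (rates move by
at most ×/÷ exp(0.05/RT) = 1.088 in the activation-controlled regime,
via `perturb()`).

What passing tests do *not* show: the generator draws independent
uniform energies, so correlated chalcogen trends, systematic
method error in the underlying electronic structure, and real solvent
effects beyond a two-class polarity split are all outside its scope.
Agreement with the oracle validates the kinetics chain, not the upstream
free energies.

Problem sizes were chosen so the whole suite runs in seconds: 228 fixture
channels, 1080 synthetic channels for the oracle equivalence, 100–200
random cases per algebraic property.

## Numerical choices and degenerate inputs

* Energies stay in kcal mol⁻¹ through the thermodynamic layer; diffusion
  arithmetic is SI with a single ×10³ conversion to M⁻¹ s⁻¹ — one
  conversion point, no unit drift.
* `infer_lambda()` uses the cancellation-free quadratic form (large root
  plus product-of-roots), keeping round-trips at ~1e-13 relative.
* Zero or absent imaginary frequency → κ = 1 exactly; absent Stokes radii
  → no diffusion cap, recorded in the channel's `note`; channels without
  any activation energy (thermodynamic-screening rows) are carried with
  NA rates rather than dropped.
* Unknown site labels are warnings, not errors, so the engine generalizes
  beyond the seven-site scaffold; hard errors are reserved for structural
  impossibilities (σ < 1, SET with a site, ring opening off-site).
* Calibration roots are bracketed on log₁₀ R_AB ∈ [−12, −6] where the
  mechanism sum is strictly monotone in R_AB.

## Known limitations

* Tunneling beyond Wigner (Eckart, SCT) and variational TST are out of
  scope; published HAT/RAF values that depend on unprinted frequencies
  are classified not-reproducible rather than approximated.
* Diffusion theory assumes neutral spherical reactants; no ionic-strength
  or electrostatic corrections.
* No mixture kinetics or time-course integration: outputs are per-context
  rate constants and ratios.
* The 1800-fold correction factor and everything downstream of it assume
  the bimolecular cage form above; alternative cage conventions exist in
  the literature and would shift absolute (not relative) rates.
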