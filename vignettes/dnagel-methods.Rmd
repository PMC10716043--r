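---
title: "Methods: splint-library design and hydrogel viscoelastic analysis"
author: "dnagel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splint-library design and hydrogel viscoelastic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnagel)
```

# The material and the questions the package answers

`dnagel` models hydrogels built from an ultrahigh-molecular-weight polymer
backbone decorated with short DNA *anchor* strands, crosslinked by pairs of
DNA *splints*. Each splint has two domains: an *adaptor* that hybridizes to
an anchor (melting temperature T1) and an *overlap* that pairs with exactly
one partner splint (melting temperature T2 < T1). Because the overlap is
the weakest bond in the network, its sequence programs the gel's stiffness,
melting point, stress-relaxation time and self-healing.

A single splint species wastes most of its bonds on *intramolecular*
loops: both ends of a splint pair land on the same backbone, contributing
nothing to elasticity. Diversifying the overlap with $n$ degenerate bases
(N) creates a combinatorial crosslinker library (CCL) of $C = 4^n$
orthogonal splint pairs; an anchor is then unlikely to find its partner on
its own backbone, and intermolecular crosslinks dominate.

The package implements five coupled analyses:

1. **Library design** — expansion of degenerate designs into explicit
   splint pairs, validation of the dual-splint invariants.
2. **Hybridization thermodynamics** — nearest-neighbour duplex
   energetics, pairwise MFE matrices, Boltzmann pairing selectivity,
   melting hierarchies, blocking-strand (heat-activated crosslinker)
   occupancy.
3. **Network statistics** — Monte-Carlo and closed-form partition of
   crosslinks into intra- and intermolecular bonds versus library
   complexity; the affine rubber-elasticity inversion
   $G' = \nu k_B T$ for crosslinking efficiency.
4. **Rheology trace analysis** — Maxwell relaxation times, gel melting
   points, phase angles, self-healing recovery.
5. **Synthetic data** — seeded generators with embedded ground truth for
   every input, so the whole pipeline is testable without instrument data.

# Nearest-neighbour thermodynamics

## Parameter set and salt correction

Duplex enthalpies and entropies are summed over nearest-neighbour stacks
using the unified oligonucleotide parameters (SantaLucia-Hicks Watson-Crick
set with duplex initiation, terminal A·T penalties and the symmetry term),
extended with the published internal single-mismatch tables (G·T, G·A,
C·T, A·C and like-with-like series, including the tandem-G·T entries).
Monovalent salt enters entropically,
$\Delta S \mathrel{+}= 0.368 \, n_{\text{stacks}} \ln[\mathrm{Na^+}]$,
the standard unified-parameter practice. Free energy is evaluated exactly
as $\Delta G(T) = \Delta H - T\,\Delta S/1000$ — there is no hidden
temperature dependence, and the identity is tested to machine precision.

Default conditions follow the selectivity study design: 20 °C, 150 mM
NaCl, 75 µM total splint pool (37.5 µM per splint strand).

## MFE of a two-strand complex

The hybridization free energy of two strands is approximated as the best
*ungapped antiparallel register*: every relative alignment of the two
strands is scanned, and within each register every sub-window whose ends
are Watson-Crick pairs is scored (stacks + initiation + terminal A·T
penalties + salt). Terminal mismatches are trimmed; unpaired overhangs are
neutral; a tandem mismatch is scored as the sum of its two flanking
single-mismatch stacks (the unparameterised interior stack contributes
zero); the result is clamped at 0 kcal/mol, the unbound reference state.
This deliberately ignores hairpins, bulges and complexes larger than two
strands: overlap domains here are ≤ 20 nt and the quantity of interest is
perfect-match dominance, for which the dominant error terms are the
mismatch stacks that *are* parameterised. For strands of ≤ 8 nt the
implementation agrees exactly with a brute-force enumeration of every
register and window (property-tested on 1,000 random pairs).

The register/window scan is implemented in C++ (via Rcpp); a 256 × 256
library matrix (65,536 duplex MFEs of 14-mers) takes about 1.5 s on one
CPU.

## Selectivity matrices

For a library with forward variants $x$ and reverse variants $y$, the
pairing weight is the Boltzmann factor
$B_{x,y} = e^{-\mathrm{MFE}(x,y)/RT}$ with
$R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ (the molar gas constant replaces
the per-molecule Boltzmann constant because MFE is molar), and each row is
normalized, $B^{\text{norm}}_{x,y} = B_{x,y} / \sum_y B_{x,y}$. Rows are
shifted by their minimum MFE before exponentiation so the normalization
cannot overflow. The concentration-free row normalization treats every
reverse variant as available at its nominal concentration — a lower bound
on real selectivity, since in practice mispartners are scavenged by their
own perfect complements.

`selectivity_summary()` reports the diagonal (intended-pair) minimum and
mean. Selectivity is checked to degrade monotonically as temperature
approaches the overlap melting temperature.

## Per-variant concentration rules

Two readings of "37.5 µM per splint strand" are supported. `equal_split`
divides the pool over all $2C$ explicit strands — appropriate for melting
predictions, where dilution of each distinct pair with growing complexity
is the observable effect. `fixed` keeps each variant at its nominal
concentration — appropriate for selectivity, matching the simplifying
assumption that every competitor is present at its initial concentration.
`equal_split` is the melting default and `fixed` the selectivity default.

## Matrix melting and the domain hierarchy

The two-state melting temperature of a non-self-complementary duplex at
equal strand concentrations is
$T_m = 1000\,\Delta H / (\Delta S + R \ln(c_{\text{total}}/4)) - 273.15$
(with $c_{\text{total}}/1$ for self-complementary duplexes), validated
against a numeric root of the fraction-bound-equals-one-half equation.
Under `equal_split`, the intended overlap duplex of a CCL with complexity
$C$ sits at $c_{\text{total}}/C$, so the predicted gel melting point falls
monotonically with $\log C$. With the package's reference overlap
(calibrated below), the predicted drop from $C = 1$ to $C = 256$ is
≈ 10.9 °C, against the observed 12 °C (65 °C → 53 °C).

`domain_hierarchy()` verifies T1 (adaptor) exceeds the hottest overlap
variant's T2 by a configurable margin (default 10 °C), the condition for
sequential one-pot annealing.

## Blocking strands (heat-activated crosslinkers)

A blocking strand complementary to a contiguous overlap sub-segment
protects the splint at low temperature and releases it on warming. The
occupancy curve is the two-state bound fraction of the blocking duplex at
the stated concentrations (blocker in excess, deployed at 2:1), solving
the binding quadratic at each temperature; competition with splint-splint
pairing is ignored, making the curve a protection upper bound. The
activation temperature is the 0.5-occupancy crossing, found by
root-finding, which by construction equals the blocking-duplex melting
temperature at the effective concentration $c_B - c_S/2$.

# Network statistics

## Crosslink partition model

Each backbone carries $k$ anchors ($k$ fixed at $m$, or Poisson($m$);
fixed is the default). Every anchor binds one splint drawn uniformly from
the $2C$ variants. Two counting rules are provided:

* **any_partner** — an anchor is intramolecularly engaged if *any* other
  anchor on the backbone carries its complementary variant. This
  worst-case eligibility count has the closed form
  $f = 1 - (1 - 1/(2C))^{m-1}$, verified against exhaustive enumeration
  at small $m, C$ (e.g. $f(3,1) = 0.75$, $f(3,4) = 15/64$).
* **max_matching** — anchors engage pairwise, so the engaged count is
  twice the maximum complementary matching,
  $2\sum_p \min(n^{\text{fwd}}_p, n^{\text{rev}}_p)$. This caps each
  anchor at one bond and is the package default, reading "maximum
  percentage of intramolecular crosslinks" as a worst-case pairing count;
  it is bounded above by the any-partner count.

The Monte-Carlo core is C++ under R's RNG, so seeded runs are
bit-reproducible; $10^5$ backbones per grid point run in milliseconds.

`min_complexity_for_suppression()` sweeps the integer complexity grid
(1…1024 by default — the interesting crossings are not powers of four) and
reports the smallest $C$ whose intramolecular fraction falls to
$1 - \text{suppression}$. "Suppress 80%" is interpreted as an absolute
fraction ≤ 20%; a relative interpretation (20% of the $C = 1$ fraction) is
available behind a flag. For backbones with 3 / 20 / 28 anchors at 80%
suppression the any-partner simulation at $10^5$ chains yields minimal
complexities 5 / 43 / 61 and max-matching yields 5 / 39 / 55, bracketing
the published predictions of 4 / 40 / 60; the exact stochastic model
behind those printed values is not fully specified, and no counting
variant we examined (fixed or Poisson anchors, eligibility or matching)
reproduces all three simultaneously, so agreement is expected only to
about one grid step (and is reported with both rules).

## Affine network inversion

Rubber elasticity for an affine network gives $G' = \nu k_B T$. At full
conversion each crosslink consumes two anchors, so
$\nu_{\max} = N_A c_{\text{anchor}}/2$ per m³ and
$G'_{\max} = \nu_{\max} k_B T$ — about 91 Pa for 75 µM anchors at 293 K.
Crosslinking efficiency is the measured plateau modulus over this limit;
an efficiency above 1 is flagged, not an error. Counting crosslinks
(anchors/2) rather than elastically effective strands is the normalization
that reproduces the reported ≈ 76% efficiency ceiling; a phantom-network
alternative ($1 - 2/\phi$ with $\phi = 4$) sits behind
`model = "phantom"`. `efficiency_vs_temperature()` applies the inversion
pointwise along a temperature sweep, so temperature enters both the
measured modulus and the $k_B T$ denominator.

# Rheology extraction

* **Relaxation time (1/e rule).** $\sigma_0$ is the stress at the
  earliest sample — exactly the reported convention, not a fitted
  amplitude — and $\tau$ is where the stress crosses $\sigma_0/e$. A raw
  sample-to-sample crossing is biased early on noisy traces (the first
  noise excursion below the threshold wins), so the crossing is located
  by a local log-linear regression over the samples within ±40% (log
  stress) of the 1/e level, falling back to linear interpolation between
  the bracketing samples when fewer than three samples fall in that
  window. On a noiseless exponential the regression is exact. Traces that
  never reach $\sigma_0/e$ raise a "not relaxed" error carrying the lower
  bound $\tau > t_{\max}$.
* **Least-squares Maxwell fit.** Ordinary least squares on
  $\ln\sigma = \ln\sigma_0 - t/\tau$ (nonlinear fallback when stresses
  touch zero); the RMSE flags multi-mode relaxation. Both extractors
  recover $\tau$ with < 3% median error over 200 seeded synthetic traces
  spanning $\tau \in [1, 10^4]$ s with 1-5% noise.
* **Gel melting point.** First $G' = G''$ crossover (phase angle 45°) in
  sweep order, linearly interpolated in $(T, G'-G'')$; all crossovers are
  listed, and heating/cooling direction is reported. Recovery on synthetic
  sweeps is within 0.1 °C (0.5 °C with 1% noise).
* **Self-healing recovery.** Mean $G'$ over the last half (configurable)
  of the final healing period relative to the first, in percent.
* Traces with non-monotone time stamps are rejected rather than sorted —
  a misread file should fail loudly, not silently reorder.

All extractors are deterministic given a trace.

# Synthetic data: what it does and does not emulate

The generators produce the canonical shapes with known ground truth:
single-exponential relaxation with additive Gaussian noise (truncated at
zero stress), two-state sigmoidal melting sweeps whose $G'/G''$ crossover
sits exactly at the nominal gel point, strain-cycling traces whose healing
plateaus decay geometrically (breaking periods constructed at phase angle
≈ 74°, healing at ≈ 3°), and random dual-splint designs redrawn until the
melting hierarchy passes. Noise is additive/multiplicative Gaussian at
1-5% of signal; instrument artefacts (inertia, evaporation, slip,
drift) are deliberately not modelled. Passing the round-trip tests
therefore demonstrates correctness of the extractors on well-formed
traces, not robustness to pathological instrument output.

## The reference design

Because the deployed strand sequences live in supplementary material that
is not redistributable here, the package freezes one explicit stand-in,
chosen once against the stated study conditions and then left alone:

* overlap `GCCACAGTTGCGTC` (14 nt): its perfect duplex melts at 65.0 °C
  at a 75 µM pool in 150 mM NaCl — the observed melting point of the
  single-pair gel — with degenerate positions 3/6/9/12 for libraries of
  up to 256 pairs;
* adaptor `CGGACGCGACTCGCCGCCCG` (20 nt): melts ≥ 10 °C above the hottest
  $n = 4$ overlap variant, satisfying the annealing hierarchy;
* anchor: the adaptor's reverse complement. At one splint equivalent
  (75 µM, the stated recipe for a 1% (w/v) 20-anchor backbone) the 20-nt
  anchor plus 34-nt splints carry ≈ 1.32 g/L of DNA, matching the
  reported 1.3 g/L budget.

A plain N-expansion yields variants at Hamming distance 1, where single
mismatches in a 14-mer leave the worst-case diagonal selectivity near
0.93. The deployed libraries were reported > 95% selective;
`gen_explicit_library()` therefore also provides *distance-coded*
libraries (free positions plus a sum-mod-4 check digit, minimum
inter-variant distance 2) on which the > 95% property is reproduced at
every size from 1 to 256 pairs (diagonal minimum ≥ 0.995).

# Numerical choices and degenerate inputs

* Expansion order of degenerate designs is lexicographic (A<C<G<T,
  leftmost N slowest), so matrix indices are reproducible run to run.
* Only N is accepted as an ambiguity code; other IUPAC codes are rejected
  to keep the combinatorics tested. Libraries beyond $n = 8$ (65,536
  pairs) require an explicit override.
* Duplexes shorter than two paired positions have no stack and raise an
  error; duplexes with $\Delta H \ge 0$ have no two-state transition and
  `melting_temperature()` refuses them.
* Boltzmann rows are min-shifted before exponentiation; row sums are
  tested to $1 \pm 10^{-9}$ up to 256 × 256.
* Every stochastic routine takes an explicit integer seed, restores the
  caller's RNG state, and echoes the seed in its result; sweep outputs
  carry the per-point seeds.

# Problem sizes

The shipped tests and the acceptance script use the study's own scales:
libraries up to 256 pairs (65,536 duplex MFEs per matrix), $10^5$
Monte-Carlo backbones per complexity grid point, 200 synthetic relaxation
traces and 1,000 brute-force MFE cross-checks. The full suite runs in
under a minute on one CPU.

# Known limitations

* The MFE model is a duplex approximation: no intramolecular secondary
  structure, no complexes of size > 2, no Mg²⁺ correction. The ≤ 8-nt
  brute-force oracle bounds the implementation, not the physics.
* Selectivity ignores competitive scavenging (a conservative bound).
* The crosslink partition model is combinatorial, not spatial: no
  excluded volume, chain conformation statistics or percolation; the
  affine inversion ignores dangling ends and entanglements.
* Published minimal-complexity predictions are matched to ~1 grid step,
  not exactly (see the network-statistics section).
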