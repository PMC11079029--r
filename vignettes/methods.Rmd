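---
title: "Models and numerical methods in wwtandem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in wwtandem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wwtandem)
```

`wwtandem` packages the quantitative models behind a solution-state
study of a tandem WW domain pair and its autoinhibited recognition of
proline-rich ligands. This vignette is the package's own account of
those models: their assumptions, the parameters that matter, the
numerical choices, and what the synthetic-data validation does and
does not establish.

## Chemical shift perturbation

Titrations are compared peak-by-peak on assigned spectra. The
combined perturbation of an amide correlation is weighted as

$$\mathrm{CSP} = \sqrt{\tfrac12\left(\Delta\delta_H^2 +
w\,\Delta\delta_X^2\right)},\qquad w_{^{15}N}=0.14,\ w_{^{13}C}=0.3,$$

which maps both nuclei onto a common ppm scale. Matching is by
(residue, atom group, atom name) — no minimum-distance peak tracking —
because the workflow assumes assigned peak lists at every titration
point. Tryptophan side-chain Nε–Hε correlations use the ¹⁵N weight
(same nucleus pair as the backbone); methyl ¹H–¹³C correlations use
the 0.3 weight and are reported per methyl, with the residue-level
value taken as the maximum over its methyls (a conservative
perturbation call). Peaks present in only one list are flagged
`missing` and never imputed as zero, since a vanished peak usually
means exchange broadening, not absence of perturbation.

Interface calling defaults to mean + 1 SD over the measured entries.
No universal threshold exists for this call; mean + 1 SD is the common
field convention and the cutoff is exposed (`fixed_threshold`) so a
user can reproduce any specific choice. At least five measured
entries are required, below which the SD is meaningless.

## Relaxation

R₁/R₂ decays are fit as $I(t) = I_0 e^{-Rt}$ by Levenberg–Marquardt
with analytic-free residuals, initialised at $I_0 = \max|I|$ and
$R = \ln 2 / t_{1/2}$, with two perturbed restarts. No baseline term
is fit by default (baselines are assumed subtracted upstream); an
`offset` flag adds one. The intensity noise is estimated from the
duplicated delay as $\sigma = |I_a - I_b|/\sqrt{2}$ (pooled when
several series are supplied) and propagated through the Gauss–Newton
covariance $\sigma^2 (J^\top J)^{-1}$; without duplicates the residual
variance is used. All-equal intensities are an error, not a zero-rate
result.

The apparent correlation time uses the standard isotropic estimator

$$\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6\,R_2/R_1 - 7},$$

with $\nu_N = 0.10136905\,\nu_H$. The estimator is only valid outside
extreme narrowing ($6R_2/R_1 > 7$); inside that range the function
refuses rather than returning a complex number. Because published
workflows sometimes average R₂/R₁ with outlier trimming before the
ratio, both plain and 10 % trimmed means are exposed; the package does
not assert which a given study used.

## RDC alignment tensors

The dipolar coupling of an N–H vector $\hat v$ under weak alignment is
$D = D_{max}\,\hat v^\top S\,\hat v$ with $S$ the symmetric traceless
Saupe matrix. $D_{max}$ is computed from physical constants at
$r_{NH} = 1.02$ Å (configurable). The five independent elements are
solved linearly by SVD; the design-matrix condition number is reported
and fits with condition number above 10⁶ (e.g. near-parallel vector
geometry) are rejected rather than silently extrapolated.

Conventions, chosen once so comparisons are deterministic:
eigenvalues ordered $|S_{zz}| \ge |S_{yy}| \ge |S_{xx}|$ with the
minor axes labeled so the rhombicity $R = \tfrac23 (S_{xx}-S_{yy})/S_{zz}$
is in $[0, 2/3]$; the z axis is taken in the positive hemisphere;
$D_a = D_{max} S_{zz}/2$, so a vector along the unique axis of an
axial tensor reads $2 D_a$. The quality factor defaults to
$Q = \mathrm{rms}(D_{obs}-D_{calc})/\mathrm{rms}(D_{obs})$, with the
alternative normalisation by $D_a\sqrt{2 + 1.5R^2}$ behind a flag,
because both are in active use. Fitting is per single conformer;
ensemble-weighted tensor fitting is deliberately out of scope.
Per-domain fits on one rigid structure must agree (this is tested);
genuine interdomain mobility shows up as principal-axis divergence
between per-domain tensors, folded into [0°, 90°] to absorb the axis
sign ambiguity. Monte-Carlo errors refit on Gaussian resamples of
$D_{obs}$ within $d_{err}$, seeded for reproducibility.

Amide protons absent from a structure (common in minimal deposits)
are built geometrically: in the peptide plane, 1.02 Å from N, along
the direction opposing the bisector of the C(i−1)–N and Cα–N bonds.
The chain's first residue has no preceding carbonyl and is skipped
with a warning.

## PRE back-calculation

The transverse enhancement uses the point-dipole form

$$\Gamma_2 = K r^{-6}\left(4\tau_c +
\frac{3\tau_c}{1+\omega_H^2\tau_c^2}\right),$$

with $K = 1.23\times10^{16}$ Å⁶ s⁻² (nitroxide–¹H, configurable) and
defaults $\tau_c = 5$ ns, $R_{2,dia} = 50$ s⁻¹ for the free state
(8 ns / 55 s⁻¹ for the peptide complex). Intensity ratios are

$$I_{para}/I_{dia} = \frac{R_{2,dia}\,e^{-\Gamma_2 t_{INEPT}}}
{R_{2,dia}+\Gamma_2},$$

evaluated per conformer and per amide, and summarised as the ensemble
mean with a min/max envelope. $t_{INEPT}$ defaults to 10 ms, a
standard total ¹H transverse evolution for an HSQC; the value is
configurable and no validation quantity in this package is tied to
it. The label is modeled as a point at the labeled residue's Cβ
(`CB_point`, default, fully deterministic) or at a fixed 6 Å arm
along Cα→Cβ (`offset_point`) to mimic a nitroxide tether; label
rotamer ensembles are out of scope. A single global diamagnetic R₂
is used rather than per-residue values. Comparison against measured
ratios reports the r.m.s. deviation and flags residues outside the
conformer envelope by more than their error; observations *below* the
envelope are the transient-contact candidates, since unmodeled
approaches to the label can only deepen the bleaching. Ratios are in
(0, 1] mathematically; at sub-5 Å distances the exponential
underflows to numerical zero, which is reported as such (total
bleaching).

## Ensemble geometry

Superposition is the Kabsch algorithm with the proper-rotation
determinant correction. Ensemble precision is reported in two
conventions because published "ensemble r.m.s.d." values rarely state
one: `to_mean` (default) superposes all conformers onto the evolving
mean structure and averages the per-conformer r.m.s.d. to that mean;
`pairwise` averages over all ordered conformer pairs. `to_mean` is
iterated to convergence of the mean (coordinate change < 10⁻¹⁰ Å,
capped at 50 passes) after a pre-alignment onto the first conformer
— a fixed two-pass scheme was considered but does not make the
statistic invariant to arbitrary rigid placements of the input
conformers, which the converged iteration does. Pairwise is never
smaller than to-mean (tested empirically over generated ensembles).
Superposition uses the backbone atoms (N, Cα, C, O) of the selection;
both backbone and heavy-atom (non-hydrogen) r.m.s.d. are reported.
Residue selections follow author numbering exactly as deposited.

## ITC binding models

The forward model tracks the cell contents through the injection
ladder with the perfusion convention: resident amounts are scaled by
$(1 - \Delta V_i/V_0)$, then the injected moles are added. Instrument
vendors use slightly different perfusion corrections; because the
same convention is used for generation and fitting, recovery of
(N, K_d, ΔH) is convention-independent. Sites are identical and
independent: $N$ counts sites per molecule of the *cell* species,
each binding one titrant molecule, and the bound-site concentration
solves the standard quadratic. The heat of injection $i$ is
$V_0\,\Delta H\,(B_i - B_{i-1}(1-\Delta V_i/V_0))$ in µcal.

The autoinhibited variant adds a pre-equilibrium: unbound receptor
partitions between an open state (binding with intrinsic $K_d$) and a
closed state inaccessible to ligand, with $k_{closed} =
[\mathrm{closed}]/[\mathrm{open}]$. This is the minimal model
consistent with an intramolecular ligand that an external peptide can
displace; partial-displacement kinetics are out of scope. The
species balance is solved numerically by bracketing the free-ligand
concentration (`solve_equilibrium`, tolerance 10⁻¹⁴ on the
concentration scale); analytically the model collapses onto a
one-site isotherm with $K_{d,app} = K_d (1 + k_{closed})$, and the
package verifies the two routes against each other. Fitting the
autoinhibited data with the plain one-site model therefore measures
exactly the apparent constant — the package's formalisation of how an
autoinhibitory extension "reduces the affinity".

Fitting profiles the two linear parameters (ΔH and a constant
heat-of-dilution offset, fitted by default since blank subtraction
can leave a residual) out of the least-squares problem by variable
projection, leaving Levenberg–Marquardt over $(\log N, \log K_d)$
only, followed by a central-difference Gauss–Newton polish. This
conditioning choice is what makes noiseless round trips exact to
better than 10⁻⁶ relative even at Wiseman $c \approx 1$. Initial
values: $N$ from the molar ratio at which the heat magnitude halves,
$K_d$ from a tenth of the cell concentration, with deterministic
restart nudges. The first injection (the small 0.4 µL point) is
excluded by default. The Wiseman parameter $c = N [\mathrm{cell}]/K_d$
is reported and fits outside $[1, 1000]$ warn. A fitted $N < 1$ with
a multivalent construct in the syringe means several cell-side
molecules engage one construct; `tandems_per_peptide()` performs that
role-aware conversion.

## Motif taxonomy

Ligand peptides are classified by a deterministic priority rule
operationalising the observed affinity ranking: (1)
`pplp_bridge_polyP` — a PPLP motif bridged by at most 4 non-proline
residues to a downstream run of ≥ 4 prolines (the architecture that
spans both WW domains); (2) `two_stretches` — at least two runs of
≥ 3; (3) `broken_stretch` — one run of ≥ 3 plus ≥ 2 scattered
prolines; (4) `spaced`. The thresholds (run ≥ 3, gap ≤ 4, polyP ≥ 4)
are exposed as arguments: the taxonomy is this package's
reconstruction of a qualitative figure, not a published rule, and the
tests assert only rule-application results. Among the nine reference
16-mers exactly one — the high-affinity site PPLPPGAPPPPPPPPP —
falls in the bridge class. The scanner's PPxP family matches both
PPxP and PxxPP arrangements so that known intramolecular motifs
(PPVP, PALPP) are both reported; proline-rich regions default to
≥ 8 prolines in a 16-residue window, the grain of the peptide
taxonomy.

## The synthetic-data generator

Every generator is a pure function of its parameters and a mandatory
seed, and uses the same forward-model code paths the fitters invert,
so zero-noise round trips are exact to solver tolerance by
construction — that is the point of the design, and it is what the
round-trip tests certify.

What the generator emulates: fast-exchange titrations as a single
peak moving linearly in bound fraction (tight-binding approximation,
bound fraction = min(ratio, 1)) and slow exchange as co-existing
free/bound peak lists with complementary intensities;
mono-exponential decays with a duplicated delay; two internally rigid
backbone domains (idealised geometry, N/Cα/C/O/Cβ per residue) joined
by a linker whose torsions are resampled per conformer around an
extended conformation, with rigid-body attachment of a fixed
domain template guaranteeing *exact* internal-coordinate identity
across conformers, and a 2 Å interdomain clash filter with bounded
retries; RDCs from a known Saupe tensor; PRE ratios from the labeled
ensemble; ITC heats from the forward models above with Gaussian
noise. Default noise magnitudes are typical experimental values:
0.002 ppm (¹H scale), 2 % of I₀, 0.5 Hz, 0.1 µcal.

What it does not emulate — and hence what passing tests do *not*
show about real data: spectral lineshapes and peak overlap,
intermediate-exchange broadening, proline cis/trans exchange,
force-field-quality ensembles, anisotropic diffusion, label rotamer
distributions, or instrument-specific ITC baseline artefacts. The
tests certify that the estimators invert their stated models
correctly; they cannot certify the models' adequacy for any
particular experimental system.

Since no enthalpies are printed in the sources this package is
validated against, the synthetic isotherms default to
ΔH = −8 kcal/mol, a typical exothermic magnitude for WW/polyproline
binding; dissociation-constant recovery is insensitive to the choice.

## Problem sizes and runtime

The shipped test-suite fixtures are deliberately small: 20–60 residue
titrations, 10-delay decay series, dumbbell ensembles of 1–20
conformers with 5–12 residues per domain, 26-injection isotherms, and
Monte-Carlo loops of 100–200 draws. These sizes exercise every code
path while keeping the full suite around half a minute on one core;
all statistics scale routinely to deposit-sized inputs (a 20-model
NMR ensemble of a ~100-residue protein).

## Known limitations

No ensemble-averaged RDC fitting, model-free relaxation analysis, or
CPMG dispersion; no multiple-timescale PRE models or solvent PRE; no
kinetic or displacement ITC and no global multi-experiment fitting;
no mmCIF support beyond what the PDB reader provides; the motif
classes are a reconstruction with exposed thresholds, not a published
assignment table.
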