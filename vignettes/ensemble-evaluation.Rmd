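---
title: "Evaluating protein conformational ensembles with EnsembleMetrics"
author: "EnsembleMetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating protein conformational ensembles with EnsembleMetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EnsembleMetrics)
```

# The problem

Generative models of protein conformational ensembles (and cheap surrogate
samplers in general) produce stacks of 3D structures that must be compared
against a reference — usually molecular-dynamics (MD) sampling — along several
orthogonal axes: backbone flexibility, side-chain rotamer statistics,
secondary-structure retention, native-contact foldedness, thermodynamic
response to temperature, and plain stereochemical sanity. EnsembleMetrics
implements this evaluation battery as a set of S4 containers
(`Ensemble`, `TorsionTable`, `NativeContactSet`, `MeltSeries`/`MeltFit`,
`MetricReport`) and camelCase functions, together with seeded synthetic
generators that make every score testable against known ground truth without
any external data.

All coordinates are Ångström, all angles degrees on $(-180, 180]$, all
temperatures Kelvin. Residue numbering is 1-based everywhere a user sees it.

# The scores

## Side-chain torsion divergence (chiJSD)

For every residue, each consecutive pair of side-chain torsions among
$(\chi_1,\chi_2), (\chi_2,\chi_3), (\chi_3,\chi_4)$ — as many as the residue
type defines (ARG/LYS have four $\chi$, ALA/GLY none) — is discretized into a
joint histogram on the 2-torus. Each axis has three bins with edges at
$-120^\circ, 0^\circ, 120^\circ$; values outside $[-120, 240)$ wrap around
the circle, giving 9 equally sized cells. These edges track the natural
gauche−/trans/gauche+ structure of most $\chi$ distributions. The score is

$$\mathrm{chiJSD} = \frac{1}{N_{\chi\,\mathrm{pairs}}}
\sum_i \sum_{(j,k) \in C_i} \mathrm{JSD}\!\left(X^i_{j,k}, \hat X^i_{j,k}\right),$$

the mean natural-log Jensen–Shannon divergence between the normalized
9-bin histograms of the two ensembles. It is symmetric, 0 for identical
rotamer statistics, and exactly $\ln 2$ when every pair has disjoint bin
occupancy. No pseudocounts are added; the JSD convention $0 \ln 0 = 0$
handles empty cells. Pairs with zero valid observations in either ensemble
are excluded from the mean and reported via attributes.

Bin boundaries are half-open, $[-120, 0)$, $[0, 120)$, $[120, 240)$, with
$[-180, -120)$ wrapped into the third bin; a boundary convention has to be
fixed somewhere and this one keeps every angle in exactly one cell (verified
by an exhaustive 1° sweep in the tests). Two-fold-degenerate terminal
torsions (ASP $\chi_2$, PHE/TYR $\chi_2$, GLU $\chi_3$) are *not* folded onto
$[0, 180)$: raw dihedrals preserve information, and symmetry folding is easy
to apply upstream if desired.

## Secondary structure element preservation (SSEP)

A three-state secondary structure (H/E/C) is assigned per frame from
backbone hydrogen-bond geometry: the classic electrostatic energy
$E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$ kcal/mol
with a bond called below $-0.5$ kcal/mol. Because the model is heavy-atom
only, the amide hydrogen is constructed 1 Å from N, antiparallel to the
preceding carbonyl — the standard device of trajectory-analysis DSSP
implementations. Helices come from consecutive 3-/4-/5-turns, strands from
parallel/antiparallel bridge patterns; 8-state classes collapse as
$\{H,G,I\}\to H$, $\{E,B\}\to E$, else C, with α-helix taking precedence in
conflicts. Assignments on ideal helices, isolated extended chains and a
β-hairpin were cross-checked against an independent DSSP implementation on
identical files and frozen into the test suite.

Given the native assignment $s^0$, a frame scores
$S(x) = N_{HE}^{-1} \sum_{i \in HE} \mathbf{1}[s_i = s_i^0]$ over the
natively helical/strand residues, and SSEP is the ensemble mean of $S(x)$.
A coil-only native leaves SSEP undefined (an error, not a silent 0).

## Native contacts, Q and the folded-state fraction

Native contacts are all residue pairs at least 3 apart in sequence whose
minimal heavy-atom distance in the native structure is at most 10 Å
(inclusive), with that distance stored as $d^0_{ij}$. Foldedness of a frame
is the soft logistic count

$$Q(x) = \frac{1}{N_\mathrm{contacts}} \sum_{(i,j)}
\frac{1}{1 + \exp\!\big(\beta (d_{ij} - \lambda d^0_{ij})\big)},
\qquad \beta = 5.0\ \text{\AA}^{-1},\ \lambda = 1.2,$$

where $d_{ij}$ is recomputed as the minimal heavy-atom distance over the
same pair. The folded-state fraction (FSF) of an ensemble is the fraction of
frames with $Q > 0.6$ (strict inequality); 0.6 is used as a fixed,
system-independent threshold. "At least 3 residues apart" is read literally
as $|i-j| \ge 3$; parts of the native-contact literature use $> 3$, so the
sequence-separation rule is centralized in `nativeContacts()`.

## Fluctuation and landscape metrics

* `rmsfProfile()` superposes every frame onto the initial structure over
  Cα atoms (Kabsch, no reflection) and reports per-residue RMSF about the
  *ensemble-mean* position. Fluctuation-about-the-mean matches common
  trajectory-analysis semantics; the alternative (deviation from the
  reference itself) is `initRmsd()`, reported separately.
* `rmsfPcc()` is the plain Pearson correlation of two RMSF profiles.
* `radiusOfGyration()` is mass-unweighted over heavy atoms — the model is
  hydrogen-free and unit masses keep the measure purely geometric.
* `contactMap()` counts Cα–Cα contacts at an inclusive 9 Å (0.9 nm) cutoff
  for $|i-j| \ge 2$.
* `fitLandscape()` runs PCA on centered, unscaled Cα–Cα distances of all
  non-adjacent ($|i-j| \ge 2$) pairs of a reference ensemble;
  `projectLandscape()` projects other ensembles on those axes. Features are
  left unscaled because all are in the same unit (Å) and scaling would
  inflate near-constant short-range distances.
* `freeEnergyGrid()` bins 2D projections into `bins`×`bins` uniform cells
  spanning the data range and applies $G = -RT \ln P$ with $P$ the raw
  frequency, $R = 8.314462618 \times 10^{-3}$ kJ/(mol·K); empty cells are
  masked (infinite $G$) and $G$ is shifted so its minimum is 0. Output in
  units of RT is available.

## Melting temperatures

`buildMeltSeries()` evaluates FSF or SSEP across temperature-labelled
ensembles; `fitSigmoid()` fits

$$f(T) = y_\mathrm{min} + \frac{y_\mathrm{max} - y_\mathrm{min}}
{1 + \exp\!\big(-(T - \hat T_m)/\hat k_\mathrm{slope}\big)}$$

by Levenberg–Marquardt least squares over $(\hat T_m, \hat k)$ only, with
$y_\mathrm{min}/y_\mathrm{max}$ fixed to the series extremes. The form rises
with $T$ for $k > 0$; decreasing observables (FSF, SSEP) simply fit a
negative $k$ rather than reordering the series, which keeps the printed
functional form intact. Initialization uses the linear-interpolated midpoint
crossing for $T_{m,0}$ and $k_0 = \pm 20$ K by series orientation; $\hat T_m$
is bounded to $[\min T - 100, \max T + 100]$ K and convergence is declared
by the optimizer (ftol $10^{-12}$, 500 iterations). Flat series raise
"no transition detected"; non-convergence returns the best iterate flagged
`converged = FALSE`. A Nelder–Mead fallback on the residual sum of squares
handles pathological inputs. `meltingTemperature()` composes both
observables and reports their $\hat T_m$ difference as a consistency
diagnostic; `deltaTm()` subtracts two converged fits.

## Stereochemical integrity

A *heavy clash* is a pair of heavy atoms from non-adjacent residues
($|i-j| \ge 2$) strictly closer than half the sum of their van der Waals
radii (Bondi: C 1.70, N 1.55, O 1.52, S 1.80 Å; the table is an argument).
A *peptide-bond violation* is an inter-residue C–N bond with
$|b - 1.348|/0.029 \ge 3$ (two-sided, inclusive): short bonds are violations
just as long ones are. Both counters are reported per frame and as
per-snapshot means. Note the exact $z = 3$ boundary is not representable in
binary floating point for these constants; tests bracket it at $\pm 10^{-9}$ Å.

## Restrained relaxation

`relaxEnsemble()` removes heavy clashes with minimal perturbation by
minimizing, per frame,

* harmonic bond terms (k = 300 energy/Å²) and bond-angle terms
  (k = 80 energy/rad²) toward idealized template geometry,
* planarity/chirality torsion terms (k = 40 energy/rad²) for peptide
  carbonyls, rings, sp² branches and the Cβ chirality improper,
* harmonic restraints tethering every $\phi/\psi/\omega/\chi_{1..4}$
  (circular difference, default 0.02 energy/deg²) and every adjacent
  Cα–Cα distance (default 20 energy/Å²) to its input-frame value,
* an optional half-quadratic steric repulsion
  $k_\mathrm{rep}\max(0, s(r_i + r_j) - d)^2$ over heavy-atom pairs with
  $|i-j| \ge 2$, $k_\mathrm{rep} = 15$, onset scale $s = 0.7$ by default,

with L-BFGS-B and analytic gradients (verified against finite differences in
the tests). Branch torsions of a displaced atom are restrained to their
*ideal* offsets relative to the input's canonical $\chi$, not to the
defective input value — this is what lets bond/angle restoration repair an
injected defect without fighting the restraints. The onset scale 0.7 was
chosen after observing that an onset of 0.8 engages on perfectly normal
helix packing (carboxylate-oxygen-to-backbone-nitrogen pairs near 2.2 Å) and
drags clash-free frames away from their input; at 0.7 a clash-free ideal
frame is a fixed point to ~4×10⁻⁶ Å while injected clashes still resolve
completely. Frames whose minimization fails (non-finite energy, energy or
clash count increase) are returned unmodified and flagged in the
diagnostics.

# The synthetic generators

The generators exist to make every score falsifiable offline:

* `buildIdealChain()` constructs heavy-atom chains from internal coordinates
  (NeRF placement). Side-chain branch geometry comes from chemical-component
  ideal templates; peptide C–N bonds are built at 1.348 Å so a fresh chain
  has zero bond violations by construction, and default rotamers were chosen
  so that helix and extended presets are clash-free for all 20 residue
  types. Construction is the exact inverse of `computeTorsions()` (round
  trips to ~10⁻⁶°), which is what makes the torsion machinery testable.
* `twoStateEnsemble()` draws each frame folded with probability
  $p(T) = 1/(1 + \exp((T - T_m^\mathrm{true})/k^\mathrm{true}))$; folded
  frames are native torsions plus 5° Gaussian jitter, unfolded frames are
  uniform-random $\phi/\psi/\chi$ rebuilds made self-avoiding by rejection
  (clash count ≤ 5 within 100 retries, best-effort otherwise — strict
  self-avoidance buys nothing for score testing). The realized folded count
  is recorded as ground truth.
* `rotamerEnsemble()` samples $\chi$ angles per frame so that consecutive
  chi-pair bins follow prescribed 9-cell probability tables; chains of more
  than two $\chi$ are sampled sequentially, conditioning each table's row on
  the previous angle's bin — exact when the tables are mutually consistent
  (point masses, products), which is what the oracles use.
* `gaussianNoiseEnsemble()` adds i.i.d. per-coordinate noise, whose RMSF
  limit $\sigma\sqrt 3$ anchors the fluctuation machinery.
* `injectDefects()` moves named atoms to prescribed clash distances
  (searching approach directions so exactly one new clashing pair results,
  with a 0.2 Å clearance margin elsewhere) and sets peptide bonds to target
  lengths by rigid translation of the downstream chain; it verifies the
  final clash set equals base-plus-intended and errors otherwise, so its
  manifests are guaranteed, not hoped for.

What the generators deliberately do **not** emulate: realistic unfolded-state
statistics (no Flory scaling, no solvent), correlated backbone/side-chain
motions, rotamer libraries conditioned on backbone, multi-chain assemblies,
or experimental noise models. Green tests therefore certify the *scores and
fits*, not any claim about real proteins.

# Problem sizes and determinism

The test suite and the acceptance script run on deliberately small systems:
16-residue helical natives, 30-residue fixtures for the contact oracle,
8-temperature sweeps of 200 frames for thermal recovery, 2000 frames for the
Gaussian RMSF limit. These sizes put every stochastic check several standard
errors away from its tolerance while keeping the whole battery in the
minutes range on one CPU. All randomness flows through explicit seeds; the
analysis functions themselves are deterministic.

# Known limitations

* DSSP here implements the hydrogen-bond core with simplified helix/strand
  pattern rules; rare edge classes (isolated bridges at chain termini,
  π-helix priority subtleties) may differ from full implementations — on
  fixture-style structures it matched an independent implementation exactly.
* The relaxer is a protocol, not a force field: no electrostatics, no
  attractive dispersion, no solvent. Its contract is clash removal under
  feature restraints, and only that contract is tested.
* PRO ring closure (CD–N) is maintained by bond/angle terms around
  template-consistent ring torsions, not by exact ring-closure kinematics.
* XTC trajectories are not read (no reader in the R dependency stack);
  multi-model PDB and DCD are. The test suite is PDB-only by design.
* `rotamerEnsemble()` matches prescribed pair tables exactly only when the
  per-pair tables are consistent with a single joint distribution.
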