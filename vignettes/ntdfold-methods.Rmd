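---
title: "Methods: a desk-scale helix-coil view of the H1 NTD disorder-to-order transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale helix-coil view of the H1 NTD disorder-to-order transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntdfold)
```

## The scientific question

The N-terminal domain (NTD) of the H1 linker histone is an intrinsically
disordered, lysine-rich peptide. Atomistic enhanced-sampling studies have
argued that the NTD undergoes a *disorder-to-order transition*: in isolation
it is unstructured, but when the repulsion among its Lys/Arg sidechains is
screened -- by artificial charge neutralization or, physiologically, by
binding the DNA phosphate backbone -- an amphipathic helix forms in the
basic subregion, concentrating the positive charge on one helical face. The
strength of this effect differs across human subtypes (H1.0 strongest,
H1.2 intermediate, H1.1 essentially none) and tracks their experimentally
measured nucleosome binding affinities.

`ntdfold` re-implements the full computational tool-chain behind that kind
of study at desk scale: sequence analytics (composition tables, helical
wheels), a coarse-grained (CG) helix-coil peptide model with a
charge-neutralization switch and a DNA-rod field, the enhanced-sampling
machinery (well-tempered metadynamics, the well-tempered ensemble,
temperature replica exchange, umbrella sampling), time-dependent bias
reweighting, ensemble analytics, and WHAM with Bayesian-bootstrap errors.
Every stochastic engine is validated against an exact or brute-force
oracle; microsecond atomistic results are *context*, not targets.

## The coarse-grained model

Each residue carries a binary helix/coil state. A state vector has
statistical weight

$$ W(\mathbf{s}) \;=\; \prod_{i\,:\,s_i = h} w_i \;\times\; v^{\#\text{runs}}, $$

i.e. energy $E_{hc} = -k_B T_{\mathrm{ref}} (\sum_{h} \ln w_i +
n_{\mathrm{runs}} \ln v)$. Three residue classes set $w_i$: Pro
(`w_pro`, default 0.02), Gly (`w_gly`, default 0.3) and everything else
(`w`, default 2.0); the nucleation weight `v` defaults to 0.05. Only these
features -- helix propagation, a nucleation penalty, and Pro/Gly as
breakers -- are modelled, because the subtype differences at stake are
attributed to charge density and Pro/Gly content. Using a reference
temperature $T_{\mathrm{ref}} = 300$ K inside $E_{hc}$ (rather than the
simulation temperature) makes the helix-coil bias a fixed energy scale, so
high-temperature replicas genuinely melt structure and the infinite-
temperature limit samples states uniformly.

Geometry: the C$\alpha$ trace uses a fixed virtual bond of 0.38 nm.
Maximal helical runs of $\ge 4$ residues are built on ideal
$\alpha$-helix geometry (0.15 nm rise and 100$^\circ$ twist per residue);
all other residues use per-residue coil angles drawn from a deliberately
broad uniform library (virtual bond angle 75--145$^\circ$, dihedral
uniform). The library aims only at a statistically reasonable coil
compaction, not Ramachandran fidelity.

Electrostatics: each Lys/Arg (+1) and Asp/Glu (-1) carries one pseudo-atom
0.25 nm off the backbone (His is treated as neutral). Pairs interact by a
screened Coulomb term $A\, q_i q_j e^{-r/\lambda_D}/r$ with
$\lambda_D = 0.78$ nm (0.15 M monovalent salt) and
$A = k_B \cdot 300\,\mathrm{K} \cdot 0.7\,\mathrm{nm}$, the Bjerrum
prefactor of water at 300 K. The `neutralized` switch zeroes the basic
charges. The optional DNA rod is rigid and straight -- one phosphate site
per bp per strand at radius 0.9 nm, 0.34 nm rise, 36$^\circ$ twist, the
central 11 bp flagged -- and attracts the positive pseudo-charges through
the same screened kernel scaled by `dna_strength`. No groove geometry is
modelled: the rod exists to support contact counting and radial-distance
free-energy profiles, nothing more.

Sampling is Metropolis Monte Carlo: single-residue state flips,
coil-dihedral perturbations, and (with a rod) rigid-body translations.
Everything runs on R's RNG, so a seed reproduces a run bit for bit.

### Exact oracles

Because the helix-coil part couples residues only through run bookkeeping,
its per-residue helicity and the expected number of all-helical six-residue
windows are computed *exactly* by a two-state transfer matrix
(`transfer_matrix_helicity()`, `transfer_matrix_salpha()`). For chains of
$\le 16$ residues with frozen coil geometry, `enumerate_states()` gives the
full Boltzmann distribution including electrostatics. The test suite holds
the MC sampler, the replica-exchange engine and the reweighting machinery
to these references.

## Collective variables

* `s_alpha`: for every contiguous six-residue window, the best-fit (Kabsch)
  C$\alpha$ RMSD to an ideal six-residue helix is passed through the
  rational switch $(1 - x^n)/(1 - x^m)$ with $R_0 = 0.08$ nm, $n = 8$,
  $m = 12$; the CV is the sum over the $L-5$ windows. Superposition is
  used because that is the standard realization of this CV family; all
  contiguous windows (stride 1) are included. The $x = 1$ singularity is
  evaluated as $n/m$ with a $10^{-9}$ guard band. An ideal helix of length
  $L$ scores exactly $L-5$.
* `s_rg`: mass-weighted RMS distance of the C$\alpha$ atoms from their
  centre of mass.
* `s_cont`: the smooth contact count between positive sidechain sites and
  the central-11-bp phosphates, same switch with $R_0 = 0.2$ nm, $n = 8$,
  $m = 10$. In the CG representation the donor set is the single charge
  pseudo-atom of each Lys/Arg. Note the $m - n = 2$ tail decays only as
  $(r/R_0)^{-2}$, so distant donors contribute small non-zero counts.
* `rdist`: the distance between the peptide C$\alpha$ centroid and the rod
  centre in the plane normal to the rod axis.

The helicity CV supports a dual mode: C$\alpha$-only templates for CG
conformations (the model has no other atoms) and, for PDB input, the
backbone + C$\beta$ convention via the dihedral-based secondary-structure
assignment described below.

## Enhanced sampling

`meta_bias()` objects accumulate Gaussians; with bias factor $\gamma$ the
deposit height decays as $W e^{-V/(k_B \Delta T)}$, $\Delta T =
(\gamma-1)T$, and $\gamma = \infty$ reproduces fixed-height deposition. The
production default is $\gamma = 10$, height 1 kJ/mol, widths of order the
CV resolution (0.1), deposition every 500 sweeps; these live in the run
configuration because no canonical CG values exist.

`run_ptmetad_wte()` follows the two-stage protocol: a preliminary stage
biases the *potential energy* of every replica (height 2.5 kJ/mol, bias
factor 50, deposition every 250 sweeps by default; the kernel width is
auto-estimated from a short unbiased run since a CG system's energy scale
is far from atomistic values), which broadens the energy distributions --
this is the well-tempered ensemble. That bias is then frozen, and
production metadynamics runs independently per replica on conformational
CVs. Exchanges alternate even/odd adjacent pairs; the acceptance rule is
the bias-aware Metropolis expression, which `exchange_probability()`
implements verbatim, and which reduces exactly to the plain
temperature-exchange factor at zero bias. The frozen WTE bias is a
function of $U$ identical in form on every replica, so the driver folds it
into the effective potential energy of each replica rather than into the
CV-bias terms; the two bookkeepings agree for detailed balance, and this
one is simpler to verify.

The ladder is geometric, $T_i = T_{\min} (T_{\max}/T_{\min})^{(i-1)/(N-1)}$.
One nominal "ps" of the cited schedules maps to 10 MC sweeps in the run
configuration; the CG model has no physical clock and this constant only
sets stride bookkeeping.

`run_umbrella()` adds $\tfrac12 k (s - s_0)^2$ per window. Two
initialization policies are provided: `"chain"` (each window continues
from the previous one -- the stepwise-dragging protocol of the atomistic
studies) and `"center"` (each window starts fresh at its own center).
For the CG peptide-rod system the adsorbed state is sticky enough that
chaining shows visible hysteresis at desk-scale window lengths, so the
bundled demonstrations use `"center"`; both are tested.

## Reweighting

A metadynamics trajectory is unbiased with time-dependent weights
$w(t) \propto e^{\beta [V(s(t),\,t) - c(t)]}$. The offset $c(t)$ is the
log-ratio of partition integrals of $F$ and $F + V(\cdot,t)$, with $F$
taken from the bias at the same time through the well-tempered relation
$F = -\tfrac{\gamma}{\gamma-1} V$; integrals use trapezoidal quadrature on
a fixed grid (201 points per CV spanning the sampled range plus 3$\sigma$)
and $c$ is interpolated linearly between evaluation times. Degenerate
limits are exact: a zero bias yields $c \equiv 0$ and uniform weights; a
constant bias $\kappa$ yields $c = \kappa$. Weights are max-shifted before
exponentiation, so a shared additive constant in $V$ and $c$ cannot
overflow or change the normalized weights.

## Ensemble analytics

* Secondary structure: no external assignment program is called. A CG
  residue is "helical" when it sits in a run of $\ge 3$ helical states
  (runs of exactly 3 are the 3$_{10}$-like motif, longer runs
  $\alpha$-like; both count toward helicity, matching the usual
  $\alpha + 3_{10}$ convention). For atomistic dihedrals the window is
  $\phi \in -57 \pm 30^\circ$, $\psi \in -47 \pm 30^\circ$ over $\ge 3$
  consecutive residues.
* Compaction baselines: $R_g^{\mathrm{glob}} = 2.2 N^{0.38}$ and
  $R_g^{\mathrm{coil}} = 2.02 N^{0.60}$ (Angstrom). The model works in nm
  and converts explicitly at this interface, as it does for the 2.5
  Angstrom clustering and 3.2 Angstrom contact cutoffs.
* Clustering: single linkage, i.e. the transitive closure of "best-fit
  C$\alpha$ RMSD < 2.5 Angstrom". The $O(n^2)$ RMSD matrix is computed on
  at most 2000 frames (the stride is recorded). Cluster populations are
  reweighted frame weights; representatives are highest-weight members.
* Free-energy surfaces come in two modes -- from the bias
  ($-\tfrac{\gamma}{\gamma-1}V$) and from weighted histograms
  ($-k_BT\ln$) -- and the test suite requires them to agree on a converged
  run. Empty bins are masked, never imputed, and minima are only reported
  where a sampled neighbour certifies them.
* WHAM: the standard self-consistent iteration (tolerance $10^{-6}$
  kJ/mol on the window constants, $10^5$ iteration cap), with adjacent
  windows checked for histogram overlap (failure names the gap). The
  profile zero is anchored at large distance, estimated as the mean of the
  outermost two sampled bins. Bayesian bootstrap draws unit-mean
  exponential weights over *complete windows* -- the trajectory, not the
  sample, is the resampling unit -- and reruns WHAM per replicate.

## What the synthetic generator emulates, and what it does not

The generator reproduces, qualitatively: sequence-dependent helix
propensity with Pro/Gly as breakers; suppression of helicity by
electrostatic repulsion among basic sidechains; its release upon charge
neutralization; compact-coil versus helical $R_g$ statistics; and
adsorption of a polycation to an oppositely charged rod. It does *not*
emulate: atomistic packing or hydrogen bonding, water or explicit ions,
$\beta$ structure, groove geometry or sequence-specific DNA binding, or
any physical timescale. Consequently, passing tests demonstrate that the
*method implementations* are correct and that the model reproduces the
qualitative subtype physics; they say nothing quantitative about real
peptides. Published atomistic numbers (free-energy minima near
$S_\alpha \approx 4.4$, basin gaps of a few kJ/mol, PMF depths of 15--20
kJ/mol) are not desk-reproducible and are treated only as context; the CG
peptide-rod PMF depth, for instance, is an order-of-magnitude analogue
with substantial seed-to-seed variance at the bundled run lengths.

## Bundled sequences and the composition table

The H1.0 NTD (26 residues, `MTENSTSAPAAKPKRAKASKKSTDHP`) is fully
determined by the published composition and motif anchors. The H1.1 and
H1.2 NTD records bundled in `inst/extdata/ntd_subtypes_synthetic.fasta`
are *synthetic reconstructions*: the source figure's sequences are not
recoverable from text, and its residue numbering is internally
inconsistent in places (for H1.2, the printed helix span and the printed
basic-face residues disagree; similar for one H1.1 loop residue). The
reconstructions reproduce the published basic-subregion composition
exactly -- H1.0: 10 residues, 6 Arg/Lys (60.0%), 1 Pro/Gly; H1.1: 21, 9
(42.8%), 3; H1.2: 18, 8 (44.4%), 4 -- and keep the printed motif strings
where they are self-consistent (`PVKKKAAKKAGG`, the G-G breaker pair,
`RKAS`, `KPLA`). Percentages in the composition table are *truncated* to
one decimal (9/21 prints as 42.8), because that is the convention the
printed table follows; prose percentages elsewhere use ordinary rounding
(6/26 prints as 23.1), and `composition_stats()` follows the table.

## Cross-subtype helicity comparison

The subtype claim -- neutralization induces helicity in the order
H1.0 > H1.2 > H1.1 -- is evaluated on the *per-window normalized* CV,
$\langle S_\alpha \rangle / (L-5)$. The basic subregions differ in length
(10, 18, 21 residues), so the raw window count trivially scales with
length and would compare peptide sizes rather than propensities;
normalizing by the window count makes the quantity an intensive helical
propensity, which is also what per-residue helicity plots compare. Under
the shipped defaults the ordering holds both in MC sampling and in the
exact transfer matrix, and `scripts/calibrate_model.R` shows it is stable
across a broad region of the (w, w_pro, w_gly, v) space rather than a
tuned point.

```{r ordering, eval = FALSE}
subs <- lapply(ntd_fixture_sequences(), extract_basic_subregion)
vapply(subs, function(s) {
  transfer_matrix_salpha(
    model_params(s, neutralized = TRUE), normalized = TRUE
  )
}, numeric(1))
#>      H1.0      H1.1      H1.2
#> 0.2590598 0.0820459 0.2156482
```

## Numerical conventions and problem sizes

Units are kJ/mol, nm and K throughout, with $k_B = 0.0083145$ kJ/mol/K;
Angstrom appears only at the documented literature cutoffs. Residue
numbering is 1-based inclusive. Hard-core overlap of charge sites
($r < 0.01$ nm) returns a rejection-scale energy rather than an
exception inside the sampler.

The bundled validation runs use desk-scale sizes chosen so each check has
comfortable statistical margin: $1.6 \times 10^5$ steps for the double-well
metadynamics recovery (RMS target 0.5 kJ/mol after removing the arbitrary
constant), $10^5$ sweeps for the six-residue reweighting oracle, 29
umbrella windows of 8000 sweeps for the WHAM oracle, and $3 \times 10^4$
sweeps per subtype/charge condition for the helicity ordering. These sizes
are statements about statistical sufficiency of the checks, and the
calibration scan documents that none of the scientific conclusions depend
on them finely.

## Known limitations

* The transfer-matrix oracle covers only the charge-free Hamiltonian; with
  charges on, validation falls back to enumeration at small $L$.
* Rigid-body orientation sampling of the peptide at the rod surface is
  slow; CG PMF depths are reproducible in sign and rough magnitude, not to
  fractions of $k_BT$.
* The coil library is not Ramachandran-weighted, so coil-state $R_g$
  distributions are broader than experiment.
* `s_cont`'s slow switch tail means "zero contact" reads as a small
  positive number at finite distance; thresholds in analyses should use
  the documented cutoffs rather than exact zero.
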