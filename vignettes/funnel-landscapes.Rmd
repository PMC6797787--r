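---
title: "Constructing folding free-energy landscapes with funnelscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing folding free-energy landscapes with funnelscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelscape)
```

## The model

The landscape this package constructs is the graph of the *effective
energy* of a single protein configuration $\mathbf{r}$,

$$f(\mathbf{r}) = E_u(\mathbf{r}) + G_{\mathrm{solv}}(\mathbf{r}),$$

the gas-phase potential energy plus the solvation free energy.  Because
$f$ is defined per configuration it carries no configurational entropy;
the probability of observing $\mathbf{r}$ is
$P(\mathbf{r}) \propto e^{-f(\mathbf{r})/k_BT}$.  The high-dimensional
landscape is reduced onto the fraction of native contacts,

$$Q(\mathbf{r}) = \frac{1}{N}\sum_{(i,j)}
  \frac{1}{1 + e^{\beta_{sw}(r_{ij} - \lambda r^0_{ij})}},$$

a smooth switching sum over the native heavy-atom contact pairs, and the
reduced landscape $f(Q)$ is the conditional average of $f(\mathbf{r})$
over configurations at each $Q$, computed here by binning.  The *slope*
of $f(Q)$ measures the global funneledness: how much effective energy is
gained per fraction of native contacts formed.  It is distinct from the
free-energy *profile* $F(Q) = -k_BT\log P(Q)$; the two are connected by
the configurational-entropy profile,
$F(Q) = f(Q) - T S_{\mathrm{config}}(Q)$, which the package computes by
subtraction of the two independently estimated curves.

For coupled folding and binding, the effective energy of the folding
partner inside a complex is extended by the solvent-averaged binding
potential $\Delta f_{\mathrm{int}} = \Delta E_{\mathrm{int}} +
\Delta G_{\mathrm{solv}}$, where $\Delta E_{\mathrm{int}}$ is the direct
inter-partner interaction energy and
$\Delta G_{\mathrm{solv}} = G_{\mathrm{solv}}(AB) -
[G_{\mathrm{solv}}(A) + G_{\mathrm{solv}}(B)]$ at identical coordinates.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| contact cutoff | 4.5 (all-atom), 6.5 (bead) | A | native-pair definition |
| min. sequence separation | 4 (all-atom), 3 (bead) | residues | excludes trivial neighbours |
| $\beta_{sw}$ | 5 | 1/A | switching steepness of Q |
| $\lambda$ | 1.8 | -- | switch midpoint at $\lambda r^0$ |
| bin width | 0.05 | Q | 20 landscape bins |
| blocks | 5 | -- | block-analysis error estimate |
| temperature | 300 | K | enters $F(Q)$ and all entropies |
| $k_B$ | 0.0019872041 | kcal/mol/K | natural-log convention |

The all-atom contact convention (4.5 A between heavy atoms, four
residues apart, $\beta_{sw} = 5$/A, $\lambda = 1.8$) is the standard
fraction-of-native-contacts parameterization.  At one bead per residue
no $i,i{+}4$ pair sits inside 4.5 A (an ideal-helix $C_\alpha$
$i,i{+}4$ distance is about 6.2 A), so the bead-model generators default
to 6.5 A and separation 3.  Every parameter is config-exposed and every
CLI run records all effective values in its metadata sidecar.

Two conventions are worth calling out because the fit depends on them:

* **Slope abscissa.** The funnel line is fit by unweighted least squares
  through the occupied-bin points (mean $Q$ in bin, mean $f$ in bin).
  Using the bin's mean $Q$ rather than its midpoint keeps the fit exact
  whenever the samples lie exactly on a line, independent of how $Q$ is
  distributed within bins; a count-weighted fit is available behind the
  `weighted` flag.
* **References.** The landscape is referenced to its lowest-$Q$ occupied
  bin ($f(Q{=}0)$ anchor), the profile to its minimum, and the entropy
  profile -- defined only up to an additive constant because its two
  inputs carry different references -- to the lowest-$Q$ bin shared by
  both.  Empty interior bins are reported as gaps and never
  interpolated, so no landscape structure is fabricated.

## Error analysis

Standard errors of the slope, of $\langle f\rangle$ and of entropy
estimates come from block analysis: the trajectory is split into five
contiguous equal segments in frame order, each block is analysed
identically, and the SE is the standard deviation of the per-block
estimates over $\sqrt{n_{\mathrm{blocks}}}$.  The slope *value* is
invariant to frame reordering; the block SE is not, since blocks encode
temporal correlation -- that is the point of the construction.  With
five blocks the SE itself carries four degrees of freedom, so a
$\pm3\,\mathrm{SE}$ band has roughly 96% coverage rather than the
Gaussian 99.7%.

## Energetics and the solvation surrogate

`gas_phase_energy()` evaluates a deliberately small force field --
harmonic bonds, Lennard-Jones, Coulomb (332.0637 kcal A/(mol e^2), no
cutoffs), and 12-10 Go contact terms -- and itemizes every pair term in
a ledger.  Solvation free energies are consumed from precomputed
per-frame tables (the intended route when an external solver such as an
integral-equation theory has been run) or evaluated by a built-in
**surrogate**: a generalized-Born-style screened electrostatic term
(effective dielectric 78.5) plus Born self-terms and a finite-range
sphere-overlap exposed-area term ($\gamma = 0.005$ kcal/mol/A^2, probe
1.4 A).  The surrogate is a pairwise- and residue-decomposable stand-in
for testing and fixtures -- it is tagged `"surrogate"` in every output
and is not an integral-equation solvation model.  When both a table and
the surrogate are supplied the call errors rather than silently
preferring one.

## Exact site-directed decomposition

The average binding potential is decomposed into per-residue
contributions without mutating anything: each inter-partner pair term is
split half/half between its two residues, and each residue's solvation
part is its contribution in the complex minus its contribution in its
free partner at identical coordinates.  The half-split is this package's
convention; it is chosen because it yields a single partition of
$\langle\Delta f_{\mathrm{int}}\rangle$ over all residues of both
partners that is exact to rounding error per frame and in the average --
the defining invariant, enforced in code.  An alternative
`partner-full` attribution (each side's residues receive the full pair
value, so each partner's direct sums equal
$\Delta E_{\mathrm{int}}$) is provided for comparison and is *not*
exact over all residues.  Group sums over neutral and charged residues
(charged = Asp, Glu, Lys, Arg, phosphoserine; His neutral; overridable
per residue via a class table) always reassemble the total.

One scope choice: the bound-state effective energy is
$f = f_{\mathrm{partner}} + \Delta f_{\mathrm{int}}$ exactly -- the
other partner's self-energy is excluded, so bound and free landscapes of
the folding partner are directly comparable.

## Thermodynamic assembly

The thermodynamic free energy is $F = \langle f\rangle -
TS_{\mathrm{config}}$ with
$S_{\mathrm{config}} = -k_B\int d\mathbf{r}\,P\ln P$.
$S_{\mathrm{config}}$ is estimated quasi-harmonically: frames are
least-squares superposed onto their mean structure, and the entropy is
the Gaussian value $\tfrac{k_B}{2}\sum_m \ln(2\pi e\lambda_m)$ over
covariance eigenvalues above a floor (`mode_tol`, default $10^{-8}$
A^2), which automatically drops the near-zero rigid-body modes.  Unit
masses keep the estimate consistent with the configurational partition
function in Angstrom units, so that on a harmonic fixture
$\langle f\rangle - TS_{\mathrm{config}}$ reproduces $-k_BT\ln Z$
(closure verified to $10^{-2}$ kcal/mol at $2\times10^5$ frames in the
tests).  The estimator is a stand-in choice, recorded as
`"quasi-harmonic"` in all outputs and pluggable.

Binding adds the external entropy: the loss of relative translational
and rotational freedom on complexation, estimated from Gaussian
fluctuation volumes of the bound ensemble against the 1 M standard
state,

$$T\Delta S_{\mathrm{ext}} = k_BT\left[
  \ln\frac{(2\pi e)^{3/2}\sigma_x\sigma_y\sigma_z}{V^0}
  + \ln\frac{(2\pi e)^{3/2}\sigma_\alpha\sigma_\beta\sigma_\gamma}
            {8\pi^2}\right],$$

with $V^0 = 1660.5$ A^3.  Translational fluctuations are principal-axis
standard deviations of the relative center-of-mass displacement after
superposing each frame on partner A; rotational ones are rotation-vector
fluctuations of partner B about its mean orientation (omitted for
partners without orientational degrees of freedom, e.g. single beads).
Standard deviations below $10^{-3}$ A (or rad) raise an error instead
of returning a divergent entropy.  The standard binding free energy is
assembled as
$\Delta G^0_{\mathrm{bind}} = \Delta\langle f\rangle -
T(\Delta S_{\mathrm{config}} + \Delta S_{\mathrm{ext}})$ with
$\Delta X = X_{\mathrm{complex}} - (X_A + X_B)$ and errors propagated
in quadrature.  $\Delta S_{\mathrm{config}}$ is the change in *internal*
(per-partner superposed) entropy, keeping it disjoint from the external
term.  On a harmonic two-bead dimer this assembly reproduces the
analytic $-k_BT\ln\!\big[(2\pi k_BT/k)^{3/2}/V^0\big]$ within 0.2
kcal/mol.

## What the synthetic generators emulate -- and what they do not

`generate_toy_chain()` builds one-bead-per-residue chains (ideal helix:
rise 1.5 A, radius 2.3 A, 100 degrees/residue; or a two-strand hairpin)
with harmonic bonds ($k = 100$ kcal/mol/A^2, $b = 3.8$ A) and Go
contacts ($\varepsilon = 1$ kcal/mol) placed exactly on the native
contact set -- the smallest model in which $Q$, $E_u$ and
folding/unfolding are all meaningful.  `sample_ensemble()` runs
single-bead Metropolis Monte Carlo on $E_u$; it satisfies detailed
balance (verified against the Boltzmann bond-length distribution) and is
bit-reproducible from its mandatory seed.  `generate_slope_samples()`
draws $(Q, f)$ pairs with a known conditional-mean slope and Gaussian
noise, emulating the statistical structure of a funneled landscape
without any mechanics.  `generate_complex_fixture()` docks two helices
with a seeded Go/charge interface and emits a scalar-loop ground-truth
ledger of every interaction term; the docking gap (9 A) keeps the
partners outside the surrogate's finite occlusion range so the ledger is
exact.

These generators emulate the *statistical* structure of the real
problem -- a conditional mean of $f$ linear in $Q$, block-correlated
noise, an exactly decomposable interaction -- not its physics: no
explicit solvent, no realistic side chains or force fields, microsecond
sampling or integral-equation solvation energies.  Passing tests
therefore demonstrate that the estimators are correct and exact where
exactness is claimed, not that any particular protein's published slope
would be reproduced; published values (slopes near -50 kcal/mol for
ordered proteins, about -24 for a free disordered chain) enter the test
surface only as the true parameters of synthetic ensembles, which the
estimators recover within their reported errors.

## Numerical choices and degenerate inputs

* Bins are half-open $[q_{\mathrm{low}}, q_{\mathrm{high}})$ with the
  last bin closed at $Q = 1$; contacts exactly at the cutoff are
  included.
* Ledger conservation (itemized terms sum to totals) is enforced at
  $10^{-10}$ relative; decomposition exactness at $10^{-8}$ relative.
* Single-occupied-bin landscapes warn and make the slope an error
  downstream; a block with fewer than two occupied bins is an error
  suggesting fewer blocks; frozen ensembles are a degenerate-ensemble
  error rather than $-\infty$ entropy.
* Contact ranking breaks ties by residue index; all generator RNG is
  local to the call (the global RNG state is saved and restored).

Problem sizes used by the test-suite and the acceptance script --
50,000-sample slope ensembles with 100 replicates per slope, 100
ten-frame complex fixtures, $2\times10^5$-frame Gaussian ensembles --
were chosen as the smallest sizes at which estimator noise sits well
inside the tolerances being checked.

## Known limitations

Trajectory input is multi-model PDB (binary DCD/XTC readers are not
provided); coordinates are assumed unwrapped, with no periodic-box
handling.  The gas-phase model has no angle/dihedral terms and imports
no biomolecular force field.  The quasi-harmonic estimator assumes a
unimodal, roughly Gaussian ensemble -- it overestimates the entropy of
multi-state ensembles; the external-entropy closed form assumes
single-basin Gaussian fluctuations of the bound complex.  2D landscapes,
temperature reweighting, and kinetic analyses are out of scope.
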