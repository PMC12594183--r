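---
title: "Methods: anchor-guided docking and biophysical analysis with anchordock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-guided docking and biophysical analysis with anchordock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchordock)
```

## The modelling problem

Sirtuin deacetylases engage their protein substrates through two coupled
interfaces: the catalytic domain (CD) threads the acetyl-lysine-bearing
segment of the substrate into its active-site groove, while an ordered
three-helix bundle in the N-terminal domain (the NTD 3-helix bundle,
"NTD(3HB)") can clamp the substrate from a second side. No crystal
structure exists for a sirtuin bound to a *native* substrate protein, so
complex models must be assembled from pieces: a receptor structure with a
short acetyl-peptide bound, a substrate domain whose modified lysine sits
on a flexible loop, and the accessory bundle connected to the CD by a
flexible linker of known maximum span.

`anchordock` implements that assembly as a reusable, testable protocol:

1. **Anchor-window identification** — across several aligned
   sirtuin–peptide complexes, find the contiguous peptide positions whose
   backbone geometry is most conserved. In real sirtuin structures these
   are offsets −1, 0, +1, +2 relative to the acetylated residue
   (`anchor_variance()`).
2. **Conformer sampling** — sample conformations of the substrate loop
   with an elastic-network generator run over generations with an
   expanding cluster cap (`sample_generations()`).
3. **Anchor docking** — superpose each conformer's anchor-window backbone
   onto the bound reference peptide and keep the rigid pose
   (`dock_by_anchor()`), rejecting poses with steric clashes.
4. **Ensemble reduction** — cluster the accepted poses and keep ~60
   representatives (`reduce_ensemble()`).
5. **Accessory placement** — re-attach the NTD(3HB) under a linker
   distance restraint (`sample_placements()`).
6. **Trajectory metrics** — given multi-frame coordinates of a model,
   report the fraction of native contacts *Q*, residue contact-frequency
   maps, and inter-domain geometry series (`q_fraction()`,
   `contact_frequency()`, `domain_geometry_series()`).

A companion layer reproduces the biophysics used to constrain such models:
sedimentation-velocity hydrodynamics (`s_to_s20w()`, `mass_from_s()`,
`rh_from_mass()`), Hill fits of polarization titrations and thermal melts
(`fit_hill()`, `fit_melt()`), nanoDSF inflection temperatures
(`first_derivative_ti()`), and Welch t-tests (`unpaired_ttest()`).

## Elastic-network sampler: what stands in for what

The published loop-sampling method combines elastic-network deformation
with force-field relaxation (energy minimisation and implicit-solvent
heating) between generations. That relaxation requires a molecular
mechanics engine and is deliberately **not** reproduced here. Instead,
`sample_generations()` does pure geometric mode-following:

* an anisotropic network model (ANM) is built on the Cα trace (cutoff
  15 Å, uniform spring constant); its Hessian has exactly six zero modes
  for a connected network, which the tests enforce;
* each child conformer displaces along a uniformly random combination of
  the first five non-rigid modes, **scaled so the child–parent Cα-RMSD
  equals `step_amplitude`** (default 1.5 Å, a loop-scale perturbation).
  Amplitude control replaces thermal/energetic control; the deformation
  magnitude is exact by construction rather than emergent;
* all atoms of a residue move with its Cα (a coarse-grained
  reconstruction), so backbone anchors remain available for docking;
* per generation the child pool is clustered on pairwise Cα-RMSD with
  average linkage, cut at the generation's cap (20·g, to 200 at
  generation 10), and representatives seed the next generation.

Because the deformations live in the span of the non-rigid modes, all
conformers share one coordinate frame, and the pairwise RMSD used for
clustering is computed **without re-superposition** (a Euclidean distance
on flattened coordinates). This is both principled — no rigid motion is
ever introduced — and what keeps thousand-frame pools fast.

Consequences to keep in mind: conformers are not energy-relaxed (bond
geometry degrades slightly at large amplitude), and the published
"~3000 configurations" cannot be matched exactly — the cumulative
representative count of the default schedule is 1070, which the tests
check only as an order of magnitude (500–3000).

## Docking and filtering conventions

* **Window atoms** are backbone {N, CA, C, O}; side chains vary across
  structures and would blur the anchor.
* **"No significant clashes"** has no published definition; here it is
  `clash_count == 0` with a heavy-atom contact distance of 2.5 Å, both
  configurable. Clash counting excludes the reference peptide (which the
  substrate loop replaces) and, optionally, a named accessory selection
  detached before docking and re-attached at the placement stage.
* **Ensemble reduction** clusters substrate Cα coordinates in the common
  receptor frame (no double fitting). Whether the original clustering used
  full-complex or substrate-only coordinates is unstated; substrate-only
  is the default here since the receptor is common to all members. The
  cluster representative is the member with the lowest anchor RMSD to the
  reference peptide, ties broken by clash count and then input order, so
  the reduction is deterministic for a fixed input ordering.

## Accessory placement

FFT-based rigid docking is replaced by transparent rejection sampling:
uniform random orientations (quaternion method), positions uniform in a
**fixed** sampling ball (default radius 40 Å) around the restraint partner
atom. A pose is retained when (i) the restraint atom falls within
`max_distance` (25 or 30 Å are the conventional linker limits), (ii) it has
zero heavy-atom clashes, and (iii) at least `min_contacts` (default 10)
inter-domain heavy-atom pairs lie under 5 Å — the contact filter removes
grazing poses; ranking is by contact count. Drawing the randomness once,
independent of `max_distance`, guarantees the tested subset property:
poses retained at 25 Å are a subset of those retained at 30 Å at a fixed
seed. Which atoms define the restrained "termini" is not standardised;
the default is the terminal Cα of each domain, and the choice is exposed
in `restraint_spec()`.

## Trajectory metrics

The fraction of native contacts follows the Best–Hummer–Eaton soft count

$$Q(X) = \frac{1}{N}\sum_{(i,j)} \frac{1}{1 + e^{\beta\,(r_{ij}(X) - \lambda r^0_{ij})}}$$

over inter-domain heavy-atom pairs within 5 Å in the reference frame
(by convention the *last* frame of a production run, but any frame may be
chosen). β is a sharpness in Å⁻¹ (default 5) and λ a dimensionless
tolerance (default 1.8): source texts sometimes attach "Å" to both, but
dimensional consistency of the exponent requires β in inverse length and
λ unitless, and that is how the package interprets them. Contact maps use
the minimum inter-residue heavy-atom distance under 5 Å, per frame, over a
stated window — the convention "analyse the last 40% of frames"
(`last_fraction_window()`) mirrors analysing the last 800 ns of a 2 µs
run. Hydrogens are never counted (crystal-structure convention; whether
the original maps counted them is unstated). Equilibration detection
(`detect_equilibration()`) is descriptive only and never auto-applied.

## Hydrodynamics

Sedimentation coefficients observed in buffer are standardised to water at
20 °C ( ρ = 0.99823 g/mL, η = 1.002 cP ):

$$s_{20,w} = s_b\,\frac{\eta_b}{\eta_{20,w}}\cdot\frac{1 - \bar v\rho_{20,w}}{1 - \bar v\rho_b}$$

and mass follows from the Svedberg equation with Stokes friction of the
equivalent sphere,
$M = \left[ s\,N_A^{2/3}\,(f/f_0)\,6\pi\eta\,(3\bar v/4\pi)^{1/3} / (1-\bar v\rho)\right]^{3/2}$,
with $R_H = (f/f_0)(3M\bar v/4\pi N_A)^{1/3}$. Two interpretation choices
are worth recording. First, a quoted buffer viscosity of "0.0144" is taken
as **poise** (1.44 cP), the only dimensionally sane reading for a 10%
glycerol buffer (water ≈ 0.01 P). Second, where a results table lists a
species with observed 3.24 S and standardised 3.41 S while the running
text quotes "3.41 S" as if observed, the package follows the table: the
text evidently quotes the standardised value. A single frictional ratio
(e.g. 1.37) is applied to all species of a run, with per-species override.
Agreement with published tables is limited by the rounding of the printed
inputs; the acceptance tolerance of ±3% reflects that, and the package's
own inversion is exact (round-trip `mass_from_s(s_from_mass(M)) = M` to
1e-9 relative).

## Assay fitting

"Hill1" is Origin's four-parameter sigmoid
$y = base + (amp-base)\,x^n/(k^n+x^n)$; one kernel backs both the
titration fit (k = K\_D) and the melt fit (k = T\_m, n absorbing the
transition steepness), so there is a single tested code path.
Initialisation: plateaus from the signal extremes, k from the abscissa
nearest half-signal, n = 1 (titration) or 30 (melt); `port` algorithm,
tolerance 1e-10, 10 000 iterations. Whether the original fits fixed n = 1
is unstated, so both free-n (default) and fixed-n modes exist. A melt fit
additionally requires the sigmoid to explain ≥ 80% of the signal variance
and the midpoint to lie inside the scanned range — otherwise it is flagged
non-converged rather than reporting a meaningless midpoint. T\_i is the
temperature of the extremal smoothed first derivative (centered moving
average, default 5 points — the instrument software's smoothing is
unspecified); all local extrema above 20% of the global one are listed so
double transitions are visible. The two-group comparison is the **Welch**
unequal-variance t-test: with triplicates, equal variances are
unverifiable, and Welch is the conservative choice (a pooled-variance
tool would differ slightly).

## The synthetic world

`make_toy_complex()` builds the smallest geometry that exercises every
distance rule: ideal α-helices (rise 1.5 Å, 100°/residue, Cα radius
2.3 Å) form a 40-residue receptor groove flanking a 6-residue extended
reference peptide whose central residue is flagged as the acetyl-lysine
analog (resname `ALY`); the substrate repeats that peptide backbone as its
flexible loop (Gaussian jitter `loop_flex_sigma`, default 0.3 Å) fused to
a body helix extending away from the receptor, so a clash-free docked
solution exists by construction; a three-helix bundle stands in for the
accessory domain. `make_trajectory()` plants atom-pair contacts at exact
Bernoulli frequencies (3.9 Å in contact, 6.5 Å apart otherwise) over a
jittered topology, and `make_assay_data()` draws titration/melt/nanoDSF
tables from the stated generative models with homoscedastic Gaussian
noise (σ = 3% of the dynamic range by default, matching a triplicate
design). Assay ground-truth scenarios use experimentally reported values
(K_D 0.24 µM, T_m 45.11/46.26/43.60 °C, T_i 52.19 °C) as generator
settings — a green recovery test establishes that the *estimator*
recovers a known truth under the stated noise, **not** that the
experimental numbers themselves are reproduced; raw assay data is not
available, so they cannot be.

What the toys do not emulate: side chains and rotamers, realistic loop
closure, solvent, force-field energetics, and the conformational
correlations of real trajectories. A green pipeline test therefore
establishes the protocol's bookkeeping and geometry, not biophysical
accuracy on real proteins.

## Degenerate inputs and numerical edges

* Kabsch superposition flips the smallest singular axis when the optimal
  orthogonal matrix is improper (chirality guard); rank < 2 point sets are
  flagged degenerate and fitted by translation only.
* Altloc policy on PDB read: keep the highest-occupancy alternate, ties by
  label order — a deterministic single-conformer topology.
* Multi-model files with inconsistent atom counts are rejected, never
  truncated.
* Collinear Cα chains give an ANM with more than six soft modes; the
  connected-network check names component sizes when the cutoff is too
  small.
* An infeasible placement restraint yields an empty pose set with a
  warning, not an error, so pipelines can report zero retained poses.

## Known limitations

* Conformers are unrelaxed; at amplitudes ≫ 2 Å the backbone geometry is
  no longer protein-like.
* The rejection-sampling placement explores a ball, not the full
  restraint-satisfying manifold conditioned on shape complementarity; with
  few samples, narrow pockets can be missed (raise `n_samples`).
* Residue correspondence between structures is positional (chain +
  residue number + offset), not sequence-aligned; inputs must be numbered
  consistently (an integer offset parameter covers isoform renumbering).
* RMSD selections support both Cα-only and full backbone; published
  backbone RMSDs rarely state which was used, and the two differ slightly.
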