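---
title: "Methods: conformational and binding free-energy analysis of kinase MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational and binding free-energy analysis of kinase MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and scientific background

`mdconf` implements the trajectory-analysis layer used to characterise how a
kinase mutation shifts the balance between active and inactive conformations,
and how that shift reads out in inhibitor binding:

* **Salt-bridge stability.** In EGFR-family kinases the K745–E762 salt bridge
  (β3-strand lysine to αC-helix glutamate) is present only in the active
  conformation. A mutant whose bridge is stably maintained is locked
  active-like; frequent cleavage and reformation marks a conformationally
  dynamic kinase whose inactive state — and hence the allosteric pocket bound
  by inhibitors such as EAI-045 — remains accessible.
* **Backbone flexibility.** Per-residue RMSF of the Cα trace, with the
  P-loop (glycine-rich phosphate-binding loop) and αC-helix annotated,
  distinguishes mutants whose drug-binding pocket rigidifies.
* **αC-helix orientation.** The distribution of helix Cα RMSD against an
  inactive-state reference structure, after global Cα alignment, measures how
  far an ensemble sits from the conformation competent to bind an allosteric
  inhibitor.
* **Binding free energies.** Per-λ-window forward/reverse work samples from a
  double-annihilation alchemical cycle are aggregated with the Bennett
  acceptance ratio (BAR), chained over windows, closed over the
  complex/solvent cycle, and decomposed into Coulomb and van der Waals
  components with replica-spread uncertainties.

Running molecular dynamics itself is out of scope: the package consumes
trajectories (multi-model PDB) and work tables (delimited text), and ships a
synthetic-data generator whose outputs have closed-form ground truth so every
analysis operation can be validated end to end.

# Data model and conventions

Coordinates are Ångström, times picoseconds, residue numbers author
numbering (the kinase-domain numbering such as K745/E762 is used verbatim and
never renumbered), energies kcal/mol. A `StructureModel` holds atom
identities plus an *n* × 3 coordinate matrix; a `Trajectory` holds a
topology plus an *n*~frames~ × *n*~atoms~ × 3 array with a fixed frame
interval, frame *k* sitting at *t* = (*k*−1)·Δ*t*. Frame/topology consistency
is enforced at construction (class validity), never re-checked downstream.

The trajectory interchange dialect is multi-model PDB: self-contained,
text-diffable, and testable byte for byte. Binary trajectory formats are
deliberately not parsed here; converting to multi-model PDB is the supported
adapter route. Only the first MODEL of a reference file is read and altloc
codes other than blank/'A' are dropped, so a real PDB entry can stand in as a
reference; insertion codes are rejected rather than silently renumbered.
Coordinates assume unwrapped (non-periodic) frames; the synthetic generator
produces unwrapped coordinates by construction, and no minimum-image handling
is attempted.

# Superposition, mean structures, RMSF

Rigid-body superposition is the unweighted Kabsch least-squares fit via SVD
of the 3 × 3 cross-covariance, with the reflection branch corrected through
the sign of the smallest singular value, so the rotation is always proper.
Collinear point sets leave the rotation about the common axis undetermined;
the fit is still returned, flagged ill-conditioned. "Backbone Cα" alignment
is taken literally as Cα only — one atom per residue, no mass weighting —
which keeps the alignment set and the RMSF measurement set identical in
spirit and avoids ambiguity about which backbone atoms participate.

The mean structure is computed iteratively: the reference starts as the
first pooled frame; each iteration aligns every frame (all replicas pooled
with equal weight) to the current reference on the alignment selection and
averages the coordinates; iteration stops when successive means differ by
less than 10⁻⁶ Å RMSD (far below thermal noise; typically 3–5 iterations) or
at 100 iterations, in which case the result is returned with
`converged = FALSE` rather than erroring. The arithmetic mean structure can
be stereochemically unphysical; it serves only as the alignment and
fluctuation reference.

RMSF of atom *i* is √⟨|r_i(t) − ⟨r_i⟩|²⟩ over all pooled aligned frames.
Pooling replicas is identical to concatenating their frames (tested as an
invariant). The default aligns on all Cα including flexible loops — the
choice is recorded in the output headers — and `alignOn = NULL` disables
alignment entirely, which is the configuration in which the
Ornstein–Uhlenbeck closed form (below) holds exactly.

Per-frame RMSD against a reference structure aligns each frame on one
selection and measures on another without re-fitting, matching atoms between
topology and reference by (residue number, atom name) and failing loudly
with the list of missing residues.

# Salt-bridge statistics

The monitored distance is exactly the donor side-chain terminal nitrogen
(Lys Nz) to acceptor carboxyl carbon (Glu Cδ) — not the more common N–O
convention — because that is the atom pair conventionally plotted for this
bridge. Defaults mirror the standard protocol numbers: samples every 100 ps,
smoothing by a 10 ns centered window average (truncated at the edges, output
times equal input times), statistics on *t* ≥ 100 ns with the first 100 ns
discarded as equilibration.

The formed fraction is the fraction of raw frames below the formed
threshold, default 4.5 Å on the Nz–Cδ distance — the conventional
salt-bridge cutoff, configurable; no published threshold exists for this
exact atom pair, so headline tests rely on generator ground truth rather
than the default's absolute value. Cleavage events are counted on the
smoothed series as excursions at or above the threshold lasting at least
`minEventNs` (default 10 ns, one smoothing window, suppressing single-frame
recrossings), within the same analysis window as the occupancy statistics.
A run that is already above threshold when the window opens is state, not an
event: events are formed→cleaved transitions. Replicas are labelled
"active-stabilized" when their formed fraction reaches `stableFraction`
(default 0.9) and "dynamic" otherwise; the ensemble label is the replica
majority with ties going to "dynamic". The stable/dynamic thresholds are
declared conventions — the phenomenon they quantify is described
qualitatively in the literature — and they are echoed in every output file.

# Helix-orientation distributions

For each frame the structure is aligned to the inactive-state reference on
all shared Cα atoms and the RMSD is then measured over the helix Cα atoms
(residues 752–767 by default, a 16-residue span) without re-fitting.
Whether the helix itself should be part of the alignment set is genuinely
ambiguous; the default includes it (the literal reading of "aligned on
backbone Cα"), and `excludeHelixFromAlignment = TRUE` provides the stricter
orientation-sensitive variant. Neither is asserted to be *the* published
choice. Histograms use fixed 0.25 Å bins from zero and are
density-normalised; the overlap coefficient between two distributions
(∑ min(d₁, d₂)·Δ, after rebinning to the coarser bin width) summarises
separation: 1 for identical ensembles, 0 for disjoint ones.

# Free-energy aggregation

Each λ window is estimated with the Bennett acceptance ratio in its general
unequal-sample-count form: the self-consistency equation is solved by damped
Newton iteration with a bisection fallback on a bracketing interval (the
residual is monotone in ΔG, so the solve is globally convergent; tolerance
10⁻¹⁰ kcal/mol). The standard error is Bennett's asymptotic variance over
the combined samples; windows whose work distributions barely overlap are
flagged, never silently accepted. Windows must tile [0, 1] contiguously and
are summed per leg with independent-variance error propagation.

The binding free energy follows the double-annihilation convention:
ΔG_bind = ΔG_annihilate(solvent) − ΔG_annihilate(complex), per component,
with the electrostatic (Coulomb) leg decoupled first and van der Waals
second — the decomposition order is a declared convention of the protocol
lineage this follows. The replica layout mirrors the standard protocol of
five complex production runs against three solvated-ligand runs: with equal
replica indices the cycle closes replica by replica; with unequal protocols
each complex replica is combined with the replica mean of the solvent legs.
The headline uncertainty is the SD across replica means — the spread across
independent production runs, which is what error bars on ΔG plots of this
kind usually show — while the BAR-propagated asymptotic se is reported
separately, since the two can differ and the published convention is not
stated. λ schedules are input data, never hard-coded. Mutant comparison
reports ΔΔG against a chosen reference, attributes it to whichever component
carries ≥ 50 % of its magnitude, and applies an unpaired two-sample *t*-test
on replica means (unpaired, because replica indices of different mutants
share nothing).

# The synthetic-data generator

The generator emulates the *statistical* structure of the real study
conditions — never the physics:

* **Scaffold.** A self-avoiding random walk with 3.8 Å consecutive Cα
  spacing (the trans-peptide virtual bond length) and a 3.5 Å clash cutoff,
  with residues numbered from 718 (or 700 for the 100-residue default) so
  the familiar numbering (P-loop 718–726, K745, E762, helix 752–767) applies
  verbatim. The Glu Cδ atom is offset 2.5 Å from its Cα; the Lys Nz sits at
  3.0 Å bonded geometry from Cδ.
* **Fluctuations.** Per-atom, per-coordinate Ornstein–Uhlenbeck processes
  about the scaffold with region-dependent stationary SD *s* (defaults:
  core 0.4 Å, P-loop 1.0 Å, helix 0.5 Å; relaxation time 100 ps). The exact
  discretisation x ← x·e^(−Δt/τ) + √(1−e^(−2Δt/τ))·s·ξ is used rather than
  an Euler step so the stationary variance — and therefore the RMSF ground
  truth √3·s — is exact at any frame interval, which is what makes 5 %
  recovery tolerances meaningful.
* **Salt bridge.** A two-state continuous-time telegraph process (cleave and
  reform rates in events/ns) selects a bonded (3.0 Å) or cleaved (8.0 Å)
  mean distance, plus 0.3 Å Gaussian observation noise; the distance is
  imposed kinematically by placing Nz radially from Cδ. Stationary occupancy
  k_reform/(k_cleave + k_reform), correlation time 1/(k_cleave + k_reform)
  and raw cleavage-transition rate π_bonded·k_cleave are the closed-form
  ground truth. Because the pipeline only ever observes distances, dynamical
  realism of the imposition is out of scope by design.
* **Helix pose.** The helix block switches between an active-like pose (a
  rotation about the z axis through its centroid) and the inactive pose
  (the scaffold itself, which doubles as the inactive reference structure)
  by its own telegraph process.
* **Work samples.** Forward work ~ N(ΔG + βσ²/2, σ²) and reverse work ~
  N(−ΔG + βσ²/2, σ²) satisfy the Crooks fluctuation relation exactly, so
  BAR is a consistent estimator of the built-in ΔG; per-replica leg offsets
  model run-to-run spread.

Three presets encode the qualitative study conditions. "WT-like" and
"L858R-like" break and reform the bridge (symmetric ~0.01/ns rates, formed
fraction 0.5), mix helix poses and have a flexible P-loop (1.0 and 0.9 Å).
"L747P-like" never cleaves (rate 0, started bonded), locks the helix in a
pose far from the inactive reference (45° vs the 20–22° active poses of the
dynamic presets, so the two ensembles are also separated from each other)
and halves the P-loop amplitude. All preset numbers are documented synthetic
choices living in one place; tests assert orderings and closed-form
recoveries, never the constants themselves.

What the generator does **not** emulate: real force-field energetics,
solvent, anharmonic or correlated collective motions, periodic boundary
artefacts, or genuine kinase geometry beyond labelled residue numbers.
Passing tests therefore demonstrate that the *estimators* are correct and
well-calibrated on data whose truth is known — not that any particular
biological conclusion would be reproduced from real trajectories.

# Statistical tolerances used in the tests

Occupancy-type estimates from a telegraph process observed for time *T* with
correlation time τ have standard error √(p(1−p)·2τ/T); tests assert
agreement within 3 SE. Event counts are compared against the 95 % band of a
Poisson law with the dwell-thinned rate π_b·k_c·T·e^(−k_reform·d_min), since
cleaved dwells are exponential and excursions shorter than the dwell filter
d_min are dropped. BAR recovery is judged against its own asymptotic se
(which the suite also verifies matches the spread across seeds). The
superposition oracle is a Nelder-Mead/BFGS minimisation over
quaternion-parameterised rotations with random restarts, agreeing with the
SVD solution to better than 10⁻⁶ Å; a 10,000-rotation Monte-Carlo sweep
checks optimality directly.

# Problem sizes

The validation suite uses: 10,000-frame trajectories (1 μs at the 100 ps
interval — the full production length) for single-run closed-form
recoveries; 50-residue scaffolds (chain 718–767, covering every annotated
region) for fluctuation work and 30-residue scaffolds for the
salt-bridge-only classification study; 50 seeded repetitions for ordering
properties and 100 for classification accuracy, with repetition runs at
1,000–2,000 frames where the tested ordering is scale-free. The shipped
demo runs three replicas × three presets at 2,000 frames (200 ns) on a
60-residue scaffold and completes in about a minute on one CPU. These sizes
are the package's own validation choices; the statistical tolerances above
scale with them explicitly.

# Known limitations

* Multi-model PDB is verbose; microsecond trajectories at full atom count
  are better converted in chunks or down-sampled before analysis.
* The window smoother assumes (but does not require) uniform sampling; the
  event counter uses the sampling interval of the analysis window, so
  non-uniform series should be resampled first.
* BAR is implemented per window-pair only; multi-state estimators (MBAR) are
  out of scope, as window-chained BAR is sufficient for the tiled schedules
  this protocol uses.
* The mean structure is an alignment reference, not a physical conformation;
  do not interpret its stereochemistry.
* Classification labels at short trajectory lengths (≲ 200 ns) are noisy by
  nature — the formed-fraction estimator's SE at τ = 50 ns is ~0.17 even at
  900 ns of data — which is why label-accuracy claims are made only at the
  full problem size.
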