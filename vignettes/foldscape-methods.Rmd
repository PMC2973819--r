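---
title: "Methods: mapping the fold space of short polypeptide chains"
author: "foldscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping the fold space of short polypeptide chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(foldscape)
```

## The question and the pipeline

How many distinct compact folds can a ~60-residue polypeptide chain adopt,
and how do the folds observed in nature relate to that larger set of
physically possible ones?  `foldscape` implements the analysis side of that
question as a reusable pipeline.  Given an ensemble of conformations (a
simulated trajectory read from a multi-model PDB file, or a synthetic
ensemble generated in-package), it:

1. filters frames down to protein-like conformations (secondary content,
   compactness, time decorrelation);
2. quantifies pairwise structural similarity by TM-score;
3. groups the ensemble into *independent structures* -- representatives that
   are pairwise dissimilar at the same-fold threshold;
4. extrapolates the discovery curve of independent structures to estimate
   the total size of the accessible fold space;
5. measures re-discovery statistics and the coverage of a target fold set
   by a conformational library;
6. compares contact-based descriptor distributions (contact order, contact
   locality) between structure sets.

The molecular-dynamics machinery that would produce a real trajectory is
out of scope; the synthetic generators below stand in for it with known
ground truth.

## Structural similarity: TM-score

For an alignment pairing residues of chain A with residues of chain B, the
score of a rigid superposition is

TM = (1 / L_target) * sum_i 1 / (1 + (d_i / d0)^2),

where d_i are the CA-CA distances of aligned pairs, L_target is the length
of the target (normalising) chain -- the shorter chain by default, or the
query in library searches -- and d0 = max(1.24 (L_target - 15)^(1/3) - 1.8,
0.5) Angstrom.  Identical structures score 1; unrelated compact structures
score around 0.25; pairs above 0.45 (`TM_FOLD_THRESHOLD`) are treated as
the same fold throughout.

The alignment search is a simplified TM-align-style procedure.  Initial
candidates come from three families: gapless threading at all sequence
offsets; dynamic programming on the two secondary-structure strings; and
the best 8-residue fragment superposition extended by distance dynamic
programming.  The most promising candidates are refined by iterating
{superpose on the current pairs, rebuild the TM-weighted score matrix
1/(1+(d_ij/d0)^2), realign by semi-global dynamic programming with gap
penalty -0.6 (opening = extension)} to convergence.  The TM-score of a
fixed alignment is itself maximised over superpositions by iterated Kabsch
fits on distance-trimmed subsets of the aligned pairs, as in the original
TM-score program.  Alignments are strictly sequence-order preserving, with
no circular permutations.

Relative to the full TM-align rotation-search schedule, this search is
deliberately lighter; its accepted risk is slightly lower scores on hard
(remote-similarity) cases.  The analyses here only require reliable
discrimination around the 0.45 same-fold and 0.25 random regimes, which
the tests check directly: self-alignments score 1 to 1e-6, 1-Angstrom
noisy copies score above 0.7, and independent compact chains average near
the random baseline.

Two performance-relevant conventions are worth stating.  For equal-length
chains the TM-score of a *fixed* alignment is identical under either
normalisation, so all-vs-all matrices run a single alignment search per
pair.  And when only the thresholded neighbour graph is needed (clustering,
discovery curves, re-discovery counts), the search uses two bounded-effort
exits: it stops as soon as a refined candidate crosses the threshold (any
valid alignment's score is a lower bound on the search maximum, so the
decision is exact), and it abandons a pair whose first refined candidate
stays more than a 0.08 safety margin below the threshold.  The margin was
validated against the full search on thousands of mixed same-fold and
different-fold pairs with no decision flips; reported TM-scores (from
`align`, `best_hit`, `coverage_analysis`) never use these exits.

## Secondary structure

Assignment re-implements the hydrogen-bond electrostatic criterion:
backbone amide hydrogens are rebuilt geometrically (1.0 Angstrom from N,
anti-bisecting C(prev)-N-CA), the bond energy is
E = 0.084 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 kcal/mol, and a bond
exists when E < -0.5 kcal/mol.  Helix comes from consecutive i+4 -> i turn
bonds (runs of at least 4), strand from ladders of bonded bridges (runs of
at least 2, parallel or antiparallel sense recorded), all else coil.  The
rarer 8-state classes (3-10 and pi helices, isolated bridges, turns,
bends) are collapsed to coil on purpose: only H/E content and coarse class
labels feed the analysis, and collapsing avoids any binary dependency on
an external assignment program.

Structural classes split at helix/strand fractions of 0.25 (dominant) and
0.05 (absent), with mixed alpha/beta requiring both above 5% and total
secondary content of at least 30%.  These split points are package
conventions -- reasonable, but not canonical, so they are parameters of the
reported tables rather than buried constants.

The collective-variable counts (`cv_count`) score how many 6-residue
windows (helix) or 3+3-residue fragment pairs (sheets) superpose onto an
ideal secondary-structure block within a 1.0 Angstrom backbone RMSD
cutoff, as hard counts.  The ideal two-strand blocks were frozen once by
maximising the number of backbone hydrogen bonds between two ideal
3-residue strands over their relative placement (azimuth and offsets); the
resulting geometry (inter-axis spacing 5.2-5.3 Angstrom) matches textbook
sheet dimensions.  Differentiable switching functions, which a biased
simulation would need for forces, are out of scope.

## Contact descriptors

Residues are in contact when any two heavy atoms lie closer than 3.5
Angstrom.  Contact order is the mean sequence separation of contacting
pairs divided by the chain length; contact locality is the fraction of
contacts with both residues in the same half of the chain, with the split
counts N_N + N_C + N_NC = N conserved by construction.  Two conventions
are exposed as arguments because the definitions leave them open: the
minimum sequence separation (default 2, excluding peptide-bonded
neighbours, which are always in contact and carry no topology signal) and
the half assignment for odd lengths (the N-terminal half takes the extra
residue).  The radius of gyration is computed over heavy atoms,
unweighted.

## Synthetic structures with known ground truth

All generators grow backbones in internal coordinates (bond lengths N-CA
1.458, CA-C 1.525, C-N 1.329 Angstrom; angles near 111 degrees; omega
fixed trans) and are pure functions of their arguments including the seed.
Side chains are a single ideally placed CB, so the chains are effectively
a polyvaline reduced representation.

**Elements and folds.**  `build_sse` grows ideal helices (phi, psi =
-57, -47) and strands (-139, 135).  `build_fold` places elements rigidly
on a user-specified axis grid (direction alternating to shorten
junctions; per-element azimuth, and for strands a small axial shift,
chosen to maximise inter-element hydrogen bonds while avoiding clashes)
and connects them with glycine loops.  Loops are grown with real peptide
geometry by turn-and-coil-basin dihedral sampling steered along a
randomised arc, then closed by cyclic coordinate descent on the loop
torsions; candidates clash-checked against the whole assembly (non-bonded
heavy atoms at least 2.5 Angstrom apart) are redrawn up to 200 times per
junction before the builder reports the junction as unresolvable.  The
`topology_sheet`/`topology_bundle` helpers build sequence-local
("sequential") and interleaved ("crossover") versions of the same
placements; the crossover versions have systematically higher contact
order (about 0.44 versus 0.17 for four-strand sheets), which gives the
descriptor-comparison stage a designed, known-direction contrast.

**Random compact chains.**  `random_compact_chain` draws runs of helix,
strand and coil dihedrals (35/20/45 state weights, run lengths 5-9 and
3-6), then anneals with greedy pivot moves -- restricted to coil positions
until progress stalls, so the drawn elements survive the collapse -- until
the chain is self-avoiding and its radius of gyration is within 10% of the
11 Angstrom target typical of compact 60-mers.  The resulting ensemble has
roughly one-third secondary content and no same-fold pairs across seeds,
which is what the random-pair TM baseline requires.

**Trajectories.**  `simulate_trajectory` emulates an exploration that
revisits a finite pool of folds: frame i copies a pool member drawn
i.i.d. from the visit weights and perturbs every coordinate with Gaussian
noise of total RMSD `noise_rmsd` (no re-superposition, so the noise
includes slight global drift), at timestamps i * dt_ps.  The defaults --
uniform weights, 1.0 Angstrom noise, 60 ps frame spacing -- keep perturbed
frames unambiguously same-fold with their source (TM well above 0.45)
while remaining visibly noisy; the generator refuses noise so large that
more than 5% of frames lose self-identity.  A production simulation of
this kind would yield tens of thousands of frames; the study conditions
used in the tests (pools of 5-20 folds, trajectories of 30-500 frames)
were chosen to exercise every code path at desk scale.  What passing these
tests shows is that the pipeline's counting, clustering and extrapolation
machinery is correct on data whose ground truth is known; it does not
certify behaviour on real trajectories, whose frames are correlated in
time and deform continuously rather than jumping between folds.

## Clustering and extrapolation

`greedy_cluster` implements offline maximum-neighbour clustering:
repeatedly take the member with the most remaining neighbours (TM above
the threshold), declare it an independent-structure representative, remove
it with its neighbours.  `discovery_curve` is the online variant: a frame
is new if it is below threshold to every previously retained
representative, and the first-seen exemplar of each fold is kept.  The
two differ in general; both are provided because both notions of
"independent structures found so far" are useful, and both recover the
exact pool size on simulated trajectories with 1 Angstrom noise.  All ties
break to the earliest index for determinism.

`fit_discovery` fits N_ind(n) = A (1 - exp(-n/tau1)) + B (1 - exp(-n/tau2))
by Levenberg-Marquardt least squares on the raw curve, with a 4x4
multi-start grid of (tau1, tau2) pairs spanning three decades up to the
curve length, exact linear least-squares solutions in (A, B) at each grid
point as additional candidates (these also cover degenerate flat curves),
and box bounds on all parameters (positive; tau at most 50 times the
observed curve length, since extrapolating time scales far beyond the data
is meaningless); the reported
asymptote A + B estimates the number of independent structures an
infinitely long exploration would reach.  A constant curve is handled by
the small-tau degenerate limit.  On coupon-collector curves from a
200-fold pool sampled 3000 times, the asymptote lands within 15% of the
truth; exact recovery is not expected because a uniform coupon collector
is single-exponential and the fitted family is richer.

## Numerical choices and degenerate inputs

* Kabsch superpositions enforce proper rotations (determinant +1);
  reflection-related point sets therefore keep a positive RMSD.  Collinear
  point sets are rejected.
* d0 is clamped below at 0.5 Angstrom so short targets do not get a
  negative or vanishing scale.
* Empty alignments score TM = 0 with undefined RMSD, by convention.
* Contact order and locality are undefined (hard error) on contact-free
  maps; the tabulated descriptor interface reports NA instead so that
  set-level summaries survive sparse members.
* PDB round trips are exact to the 1e-3 Angstrom column precision of the
  format; alternate locations keep the highest-occupancy copy (first on
  ties), hydrogens are dropped on read, and residues are renumbered
  contiguously with the original numbering kept as metadata, because every
  descriptor here is defined on sequence separation and must ignore
  numbering gaps.
* The frame filter applies strict inequalities (content > 0.30, Rg < 15
  Angstrom, spacing > 50 ps) and keeps the first frame of each
  well-separated stretch (greedy scan in time order), which makes it
  idempotent.

## Known limitations

* The alignment search is a reconstruction of the TM-align family, not a
  port; on remote similarities it can score a few hundredths lower than
  the reference implementation.
* The secondary-structure assignment collapses the rarer states to coil;
  helix content of heavily distorted helices is underestimated relative to
  a full 8-state assignment.
* The fold builder's loop closure is stochastic; topologies whose
  junctions thread narrow corridors can fail after the bounded retries,
  and such specs should use longer loops or wider placements.
* The synthetic trajectory jumps between folds i.i.d.; it has no kinetics,
  so time-correlation aspects of real trajectories are untested.
* Single chains only; no multi-chain complexes, no mmCIF.
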