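---
title: "Knowledge-based scoring of SSE-only protein models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based scoring of SSE-only protein models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ssescore` scores protein models that consist only of idealized secondary
structure elements (SSEs): alpha-helices and beta-strands, with loops and
side chains left implicit. Each residue is represented by a single
side-chain anchor point — the C-beta atom, or the H-alpha2 position for
glycine — and each SSE by a set of overlapping oriented fragments
(5 residues for helices, 3 for strands) whose main axes are obtained by
least-squares superposition of an ideal template onto the fragment's
CA coordinates.

The total energy is a weighted sum of twelve terms. Eight are statistical
potentials obtained from a training database via the inverse Boltzmann
relation

$$E(f) = -RT \,\ln\frac{p(f)}{p_{bg}(f)},$$

with $RT$ arbitrarily set to one BCL energy unit (BCLEU), so that features
more common than their background expectation score negative. Three are
penalty terms for geometries that a statistical potential cannot calibrate
because they never occur in native structures (amino acid clashes, SSE
clashes, unclosable loops), and one scores the agreement between the
model's per-residue secondary structure and an external 3-state prediction
(PSIPRED/JUFO style).

### The statistical terms and their backgrounds

| term | feature | background |
|---|---|---|
| amino acid environment | smoothed neighbour count per SSE residue | normalized sum of all per-type count distributions |
| amino acid pair distance | anchor–anchor distance, sequence separation ≥ 12, 1 Å bins 0–20 Å | frequency of either partner type with any type at that distance |
| loop length | (loop residue count, Euclidean tip distance) per consecutive SSE pair | proportional to the squared Euclidean distance |
| strand pairing | (distance, twist) of best fragment pairs, edge-weighted | proportional to distance |
| SSE packing (HH, HS, sandwich) | (distance, twist) of best fragment pairs | proportional to distance |
| contact order | CO²/N | uniform |
| radius of gyration | r²/N | uniform |

The neighbour count replaces a hard cutoff with a half-cosine step-down
transition from weight 1 at 4.0 Å to 0 at 11.4 Å (sequence separation of at
least three residues), keeping the term continuously differentiable. The
same half-cosine family is used for the packing contact weight (angles
between the shortest axis connection and the two axes, full contact when
orthogonal) and for the offset-angle weights.

### Packing geometry

Fragment main axes are treated as line segments trimmed by 2 Å at each end
(minimal 4 Å interface). A fragment pair is described by the analytically
shortest connection between the trimmed segments, the twist angle theta
(the dihedral main axis 1 – connection – main axis 2; right-handed looking
along the connection; 0 for parallel same-direction fragments, ±180 for
antiparallel), and offset angles omega measured on strand fragments between
the connection and the strand's pleat ("face") vector, folded into
[0°, 90°]. Per SSE pair, each fragment of the SSE with fewer fragments is
matched with the partner fragment maximizing the interaction weight
$w_I$; ties on fragment count resolve to the SSE earlier in sequence.
Strand–strand contacts are apportioned between a backbone-pairing table
(omegas near 90°) and a sheet-sandwich table (omegas near 0°) using
complementary half-cosine weights, so one geometric contact feeds both
regimes smoothly.

## Numerical choices

* **Interpolation.** Energies are linearly (1D) or bilinearly (2D)
  interpolated between bin centers; the twist-angle axis is periodic.
  Beyond the support, tables either clamp to the edge value or ramp the
  energy linearly to zero at the outermost break (used for the
  pair-distance 20 Å cutoff and the packing distance support, so scores
  stay continuous everywhere).
* **Under-populated bins.** Environment bins with at most one raw count
  and pair-distance bins with fewer than five raw counts receive a
  constant repulsive 18 BCLEU. For the 2D packing/pairing tables the
  repulsive constant is **not** used: empty 2D bins are scored 0. At the
  fixture scale of this package a +18 empty bin bleeds into adjacent
  occupied bins through the bilinear interpolation the continuity
  requirement demands, making even native packing geometry score
  positive; and the scoring function's own design principle is that
  geometry absent from native structures is penalized by the dedicated
  clash terms, not by pseudo-counted statistics.
* **Loop table regularization.** The loop-length table adds a pseudo count
  of 0.01 per bin before conversion. Together with the $d^2$ background
  this makes unobserved long spans score increasingly positive (about
  $2\ln d$) while leaving observed bins dominated by real counts.
* **Loop closure.** The maximal bridgeable span is
  $d_{max}(n) = 2.8\,\text{Å}\cdot n + 4.0\,\text{Å}$ per loop of $n$
  residues, chosen once to reproduce the observation that about 32 Å can
  be bridged by 10 residues; `fit_loop_closure()` re-derives slope and
  intercept from data via the 95th-percentile regression. The penalty
  beyond $d_{max}$ is quadratic in the excess (configurable exponent).
* **Clash parameters.** The SSE minimal fragment distances are 4 Å
  (helix–helix and helix–strand) and 3 Å (strand–strand) with a 1 Å ramp
  to full penalty. The default amino acid minimal-distance matrix is a
  uniform 3.0 Å; `derive_aa_min_distance()` implements the 0.05 Å-binned
  "first bin with more than one count" rule to train a full matrix.
* **Penalty amplitude.** Each violating pair contributes at most 1; the
  consensus weights (500 for the three penalties) carry the magnitude.
* **SS agreement sign.** The per-residue contribution is
  $-\mathrm{erf}(z/\sqrt{2})$ with $z = (p - \mu)/\sigma$: negative
  (favourable) when the predictor assigns the modelled state a higher
  probability than its calibrated mean.

## The synthetic world

Everything is testable without external data through a fixture generator:

* **Ideal SSEs** are built from repeated backbone dihedrals (helix
  phi/psi = −60/−45, ~1.5 Å rise per residue; strand −120/135, ~3.4 Å
  rise) with standard covalent geometry; anchors are ideal C-beta
  positions. The main axis is recovered from the screw transform between
  consecutive windows, so fragment superposition onto an unperturbed
  template reproduces the construction axis to machine precision.
* **Five toy topologies** (helix pair, three-helix bundle, antiparallel
  three-strand sheet, helix-on-sheet, beta-sandwich) emulate native
  packing: 4.75 Å strand spacing with a 15° inter-strand twist (twist
  angles near ±165° for antiparallel pairing), helix packing near 10.5 Å,
  sheet stacking near 10 Å with a −30° crossing. SSE lengths differ within
  each topology so that swapping two SSEs is never a geometric identity.
  Loop lengths are chosen with a 4 Å slack below the loop-closure limit so
  natives (and near-native decoys) satisfy every penalty term exactly.
* **Sequences** are drawn from a reduced alphabet of eight frequent
  residue types (ALA, GLY, LEU, VAL, PHE, SER, GLU, LYS at natural
  relative frequencies). This is a deliberate property of the synthetic
  world: a 50-protein fixture database cannot populate 210 amino acid pair
  tables over a 20-letter alphabet, and with the under-population rule
  almost every pair would score the repulsive constant, rewarding decoys
  for simply having fewer residues. With eight types the pair and
  environment statistics are populated at fixture scale. Real training
  databases provide the full diversity; nothing in the scoring code is
  restricted to the reduced alphabet.
* **Decoys** follow the four benchmark moves — rigid rotation/translation
  of one SSE, SSE flip, swap of two SSEs, SSE removal. Heavy decoys chain
  2–4 moves (rotation up to 60°, translation up to 8 Å); near-natives use
  one gentle rigid move (≤ 8°, ≤ 1 Å). A decoy counts as native-like when
  its RMSD100 (plain CA RMSD normalized as $rmsd/(1+\ln\sqrt{n/100})$) is
  below 8 Å **and** it retains at least 90% of the native's residues; the
  coverage condition exists because a removal decoy has near-zero RMSD
  over its surviving residues while missing a whole SSE.
* **Synthetic predictions** draw the assigned state's probability from a
  clipped normal with the calibrated per-method mean and standard
  deviation at a configurable accuracy (default 0.8).

What a green benchmark establishes — and what it does not: the toy decoy
experiment shows that the trained consensus function ranks near-native
arrangements of these idealized topologies ahead of perturbed ones. It
does not exercise sequence-structure compatibility at native scale, bent
or kinked SSEs, loop conformations, or the full amino acid alphabet, and
the table contents differ from potentials trained on a real structure
database.

## Consensus, enrichment and weight fitting

The consensus score is the weighted sum of the twelve terms; defaults are
the published set (amino acid distance 0.35, neighbour count 50, loop
length 10, radius of gyration 5, loop closure 500, amino acid clash 500,
SSE clash 500, SSE packing 8, strand pairing 20, contact order 0.5,
JUFO agreement 5, PSIPRED agreement 20). Enrichment is the fraction of
native-like models within the best-scored 10%, divided by the base rate,
capped at 10; significance uses ten balanced 1:9 subsets (over-represented
class partitioned without reuse, under-represented class re-drawn) and the
Z-score $(\bar e - 1)/sd$.

Weight optimization maximizes the sum over model sets of the square root
of the enrichment by Metropolis simulated annealing: start weights are the
inverse standard deviation of each term (zero-variance terms start at 0),
each move adds or subtracts 10% of the *starting* weight to two randomly
chosen weights (floored at 0), with at most 10,000 iterations and
termination after 250 steps without improvement. The annealing schedule is
not prescribed by the protocol; we use a geometric decay (0.999 per step)
from a start temperature calibrated so that roughly half of early
worsening moves would be accepted, both configurable. On the discrete
desk-scale objective the 250-step patience occasionally stops one
enrichment notch below the optimum; the acceptance suite therefore allows
a 2% band around the known maximum.

## Known limitations

* Each SSE is one rigid body with per-window fragments; bent or kinked
  SSEs are not split into multiple ideal segments.
* The strand-strand omega regime split and the offset weights use
  half-cosine ramps; only their endpoint behaviour is pinned down by the
  construction, the functional family is a modelling choice.
* mmCIF, insertion codes, altLoc B conformers, hetero-atoms and NMR
  multi-model files are out of scope of the PDB reader.
* Fixture-trained tables are deterministic but fixture-scale; they are not
  a substitute for potentials derived from a curated structure database.
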