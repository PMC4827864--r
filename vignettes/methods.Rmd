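---
title: "Shuffle-null homology scores and superfamily inference for outer-membrane beta-barrels"
author: "ompbarrel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shuffle-null homology scores and superfamily inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Outer-membrane pore-forming proteins (OMPPs) — the mostly beta-barrel
channels of Gram-negative bacterial, mitochondrial and chloroplast outer
membranes — diverge so far that standard database searches cannot decide
whether two families share common ancestry. Two features of these
proteins defeat the usual tools: their residue composition is strongly
biased (alternating hydrophobic/polar transmembrane strands), which
inflates raw alignment scores between non-homologues, and genuine
homologues routinely sit below 20% identity, where alignment-based trees
and profile searches lose their footing.

`ompbarrel` implements the statistical machinery used to attack this
problem: a Monte-Carlo shuffle-null "comparison score" for pairwise
global alignments, transitive homology chains, alignment-free score
trees, hydropathy-profile topology analysis, an intra-protein hairpin
repeat scan, and a synthetic beta-barrel family generator that provides
ground truth for validating every stage.

## The comparison score

For sequences $a$ and $b$, the comparison score is

$$ z = \frac{S(a,b) - \mu_0}{\sigma_0}, $$

where $S$ is the optimal Needleman–Wunsch global alignment score (affine
gaps: a gap of length $g$ costs $\mathrm{open} + (g-1)\cdot\mathrm{ext}$,
defaults 8 and 2, BLOSUM62) and $\mu_0, \sigma_0$ are the mean and sample
standard deviation of $S(a^\*, b^\*)$ over $n$ independent
residue-shuffled copies $a^\*, b^\*$ (default $n = 2000$). Because every
null replicate preserves both residue compositions exactly, $z$ is
calibrated even for compositionally extreme membrane proteins — the
package's null-calibration benchmark shows mean $z \approx 0$ for
unrelated 200-mers drawn with 70% of residues from {I,L,V,F}, while the
raw score between such sequences is wildly inflated.

Evidence rule: homology is considered established when $z \ge 12$ SD over
a *comparable segment* of at least 60 residues in each protein (the size
of a prototypical domain). Comparable segments are obtained by trimming
alignment columns from the two ends only — maximizing identities minus
gapped columns, never removing central regions — so every scored segment
is a contiguous substring of each protein
(`extractComparableSegment()`). Chain links use a strict $z > 12$; a
direct comparison that reaches $z \ge 12$ on its own makes bridges
unnecessary. Both readings are implemented exactly as stated by the
evidence protocol this package follows.

Numerical notes: the null uses the $n-1$ sample SD; shuffles are
Fisher–Yates permutations of both sequences (shuffling only one is an
option); a zero null SD (e.g. homopolymers) yields a flagged degenerate
result rather than an error; all traceback tie-breaks are deterministic
(match state over gap-in-second over gap-in-first), so identical inputs
and seeds give identical output.

## Transitive chains and superfamilies

If A is homologous to B, and B to C, then A and C are homologous
regardless of their direct score (the superfamily principle).
`verifyChain()` scores an A–B–C–D chain: the direct A-vs-D test is run
once (callers that already performed it pass the result in), and if it
fails, the chain is accepted only when all three links clear the strict
rule. `screenFamilies()` automates bridge discovery: the top-ranked
cross-family pair from a rapid all-vs-all local-alignment screen
(`screenPairs()`, Smith–Waterman, same matrix and gaps) is confirmed
first; on failure, both query sets are expanded over the pooled database
by two-iteration E-value search (`expandFamily()`, cutoffs $10^{-4}$ then
$10^{-6}$, Karlin–Altschul statistics) and the top bridging pairs are
chain-verified. Bridge candidates are prefiltered at E $\le 10^{-6}$ —
the stringent second-iteration cutoff — and the middle (weakest) link is
tested first, with results cached across family pairs under
pair-identity-derived seeds so the screen's output is independent of
enumeration order.

`buildSuperfamilies()` takes the accepted evidence and returns the
connected components of the family graph, labelled SF1, SF2, ... by
decreasing size. Families without accepted evidence are reported as
"no evidence", never as non-members: inability to establish homology is
not evidence of its absence.

E-value parameters are tabulated for BLOSUM62 (ungapped
$\lambda = 0.3176, K = 0.134$; gapped $0.267 / 0.041$). The gapped entry
is the standard BLAST default-gap estimate and is used as an
approximation for the package's 8/2 gap costs; since E-values serve only
to rank and prefilter candidates ahead of the shuffle-null confirmation,
this approximation does not touch the evidence statistic itself. Unknown
matrices raise an error naming the supported choice.

## Alignment-free trees

`allVsAllScores()` computes all pairwise local-alignment scores and
expresses them in bits, $b = (\lambda S - \ln K)/\ln 2$ — no multiple
alignment is constructed. Distances are
$d(i,j) = 1 - b(i,j)/\min(b(i,i), b(j,j))$, clipped to $[0,1]$, with
non-positive raw scores saturating at 1. Trees are standard neighbor
joining (`ape::nj`), with negative branch lengths floored at zero after
transferring their magnitude to the sibling branch.

Consensus support comes from 100 replicate trees. The published
score-tree method does not document its replicate unit, so the unit is
pluggable here: the family-level tree (`familyTree()`, the headline
operation) resamples each family's members with replacement and rebuilds
the trimmed-mean (10%) cross-family distances; the protein-level tree
(`consensusTree()`) bootstraps distance-profile coordinates. Majority
rule (>50%) consensus is used, with supports as percent of replicates.
Family positions are only trustworthy when several members represent
each family — five or more; `familyTree()` warns below that.

`msaTree()` is the conventional control: MAFFT progressive alignment,
p-distances, NJ. On the high-divergence benchmark (within-family identity
~22%) it scatters planted families that the score-based trees keep
monophyletic — reproducing the behavioral contrast that motivates
alignment-free trees for diverse families, while at low divergence the
two routes agree.

## Topology profiles and the strand caller

`avehasProfile()` computes, per alignment column: mean windowed
Kyte–Doolittle hydropathy (window 9 by default), mean windowed
hydrophobic moment $\mu = |\sum_k h_k e^{i\delta k}|/W$ at periodicity
angle $\delta$ (180° for beta-strands; ~100° probes helices), and column
conservation (1 − normalized Shannon entropy). Windowed values are
computed on each row's ungapped sequence and mapped back to columns, so
gaps never dilute a window. On synthetic families the conservation peaks
co-locate with the planted strands, mirroring the correspondence between
hydropathy peaks and similarity peaks seen in real family profiles.

`predictBetaTms()` is a deliberately simple strand caller (HMM topology
predictors are out of scope): per-residue score = 180° moment + positive
part of windowed hydropathy (window 5); greedy selection of
non-overlapping windows of 6–14 residues whose mean clears a threshold,
followed by hysteresis extension while neighbouring residues stay above
0.3× the threshold. The threshold (1.3) and extension factor were
calibrated once on the generator's 50-barrel benchmark and are stored as
named constants. Single-protein beta-strand prediction is intrinsically
noisy (real-world predictors are only ~50% accurate per protein); the
intended use is the family-consensus call, `countTmsByFamily()`, which
reports the modal strand count over family members. Profile columns with
under 50% residue occupancy are masked when calling strands on
alignments.

## Hairpin repeats

Barrels are hypothesized to have grown by amplification of a two-strand
hairpin module. `enumerateHairpins()` derives candidate units from a
strand topology (disjoint pairing (1,2),(3,4),... by default, matching
the tandem-hairpin model; units span strand $k$ through strand $k+1$
including the turn). `hairpinRepeatScan()` compares every unit pair with
the shuffle statistic over local alignments (gap open reduced to 4 for
these short units) and reports $z$ plus an empirical P value
$(1 + \#\{S^\* \ge S\})/(n+1)$. Units are shorter than 60 residues, so
hits quantify repeat similarity but are never labelled established
homology. The empirical P is not comparable to HMM–HMM repeat-detector P
values; it is the package's own statistic.

## The synthetic generator

`makeAncestor()` draws a barrel as tails + $H$ hairpin modules
(strand–turn–strand–loop), $H \in 4..14$ giving 8–28 strands and protein
lengths within the 150–1400 aa range observed across real OMPP families.
Strand positions alternate membrane-facing/lumen-facing with imperfect
class fidelity (0.85/0.70): real strands are not perfectly amphipathic,
and a perfectly periodic generator would make even unrelated barrels
mutually alignable, corrupting the null. Loops/turns are polar with
occasional prolines. `amplifiedUnit` copies one hairpin $n$ times at a
stated expected *pairwise* divergence between copies (the convention
repeat tools report).

`evolveFamily()` evolves members independently from the ancestor:
substitutions from a BLOSUM62-derived proposal, class-conservative inside
planted strands (the membrane constraint) and at 0.6x the loop rate there
(purifying selection on the membrane-spanning core — this differential is
what makes conservation peaks coincide with strands, as in real family
profiles); geometric indels are confined to loops and tails so that
planted strand coordinates remain exact ground truth. An optional
whole-hairpin gain/loss mode (`hairpinTurnover`) deletes or duplicates
entire hairpin modules, emulating barrel growth and shrinkage by
two-strand units. Divergence is parameterized by target mean pairwise identity
(practitioners reason in percent identity, not branch lengths) and
calibrated internally by bisection; a realized identity more than ~5
points off the target errors out. `makeSuperfamily()` evolves family
ancestors along a guide tree whose edge lengths are per-site substitution
probabilities, then expands each tip. Same seed, byte-identical FASTA.

What the generator does *not* emulate: real barrels' 3-D constraints and
strand register, signal peptides, the passenger domains of
autotransporters, horizontal transfer, and database-scale family-size
skew. Green benchmarks therefore demonstrate that the statistical
machinery behaves as designed under its own model — calibrated nulls, no
false merges, correct transitive logic — not that real TCDB families
would be classified identically; the real-data regression (four TCDB
sequences) is provided as an optional network-dependent script in
`inst/scripts/tcdb_regression.R`.

## Benchmarks and problem sizes

The standard benchmarks (also run by `scripts/acceptance.R`) use: 1000
biased 200-mer pairs at 200 shuffles for null calibration (the score is
stable well under 0.1 SD at that depth; the evidence-grade default stays
2000); 20 seeds for the chain benchmark (3 families on a path calibrated
to ~20 SD links and sub-threshold direct scores, 1000 shuffles); 20 seeds
of the 2-superfamily/6-family world at 500 shuffles; 10 seeds of the
5-family tree benchmark at 100 consensus replicates plus the
high-divergence MSA contrast; 50 barrels for the strand caller; 20 + 20
seeds for the repeat scan at 2000 shuffles (so that P = 0.001 is
resolvable). These sizes were chosen to give stable rates on a single
CPU; all randomness flows from one master seed through fixed per-stage
derivations.

## Known limitations

* The bit-score conversion reuses BLAST's default-gap Karlin–Altschul
  parameters for the 8/2 gap setting; bits and E-values are therefore
  approximate (ranking, not evidence).
* The strand caller is calibrated on the generator's architecture; on
  real sequences it should be used in family-consensus mode and treated
  as an estimate.
* Comparable-segment trimming maximizes a fixed objective
  (identities − gapped columns); other trade-offs between identities and
  gaps are conceivable and would shift borderline scores slightly.
* `verifyChain()` reports chains in the 4-node A–B–C–D format; longer
  paths arise implicitly through the family graph's transitive closure
  rather than as explicit multi-link chains.
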