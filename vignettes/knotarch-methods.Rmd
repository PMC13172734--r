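---
title: "Domain-architecture evolution of knottin toxin genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-architecture evolution of knottin toxin genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotarch)
```

## The biological problem

Spider venoms are dominated by inhibitor cystine knot (ICK) peptides:
small disulfide-locked toxins whose six framework cysteines follow the
pattern C-X(2–7)-C-X(3–10)-C-C-X(1–4)-C-X(3–13)-C. Some lineages carry
*bivalent* toxins — two tandem ICK domains joined by a short linker on one
precursor — and the valency of these toxins has changed repeatedly over
evolutionary time: a single ancient intra-exon duplication created
bivalency, and independent lineages have since reverted to monovalency
through distinct molecular accidents, or expanded further to trivalency.

`knotarch` implements the full forensic toolkit for reconstructing this
history from precursor sequences, gene models, transposable-element (TE)
annotations and phylogenies:

* **Detection** — framework scanning, domain/linker/tail partitioning,
  and validation of the conserved 3-exon precursor gene structure
  (signal peptide exon, propeptide exon separated by a phase 1 intron,
  and a mature-peptide exon behind a phase 2 intron).
* **Loss forensics** — classification of each reversal to monovalency as
  a nonsense point mutation, a frameshifting deletion, an unequal
  crossing-over fusion, or a TE disruption, with positional evidence,
  plus detection of pseudogenized domain remnants in 3'UTRs.
* **TE association** — flank-density permutation tests, windowed density
  tracks and shared-family synteny between paralog neighbourhoods.
* **Valency phylogenetics** — NJ trees with classical bootstrap,
  domain-clade separation tests, and Dollo/parsimony counting of gains
  and losses under alternative rootings.
* **Simulation** — a truth-tagged generator of whole toxin families, so
  every stage can be validated against known ground truth.

## Domain partitioning conventions

The literature never defines domain boundaries at residue resolution, so
the package fixes an unambiguous convention: a domain spans its first to
its last framework cysteine; the *linker* is everything strictly between
two adjacent domains; the *leader* precedes the first domain and the
*tail* follows the last. Under this convention
`leader + domain1 + linker1 + ... + tail` reconstructs the mature peptide
character-exactly, which is enforced by a property test. Overlapping
candidate frameworks are resolved greedily left-to-right with a
shortest-span tie-break; `all_matches = TRUE` preserves the full match
set for auditing. Extra cysteines inside the X-spacers do not invalidate
a match — the framework pattern implicitly allows them.

The signature of intra-exon duplication is the homology between the
interdomain linker and the C-terminal tail (in the archetypal bivalent
toxin, linker VPIS versus tail APIT: 2/4 identical). `linker_tail_homology()`
compares the last linker against the equally long suffix of the tail,
ungapped, which reproduces exactly this style of count.

## Alignment and scoring choices

No alignment scoring scheme is reported for the original nucleotide
comparisons, so the package declares one and uses it everywhere:
Needleman–Wunsch with match +1, mismatch −1, gap −2 and a deterministic
traceback (diagonal over up over left). Global identity counts gap
columns in the denominator; local and ungapped identities use segment
length. Ambiguity symbols (N, X) never match, themselves included, so
every reported "n/m bp" count is a count of unambiguous identities.
`best_local_match()` maximises the +1/−1 segment score subject to a
minimum length, breaking ties toward longer segments and then smaller
coordinates; it is verified against an exhaustive enumeration of all
ungapped segment pairs.

For crossover breakpoints, the score of a split point *b* is the number
of identical columns in the *match-maximising* global alignment of the
chimera prefix against donor domain 1 plus that of the suffix against
donor domain 2. The match-maximising global alignment of two strings is
their longest common subsequence, so one dynamic program yields all
prefix scores at once; this keeps the whole breakpoint scan at O(nm)
instead of O(n²m) and avoids tying the result to the NW gap penalty.
Maxima over consecutive *b* form the reported *ambiguity interval* — a
breakpoint between locally identical domain stretches is unidentifiable
in principle, so a point estimate would be dishonest. If the maximum
touches either end of the chimera the scan reports "no chimeric signal".

## The loss-mechanism cascade

`classify_loss_mechanism()` evaluates all four mechanisms and reports the
best-supported one, ranked by the number of mutational events each
explanation requires (a TE insertion visible in the annotation, then one
substitution, then one deletion, then one recombination event):

1. **TE disruption** — a TE annotation overlapping the region where the
   missing domain should lie (from the end of the last intact domain to
   the transcript end).
2. **Nonsense point** — the transcript's stop codon aligns in-frame to an
   ancestral non-stop codon differing at exactly one base. A guard
   requires the sequence downstream of the stop to keep tracking the
   ancestor in the same frame: a true nonsense loss leaves the lost
   domain as a 3'UTR remnant, whereas a frameshifted or fused transcript
   shows background-level identity there.
3. **Deletion stop** — a direct search over candidate ancestor spans
   (start within 75 bp of the stop, length 1–30 bp) whose removal
   recreates the observed stop as the first in-frame stop, with ≥ 80%
   reconstruction identity and the same downstream-remnant guard. The
   search is built around the re-checkability invariant: deleting the
   reported span from the ancestor reproduces the reported stop, always.
   A direct search is used instead of reading indels off the global
   alignment because near-identical tandem domains make gap placement
   non-identifiable, while reconstruction is.
4. **Fusion crossover** — the breakpoint scan above, accepted when the
   two-donor explanation strictly beats any single donor and the
   ambiguity interval is interior.

Calls that fit none of these remain `unresolved` — which is the correct
answer for, e.g., a fusion whose breakpoint region contains no divergent
site (the product is then literally identical to one parental domain).

Remnant detection (`scan_utr_remnant()`) scores the best ungapped local
match of the transcript against the lost-domain CDS at the nucleotide
level and across all six translated frames, and calibrates both scores
against dinucleotide-preserving shuffles of the query (Altschul–Erickson
Eulerian-path shuffling, preserving exact dinucleotide counts). The
significance threshold of p < 0.01 with 1,000 shuffles is a package
convention, exposed in the configuration; the profile search of the
original study used profile HMMs, which a position-specific scoring
matrix with pseudocounts (`build_pssm()`) replaces at desk scale with a
defined null.

## TE association

Flank densities are union-merged TE coverage of the ±5,000 bp flanks
divided by the total flank length; genes without full flanks on both
sides are excluded, and overlapping annotations are merged before
coverage so density is a fraction, never an insertion count. The
original comparison — ICK genes versus "the same number of non-ICK genes
selected randomly, repeated 1,000 times" — reports no test statistic.
The package instantiates it as an exact label-permutation test: the
statistic is the difference in group means, equal-size subsets are drawn
without replacement from the *pooled* densities, and the two-sided
empirical p-value carries the +1 correction so it is never zero.
Resampling only the non-ICK pool, read literally, would centre the null
on the observed difference (p ≈ 0.5 always) or understate its variance
(anti-conservative); the pooled permutation is the standard exact test
that the resampling design describes in spirit, and it is verified to be
uniform under the null and powered at 3× enrichment.

## Phylogenetics

The package does not re-implement maximum-likelihood inference:
externally inferred trees and alignments are first-class inputs, and the
internal path — p-distance/K2P distances, neighbor joining, classical
column-resampling bootstrap — exists so the pipeline is self-contained
and exactly testable (NJ recovers additive matrices to machine
precision). Taxa are sorted lexicographically before NJ so results do
not depend on input order.

Valency states collapse to binary (multivalent versus monovalent) for
event counting. `dollo_single_gain` places the one permitted gain on the
edge above the most recent common ancestor of all multivalent tips and
counts the minimum losses below it; note that when every monovalent tip
lies outside that clade, zero losses is the correct Dollo answer even if
the simulation truth placed the gain earlier — parsimony counts are
minima, not histories. `fitch` gives the unconstrained minimum-change
count via unit-cost Sankoff (so multifurcations are handled), and
`enumerate_rootings()` reports the loss count under every candidate root
edge, reproducing the "3 or 4 losses depending on the rooting" style of
robustness statement structurally rather than asserting either number.

## The synthetic world

The simulator's defaults encode the observed structure of these gene
families, and they are fixed once:

* 3-exon genes with exon-1/exon-2 CDS lengths 55 and 34 bp, which give
  intron phases 1 and 2, and the mature peptide wholly in exon 3.
* A single-domain ancestor with framework spacings (3, 6, 2, 6) and a
  4-residue tail; duplication tandem-copies the domain-plus-tail unit in
  place, so the ancestral tail becomes the linker (linker/tail homology
  is exactly 1 at the moment of duplication and decays under divergence).
* K2P substitutions with transition:transversion 2:1; framework cysteine
  codons are protected by default (purifying selection keeps
  architectures detectable, mirroring the structural conservation the
  analysis relies on); 3'UTRs evolve at a 2× rate multiplier (released
  constraint); coding sequence never acquires an unscripted in-frame stop.
* A TE catalogue whose class weights follow the reported repeat
  landscape: class II DNA elements dominate with Tc1/Mariner the largest
  single superfamily (31.5 weight), then LINEs (12.4) and Gypsy LTRs
  (7.0); insertion lengths are Normal(225, 180) bp truncated at 50, the
  reported mean and spread of shared insertions; background insertion
  rate 0.5/kb with a 3× default enrichment in toxin-gene flanks.
* For forensic validation the duplication is *ancient*: the two domains
  of the bivalent ancestor are ~25% diverged at the nucleotide level
  before any loss occurs, matching the observation that the most similar
  interdomain stretch in the real bivalent toxin is only 84% identical;
  the reduced gene and its compared bivalent relative are separated by a
  few percent of post-loss divergence.

What the generator does *not* emulate: population-level processes
(no coalescent, no selection coefficients beyond the cysteine toggle),
intron-sequence homology, TE sequence realism (TE insertions are random
sequence with family labels), and indel evolution outside the scripted
events (substitution-only divergence keeps simulated families
co-alignable, which the pipeline exploits). A green simulation-recovery
test therefore establishes correctness of the inference machinery on the
stated model, not robustness to alignment error on real data.

Scripted events that are infeasible for a realized sequence (for
example, no linker codon one substitution away from a stop) cause the
branch's substitutions to be resampled, per configuration; the truth log
records every event with before/after sequences and replays exactly.

## Numerical and degenerate-input conventions

* Internal coordinates are 0-based half-open only inside the C++
  kernels; everything user-visible is 1-based inclusive.
* Empirical p-values always use the (1 + exceedances)/(n + 1) estimator.
* `nonsense_point` evidence reports the position of the substituted base
  (matching the "stop at position 126 bp" and "position 112 bp" styles,
  which mark the mutated base within its codon), plus the full stop
  interval; deletions are reported in ancestor coordinates and stops in
  transcript coordinates, since the deleted bases do not exist in the
  observed transcript.
* Identical-domain crossovers are flagged unidentifiable rather than
  assigned an arbitrary point breakpoint.
* The homolog filter applies the 40% identity ("twilight zone") gate and
  the framework gate together, with per-candidate reason codes.

## Known limitations

* The loss cascade assumes the compared ancestor proxy is a genuine
  bivalent relative; at comparison divergences well beyond ~10%/site the
  single-substitution nonsense test and the 80%-identity deletion
  reconstruction degrade gracefully to `unresolved` rather than guessing.
* The PSSM remnant search is weaker than a full profile HMM for remnants
  much shorter than the donor; the empirical-shuffle p-value compensates
  for composition bias but not for repeat-induced autocorrelation.
* NJ+bootstrap is a plumbing substitute, not a replacement for ML
  phylogenetics; for publication-grade trees supply external newick
  files.
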