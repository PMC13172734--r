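# knotarch

Domain-architecture evolution of knottin (ICK) toxin genes.

Spider-venom inhibitor cystine knot (ICK) peptides carry six framework
cysteines in the pattern

```
C-X(2-7)-C-X(3-10)-C-C-X(1-4)-C-X(3-13)-C
```

Some lineages encode *bivalent* toxins — two tandem ICK domains joined by a
short linker on a single precursor — and valency has changed repeatedly:
one ancient intra-exon duplication created bivalency, and independent
lineages have since reverted to monovalency through nonsense point
mutations, frameshifting deletions, unequal crossing-over fusions, or
transposable-element (TE) disruption, or expanded further to trivalency.

`knotarch` is an R toolkit for reconstructing that history from precursor
sequences (FASTA), gene models (GFF3-style feature tables), TE annotations
(RepeatMasker `.out`/BED) and phylogenies (newick):

* **Detection** — framework scanning (`scan_ick_frameworks`),
  domain/linker/tail partitioning (`partition_architecture`), linker
  conservation and linker-versus-tail exaptation scores, and validation of
  the conserved 3-exon gene structure with intron phases 1 and 2
  (`validate_gene_structure`).
* **Loss forensics** — `classify_loss_mechanism` assigns each reversal to
  monovalency to `nonsense_point`, `deletion_stop`, `fusion_crossover`,
  `te_disruption` or `unresolved`, with re-checkable positional evidence;
  `scan_utr_remnant` finds pseudogenized domain remnants in 3'UTRs against
  a dinucleotide-preserving shuffle null; `locate_crossover_breakpoint`
  reports breakpoint ambiguity intervals and the facilitating
  high-identity stretch.
* **TE association** — union-coverage flank densities (±5,000 bp),
  an exact permutation test against non-ICK genes, 100 bp windowed density
  tracks, and shared-TE-family synteny between paralog regions.
* **Valency phylogenetics** — NJ + classical bootstrap (externally
  inferred trees are first-class inputs), domain-clade separation tests,
  and Dollo / minimum-change counting of valency gains and losses under
  every candidate rooting.
* **Simulation** — `simulate_family` generates truth-tagged synthetic
  toxin families (genes, transcripts, peptides, TE landscapes, trees) so
  every stage is testable without external data.

## Worked example

Simulate a six-tip family in which bivalency arises once at the root and
is lost twice — once by a nonsense point mutation, once by an unequal
crossing-over fusion — then recover both mechanisms and the event counts:

```r
library(knotarch)

nwk <- "((t1:0.05,t2:0.05):0.05,((t3:0.05,t4:0.05):0.05,(t5:0.05,t6:0.05):0.05):0.05);"
events <- list(
  list(node = "root", type = "duplication"),
  list(node = "t1", type = "loss", mechanism = "nonsense_point"),
  list(node = "t3", type = "loss", mechanism = "fusion_crossover"))
bundle <- simulate_family(sim_config(seed = 5, tree = nwk, events = events))
bundle$tip_states
#> t1 t2 t3 t4 t5 t6
#>  1  2  1  2  2  2

call <- classify_loss_mechanism(bundle$precursors$t1, bundle$precursors$t2)
call$mechanism
#> [1] "nonsense_point"
call$evidence[c("codon_from", "codon_to", "stop_position_bp")]
#> $codon_from
#> [1] "TGC"
#>
#> $codon_to
#> [1] "TGA"
#>
#> $stop_position_bp
#> [1] 177

classify_loss_mechanism(bundle$precursors$t3, bundle$precursors$t4)$mechanism
#> [1] "fusion_crossover"
```

The nonsense evidence reads: a cysteine codon (TGC) of the bivalent
ancestor became the stop TGA by a single substitution at transcript
position 177, truncating the ORF and leaving the second domain as a
3'UTR remnant — the classic route from bivalency back to monovalency.
Event counting on the true tree confirms a single origin of bivalency
with two independent losses:

```r
count_valency_events(bundle$tree, bundle$tip_states, "dollo_single_gain")
#> dollo_single_gain: 1 gain(s), 2 loss(es)
```

On a bivalent architecture, the exaptation of the ancestral C-terminal
tail into the interdomain linker is scored directly; for the archetypal
bivalent toxin's printed linker/tail pair this is 2/4 residues:

```r
pairwise_identity("VPIS", "APIT", "ungapped")
#> ungapped identity: 2/4 = 0.500
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package end to end — simulating a scripted family and
executing detection, loss forensics, the TE flank permutation test and
Dollo event counting across rootings — and writes the target report as
JSON to `--out`.

## Command-line front end

A thin Rscript wrapper ships in `inst/scripts/knotarch` with subcommands
`simulate`, `detect`, `forensics`, `teassoc` and `run`; each is a direct
wrapper over the exported functions above.
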