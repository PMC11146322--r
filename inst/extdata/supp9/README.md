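# Published supplementary inputs (not redistributed)

Two acceptance tests reproduce published per-gene branch-model results and
need the original supplementary codon alignments and guide trees, which are
external downloads and are not bundled with this package. To run those
tests, place here (plain FASTA / newick):

- `Fgf9.fasta`, `Slc25a18.fasta` — per-gene in-frame codon alignments
  (13 bat taxa, sequences labeled by genus)
- `tree1.nwk` — the guide tree for those taxa (the Lasiurus terminal
  branch is labeled foreground by the test)
- `Trpc4_bats_carnivores.fasta`, `Trpc4_itpr_region.fasta`,
  `Trpc4_tree.nwk` — the bats-vs-carnivores Trpc4 alignments (full CDS and
  the ITPR-binding region) and their tree with all bat branches tagged `#1`

Without these files the two tests report failure with this instruction;
every other test is self-contained.
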