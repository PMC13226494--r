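# Synthetic transporter-survey fixture

These TSVs are a **synthetic reconstruction** of the tabular outputs of a
sugar-transporter survey of the *Sulfobacillus acidophilus* /
*S. thermosulfidooxidans* type-strain genomes, assembled from the published
inventory of accepted systems. They are not tool outputs: bit scores,
lengths, directional best-hit score matrices, the shared nucleotide-binding
protein loci (`AEW09001.1`, `SMC09001.1`) and the incomplete
dihydroxyacetone-kinase-like PTS sequences (`SMC091xx.1`) are invented
placeholders, chosen so that the screening rules reproduce the published
family counts. Decoy rows (bit score at or below 100, unexpected
transmembrane-helix counts) are included to exercise the retention filters.

Files:

- `synthetic_hits.tsv` — homology hits: `query_id`, `subject_id`,
  `bit_score`, `family_hint`, `genome`
- `synthetic_topology.tsv` — `seq_id`, `tm_helix_count`,
  `has_signal_peptide`, `length_aa`
- `synthetic_operons.tsv` — `operon_id`, `seq_id`, `role`, `genome`,
  `substrate`
- `synthetic_mfs_scores_ab.tsv` / `_ba.tsv` — directional MFS score tables
  for bidirectional best-hit orthology (exactly four mutual best pairs; one
  deliberate tie that must yield no call)
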