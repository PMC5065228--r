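# Real reference inputs (user-supplied)

This directory ships empty: the build and test environments are offline, so
the two small public downloads that the sequence/structure acceptance checks
need cannot be fetched automatically.  To enable those checks, place here:

1. `abcg_sequences.fasta` — UniProt canonical sequences with ids containing
   `ABCG2`, `ABCG5` and `ABCG8` (accessions Q9UNQ0, Q9H222, Q9H221), e.g.

       curl -o abcg_sequences.fasta \
         "https://rest.uniprot.org/uniprotkb/accessions?accessions=Q9UNQ0,Q9H222,Q9H221&format=fasta"

2. `5do7_chainAB_ca_pairs.tsv` — tab-separated, header
   `xa ya za xb yb zb`, one row per pre-mapped C-alpha pair of chain A
   (ABCG5) and chain B (ABCG8) of PDB entry 5DO7, with the flexible
   NBD-TMD linker region excluded.  Chain mapping between the two
   non-identical chains must be done from a sequence alignment of the two
   chains; this package deliberately does not map atoms between
   non-identical chains itself.

Everything else in the test suite and the acceptance report runs fully
offline on synthetic data.
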