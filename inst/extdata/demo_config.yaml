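# Demo configuration for the ghmine discovery pipeline.
# Input paths are relative to the directory the pipeline is launched from;
# generate them first with `ghmine simulate --out demo_data` (or
# write_dataset() in R).
proteins: demo_data/proteins.faa
annotations: demo_data/annotations.tsv
alignments: demo_data/alignments.tsv
identifications: demo_data/identifications.tsv
out_dir: demo_out
min_unique_peptides: 2
top_k: 50
seed: 1
consensus:
  top_n: 25
  min_support: 0.5
  weight_by_bitscore: true
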