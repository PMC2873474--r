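# Demo configuration: a small fully synthetic run of the whole pipeline.
simulate: true
seed: 42
sim:
  genome_lengths: {chromosome: 120000, plasmid_a: 60000}
  n_genes: 60
  n_transcripts: 25
  mean_depth: 25
  end_noise_sd: 0
contig:
  L_min: 50
  L_max: 350
  C: 10
  c: 5
structure:
  enabled: true
  k: 400
  background_k: 100
  n_windows: 40
  max_candidates: 6
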