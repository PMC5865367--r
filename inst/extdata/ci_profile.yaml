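# Reduced desk-scale profile preserving the program's qualitative behaviour:
# smaller genome and cohorts, shorter chains, 5 replicates x 15 generations.
model_id: 1
training_mode: purebred
w: [0.0, 0.5, 1.0]
n_generations: 15
n_replicates: 5
n_founders: 100
n_breed_generations: 100
master_seed: 1
genome:
  n_chromosomes: 4
  chromosome_length: 1.0
  n_snps_target: 400
  n_qtl_target: 40
  n_candidate_loci: 880
  mutation_rate: 2.5e-5
  historical_size: 500
  historical_generations: 300
  maf_threshold_arch: 0.05
selection:
  n_candidates: 300
  n_males_selected: 30
  n_females_selected: 60
  n_purebred_offspring: 300
  n_crossbred_offspring: 300
chain:
  niter: 2000
  burnin: 500
  thin: 10
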