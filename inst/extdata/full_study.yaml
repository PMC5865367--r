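# Full-scale study design: 50 replicates x 40 generations of selection with
# 20000-iteration chains. Cluster-scale; use study_profile("test") or the
# reduced ci_profile.yaml for desk-scale runs. Set model_id to 1, 2 or 3 and
# training_mode to "purebred" or "crossbred" to cover the scenario grid.
model_id: 1
training_mode: purebred
w: [0.0, 0.25, 0.5, 0.75, 1.0]
n_generations: 40
n_replicates: 50
n_founders: 100
n_breed_generations: 100
master_seed: 1
genome:
  n_chromosomes: 4
  chromosome_length: 1.0
  n_snps_target: 4000
  n_qtl_target: 400
  n_candidate_loci: 8800
  mutation_rate: 2.5e-5
  historical_size: 2000
  historical_generations: 2000
  maf_threshold_arch: 0.05
selection:
  n_candidates: 1000
  n_males_selected: 100
  n_females_selected: 200
  n_purebred_offspring: 1000
  n_crossbred_offspring: 1000
chain:
  niter: 20000
  burnin: 3000
  thin: 10
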