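# Bundled synthetic-study configuration: simulates a full cohort of slides,
# extracts image features, fits and validates the TKI-benefit model, and runs
# the image-genomics stage with its shuffle control.
seed: 42
out_dir: scratch/study
stages:
  simulate: true
  features: true
  fit: true
  predict: true
  evaluate: true
  gsea: true
simulate:
  n_patients: 40
  cellmap:
    width_px: 4000
    height_px: 4000
    n_nests: 5
    nest_radius_px: 500
    mixing: 0.25
  cohort:
    baseline_rate: 0.02
    censoring_rate: 0.008
    treat_prob: 0.7
    trt_loghr_benefit: -1.6094379124341003
    trt_loghr_nonbenefit: 0.0
  expression:
    n_genes: 2000
    n_correlated: 60
    target_rho: 0.3
    planted_set_size: 30
    n_decoy_sets: 40
    decoy_set_size: 30
features:
  tile_size_px: 500
  min_tumor_cells: 10
  patch_side_px: 1024
  max_patches: 100
fit:
  alpha: 0.5
  nfolds: 5
gsea:
  feature_name: interaction_tumor_stroma
  n_permutations: 2000
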