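{
  "_comment": "Template for re-running the full analysis on a real cohort. Point the four paths at preprocessed archive exports: S/E/M as gene-by-sample TSVs (header row = sample IDs, first column = gene IDs; S binarized or raw nonzero counts), and a clinical TSV with columns sample_id, tumor_status, vital_status, survival_days. Then: Rscript inst/cli/mmibn run-all --config this_file.json",
  "paths": {
    "S": "/data/cohort/mutation_matrix.tsv",
    "E": "/data/cohort/expression_matrix.tsv",
    "M": "/data/cohort/methylation_matrix.tsv",
    "clinical": "/data/cohort/clinical.tsv"
  },
  "outcome": "tumor_status",
  "mmi": { "k": 15 },
  "selection_rule": "cdf_quantile",
  "selection_parameter": 0.995,
  "score": { "ess": 1.0, "max_parents": 4, "candidates_per_node": 10, "restarts": 5, "seed": 1 },
  "mn_radius": 1,
  "alpha": 0.05,
  "min_count": 5,
  "out_dir": "cohort_run",
  "seed": 1
}
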