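{
  "seed": 20,
  "parameters": {
    "seed": 20,
    "simulate": true,
    "data_dir": {},
    "min_markers": 20,
    "min_related": 50,
    "dissimilarity_scope": "substudy",
    "dissimilarity_interaction": true,
    "pattern_alpha": 0.05,
    "rcca_top_sgb": 20,
    "complete_case_parameter": "diastolic_bp",
    "lambda_grid1": [0.0001, 0.000158489319246111, 0.000251188643150958, 0.000398107170553497, 0.000630957344480193, 0.001, 0.00158489319246111, 0.00251188643150958, 0.00398107170553497, 0.00630957344480193, 0.01, 0.0158489319246111, 0.0251188643150958, 0.0398107170553497, 0.0630957344480194, 0.1, 0.158489319246111, 0.251188643150958, 0.398107170553497, 0.630957344480194, 1],
    "lambda_grid2": [0.0001, 0.000158489319246111, 0.000251188643150958, 0.000398107170553497, 0.000630957344480193, 0.001, 0.00158489319246111, 0.00251188643150958, 0.00398107170553497, 0.00630957344480193, 0.01, 0.0158489319246111, 0.0251188643150958, 0.0398107170553497, 0.0630957344480194, 0.1, 0.158489319246111, 0.251188643150958, 0.398107170553497, 0.630957344480194, 1],
    "r_outer": 0.5,
    "k_pairs": 10,
    "metabolite_link_alpha": 0.05,
    "n_perm": 999,
    "fdr_method": "BH",
    "sim": {
      "n_triads": 29,
      "n_substudies": 3,
      "n_sgb": 50,
      "n_donors": 8,
      "same_strain_dist": [0.01, 0.004],
      "diff_strain_dist": [0.2, 0.06],
      "engraft_prob": [0.5, 0.5, 0.5, 0.45, 0.441304347826087, 0.432608695652174, 0.423913043478261, 0.415217391304348, 0.406521739130435, 0.397826086956522, 0.389130434782609, 0.380434782608696, 0.371739130434783, 0.36304347826087, 0.354347826086957, 0.345652173913043, 0.33695652173913, 0.328260869565217, 0.319565217391304, 0.310869565217391, 0.302173913043478, 0.293478260869565, 0.284782608695652, 0.276086956521739, 0.267391304347826, 0.258695652173913, 0.25, 0.241304347826087, 0.232608695652174, 0.223913043478261, 0.215217391304348, 0.206521739130435, 0.197826086956522, 0.189130434782609, 0.180434782608696, 0.171739130434783, 0.16304347826087, 0.154347826086957, 0.145652173913043, 0.13695652173913, 0.128260869565217, 0.119565217391304, 0.110869565217391, 0.102173913043478, 0.0934782608695652, 0.0847826086956522, 0.0760869565217391, 0.0673913043478261, 0.058695652173913, 0.05],
      "p_donor_present": 0.8,
      "p_pre_present": 0.7,
      "effect_map": [
        {
          "sgb_id": "SGB0001",
          "target": "diastolic_bp",
          "type": "clinical",
          "delta": -16
        },
        {
          "sgb_id": "SGB0002",
          "target": "diastolic_bp",
          "type": "clinical",
          "delta": -19.5
        },
        {
          "sgb_id": "SGB0003",
          "target": "diastolic_bp",
          "type": "clinical",
          "delta": -13.2
        },
        {
          "sgb_id": "SGB0001",
          "target": "M01",
          "type": "metabolite",
          "delta": -0.5
        },
        {
          "sgb_id": "SGB0002",
          "target": "M01",
          "type": "metabolite",
          "delta": -0.5
        }
      ],
      "missing_dbp_subjects": 10,
      "n_metabolites": 40,
      "metabolite_missing_rate": 0.08,
      "marker_count_range": [20, 200],
      "seed": 20
    }
  },
  "stages": {
    "simulate": "ok",
    "thresholds": "ok",
    "engraft": "ok",
    "metrics": "ok",
    "integrate": "ok",
    "linkstats": "ok"
  },
  "counts": {
    "n_samples": 66,
    "n_triads": 29,
    "n_substudies": 3,
    "n_sgb": 50,
    "n_sgb_estimable": 50,
    "n_origin_calls": 1450,
    "n_engraftment_events": 285,
    "n_pattern_calls": 285,
    "n_complete_cases": 19,
    "n_selected_pairs": 10,
    "n_metabolite_hits": 11
  },
  "statistics": {
    "mean_f_donor": 0.27976044,
    "mean_f_pre": 0.74728304,
    "beta_donor_post": -0.26627541,
    "lambda1": 1,
    "lambda2": 0.039810717,
    "first_canonical_cor": 0.79415852,
    "top_lmm_sgb": "SGB0002",
    "top_lmm_parameter": "diastolic_bp",
    "top_lmm_estimate": -12.295606,
    "top_lmm_p_fdr": 0.037832952,
    "procrustes_m2": 0.87787235,
    "procrustes_p": 0.057,
    "within_pc1_var": 0.26728767
  },
  "config_hash": "01028914619ad3fe825246ab811e9eb9"
}
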