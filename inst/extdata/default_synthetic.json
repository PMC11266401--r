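{
  "n_cases": 645,
  "comparator_pool_size": 6450,
  "index_date_window": ["2016-01-01", "2018-12-31"],
  "data_end": "2019-12-31",
  "rng_seed": 20160101,
  "demographics": {
    "p_male": 0.5907,
    "age_bands": [
      {
        "lower": 20,
        "upper": 30,
        "prob": 0.0295
      },
      {
        "lower": 30,
        "upper": 40,
        "prob": 0.045
      },
      {
        "lower": 40,
        "upper": 50,
        "prob": 0.124
      },
      {
        "lower": 50,
        "upper": 60,
        "prob": 0.2667
      },
      {
        "lower": 60,
        "upper": 70,
        "prob": 0.2744
      },
      {
        "lower": 70,
        "upper": 80,
        "prob": 0.1736
      },
      {
        "lower": 80,
        "upper": 90,
        "prob": 0.0868
      }
    ],
    "region_probs": {
      "Taipei": 0.262,
      "North": 0.2667,
      "Central": 0.2186,
      "South": 0.1132,
      "East": 0.0171,
      "Kaohsiung-PingTung": 0.1224
    }
  },
  "comorbidity_prevalence": {
    "case": {
      "cardiac": 0.2729,
      "malignancy": 0.2341,
      "renal": 0.2171,
      "pulmonary": 0.0651,
      "neuropathy": 0.0248,
      "liver": 0.0233
    },
    "comparator": {
      "cardiac": 0.1211,
      "malignancy": 0.0443,
      "renal": 0.038,
      "pulmonary": 0.0026,
      "neuropathy": 0.0051,
      "liver": 0.0009
    }
  },
  "mortality": {
    "breaks": [90, 182, 1095],
    "cum_mortality": {
      "case": [0.084, 0.121, 0.188],
      "comparator": [0.0005, 0.009, 0.037]
    }
  },
  "cost_process": {
    "case": {
      "outpatient": {
        "annual_counts": [37.88, 26, 23],
        "unit_cost": [4744.98416050686, 4286.05929461805, 3937.10529205086],
        "cost_shape": 1.5,
        "med_frac": 0.484811394236119,
        "count_size": 3,
        "los": {},
        "los_size": {},
        "cost_scale": {},
        "zero_prob": 0
      },
      "emergency": {
        "annual_counts": [0.97, 0.55, 0.6],
        "unit_cost": [6494.84536082474, 5866.67760823383, 5389.03591164434],
        "cost_shape": 1.2,
        "med_frac": 0.25,
        "count_size": 0.6,
        "los": {},
        "los_size": {},
        "cost_scale": {},
        "zero_prob": 0
      },
      "inpatient": {
        "annual_counts": [1.15, 0.506, 0.55],
        "unit_cost": [9022.46256239601, 8149.82900212041, 7486.30214562098],
        "cost_shape": null,
        "med_frac": 0.3,
        "count_size": 0.8,
        "los": [10.4521739130435, 14.7280632411067, 14.1818181818182],
        "los_size": 1.2,
        "cost_scale": 6000,
        "zero_prob": 0
      }
    },
    "comparator": {
      "outpatient": {
        "annual_counts": [18.6600985221675, 18.6600985221675, 18.6600985221675],
        "unit_cost": [1800, 1800, 1800],
        "cost_shape": 1.5,
        "med_frac": 0.484811394236119,
        "count_size": 3,
        "los": {},
        "los_size": {},
        "cost_scale": {},
        "zero_prob": 0
      },
      "emergency": {
        "annual_counts": [0.350180505415162, 0.350180505415162, 0.350180505415162],
        "unit_cost": [3000, 3000, 3000],
        "cost_shape": 1.2,
        "med_frac": 0.25,
        "count_size": 0.6,
        "los": {},
        "los_size": {},
        "cost_scale": {},
        "zero_prob": 0
      },
      "inpatient": {
        "annual_counts": [0.2875, 0.2875, 0.2875],
        "unit_cost": [5916.97556499098, 5916.97556499098, 5916.97556499098],
        "cost_shape": null,
        "med_frac": 0.3,
        "count_size": 0.8,
        "los": [7.60158102766798, 7.60158102766798, 7.60158102766798],
        "los_size": 1.2,
        "cost_scale": 6000,
        "zero_prob": 0
      }
    },
    "pre_index_multiplier": {
      "case": 2,
      "comparator": 1
    }
  },
  "covariate_effects": {
    "age_log_slope": 0.006,
    "age_center": 60.78,
    "male": 1.1,
    "region": {
      "Taipei": 1,
      "North": 1,
      "Central": 1,
      "South": 1,
      "East": 1,
      "Kaohsiung-PingTung": 1
    },
    "comorbidity": {
      "cardiac": 1.25,
      "malignancy": 1.2,
      "renal": 1.25,
      "pulmonary": 1.15,
      "neuropathy": 1.1,
      "liver": 1.15
    }
  },
  "traps": {
    "no_biopsy": 6,
    "single_claim": 6,
    "short_gap": 6,
    "prior_2015": 6,
    "switch": 6,
    "registry": 6
  },
  "codes": {
    "qualifying": ["E85.4", "E85.8", "E85.9"],
    "switch_codes": ["E85.0", "E85.1", "E85.2", "E83.3"],
    "registry_nonal": [
      {
        "code": "277.3",
        "system": "icd9"
      },
      {
        "code": "E85.1",
        "system": "icd10"
      }
    ],
    "prior_icd9": "277.3",
    "biopsy_procs": ["BX01", "BX02"],
    "benign_icd10": ["Z00.0", "M54.5", "K21.0", "H52.1", "R51"],
    "benign_icd9": ["V70.0", "724.2", "530.81", "367.1", "784.0"]
  },
  "plant_patterns": true,
  "version": "1"
}
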