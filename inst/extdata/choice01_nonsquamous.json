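{
  "population": "non_squamous",
  "survival": {
    "placebo": {
      "os": {
        "intercept": 3.084,
        "log_scale": -0.399,
        "time_unit": "months"
      },
      "pfs": {
        "intercept": 2.139,
        "log_scale": -0.217,
        "time_unit": "months"
      }
    },
    "toripalimab": {
      "os": {
        "intercept": 3.758,
        "log_scale": -0.175,
        "time_unit": "months"
      },
      "pfs": {
        "intercept": 2.777,
        "log_scale": -0.174,
        "time_unit": "months"
      }
    }
  },
  "costs": [
    {
      "name": "chemotherapy_placebo",
      "arm": "placebo",
      "state": "PFS",
      "base_value": 1018,
      "low": 713,
      "high": 1325,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "chemotherapy_arm_pfs_cost"
    },
    {
      "name": "tests_placebo",
      "arm": "placebo",
      "state": "PFS",
      "base_value": 420,
      "low": 294,
      "high": 546,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "chemotherapy_arm_pfs_cost"
    },
    {
      "name": "ae_management_placebo",
      "arm": "placebo",
      "state": "PFS",
      "base_value": 138,
      "low": 97,
      "high": 179,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "chemotherapy_arm_pfs_cost"
    },
    {
      "name": "hospitalization_placebo",
      "arm": "placebo",
      "state": "PFS",
      "base_value": 50,
      "low": 35,
      "high": 65,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "chemotherapy_arm_pfs_cost"
    },
    {
      "name": "pd_treatment_placebo",
      "arm": "placebo",
      "state": "PD",
      "base_value": 342,
      "low": 239,
      "high": 445,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "pd_treatment_placebo"
    },
    {
      "name": "toripalimab",
      "arm": "toripalimab",
      "state": "PFS",
      "base_value": 342,
      "low": 239,
      "high": 445,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "combined_arm_pfs_cost"
    },
    {
      "name": "chemotherapy_toripalimab",
      "arm": "toripalimab",
      "state": "PFS",
      "base_value": 1018,
      "low": 713,
      "high": 1325,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "combined_arm_pfs_cost"
    },
    {
      "name": "tests_toripalimab",
      "arm": "toripalimab",
      "state": "PFS",
      "base_value": 439,
      "low": 307,
      "high": 571,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "combined_arm_pfs_cost"
    },
    {
      "name": "ae_management_toripalimab",
      "arm": "toripalimab",
      "state": "PFS",
      "base_value": 140,
      "low": 98,
      "high": 182,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "combined_arm_pfs_cost"
    },
    {
      "name": "hospitalization_toripalimab",
      "arm": "toripalimab",
      "state": "PFS",
      "base_value": 50,
      "low": 35,
      "high": 65,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "combined_arm_pfs_cost"
    },
    {
      "name": "pd_treatment_toripalimab",
      "arm": "toripalimab",
      "state": "PD",
      "base_value": 299,
      "low": 209,
      "high": 389,
      "distribution": "gamma",
      "application": "per_month",
      "start_cycle": 0,
      "dsa_group": "pd_treatment_toripalimab"
    }
  ],
  "utilities": {
    "u_pfs": 0.673,
    "u_pd": 0.473,
    "u_death": 0,
    "pfs_low": 0.47,
    "pfs_high": 0.87,
    "pd_low": 0.33,
    "pd_high": 0.61,
    "distribution": "beta"
  },
  "pd_cost_uptake": 1
}
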