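{
  "settings": {
    "horizon_years": 15,
    "cycle_length_years": 1,
    "annual_discount_rate": 0.03,
    "background_mortality": 0.0003,
    "background_mortality_timescale": "cycle",
    "wtp_per_qaly": 31510,
    "half_cycle_correction": false
  },
  "adt_duration_months": 24,
  "arms": {
    "crt": {
      "label": "conventionally fractionated radiotherapy",
      "scheme": {
        "total_dose_Gy": 78,
        "dose_per_fraction_Gy": 2,
        "n_fractions": 39,
        "alpha_beta_Gy": 3
      },
      "ffs_model": {
        "rate": 0.036100964302319,
        "shape": 0.978456274131801
      },
      "ps_death_model": {
        "rate": 0.141390980159197,
        "shape": 1
      },
      "toxicity_incidence": 0.02
    },
    "uhrt": {
      "label": "ultra-hypofractionated radiotherapy",
      "scheme": {
        "total_dose_Gy": 42.7,
        "dose_per_fraction_Gy": 6.1,
        "n_fractions": 7,
        "alpha_beta_Gy": 3
      },
      "ffs_model": {
        "rate": 0.036100964302319,
        "shape": 0.978456274131801
      },
      "ps_death_model": {
        "rate": 0.2468289472682,
        "shape": 1
      },
      "toxicity_incidence": 0.06
    }
  },
  "parameters": {
    "u_ffs_crt": {
      "base": 0.91,
      "low": 0.7274,
      "high": 1,
      "dist": "beta",
      "units": "utility",
      "description": "FFS utility, CRT, incl. grade >=2 urinary toxicity"
    },
    "u_ffs_uhrt": {
      "base": 0.85,
      "low": 0.7265,
      "high": 1,
      "dist": "beta",
      "units": "utility",
      "description": "FFS utility, UHRT, incl. grade >=2 urinary toxicity"
    },
    "u_ps": {
      "base": 0.61,
      "low": 0.49,
      "high": 0.73,
      "dist": "beta",
      "units": "utility",
      "description": "progressive survival utility"
    },
    "u_br": {
      "base": 0.74,
      "low": 0.592,
      "high": 0.888,
      "dist": "beta",
      "units": "utility",
      "description": "biochemical recurrence utility"
    },
    "u_cm": {
      "base": 0.25,
      "low": 0.2,
      "high": 0.3,
      "dist": "beta",
      "units": "utility",
      "description": "clinical metastasis utility"
    },
    "w_br": {
      "base": 0.7347,
      "low": 0.7347,
      "high": 0.7347,
      "dist": "fixed",
      "units": "weight",
      "description": "weight of biochemical recurrence in u_ps composition"
    },
    "discount_rate": {
      "base": 0.03,
      "low": 0,
      "high": 0.08,
      "dist": "beta",
      "units": "per year",
      "description": "annual discount rate"
    },
    "c_rt_crt": {
      "base": 7484.32,
      "low": 5987.456,
      "high": 8981.184,
      "dist": "gamma",
      "units": "USD",
      "description": "CRT radiotherapy course (planning + IMRT x 39)"
    },
    "c_rt_uhrt": {
      "base": 4711.36,
      "low": 3769.088,
      "high": 5653.632,
      "dist": "gamma",
      "units": "USD",
      "description": "UHRT radiotherapy course (planning + X-knife + IGRT x 7)"
    },
    "c_adt_monthly": {
      "base": 469.16,
      "low": 375.328,
      "high": 562.992,
      "dist": "gamma",
      "units": "USD/month",
      "description": "ADT (goserelin + bicalutamide) per month"
    },
    "c_ps_monthly": {
      "base": 1130.7275,
      "low": 904.582,
      "high": 1356.873,
      "dist": "gamma",
      "units": "USD/month",
      "description": "progressive survival monthly cost (supportive + systemic mix)"
    },
    "c_fu_annual": {
      "base": 67.26,
      "low": 53.808,
      "high": 80.712,
      "dist": "gamma",
      "units": "USD/year",
      "description": "FFS follow-up visits (PSA, DRE, bloods) per year"
    },
    "c_ut": {
      "base": 960,
      "low": 768,
      "high": 1152,
      "dist": "gamma",
      "units": "USD",
      "description": "grade >=2 urinary toxicity, one-time"
    }
  }
}
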