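{
  "description": "Base-case model inputs for the stage 1 hypertension cost-effectiveness model: event rates per 1000 person-years with 95% CIs, treatment-effect relative risks with 95% CIs, annual costs in 2020 US dollars with +/-25% uncertainty ranges, EQ-5D health-state utilities with ranges, and run-level constants.",
  "currency_year": 2020,
  "discount_rate": { "mean": 0.05, "low": 0.0, "high": 0.08 },
  "wtp_per_gdp": 10438.66,
  "productivity_window_years": 10,
  "productivity_reduction_drug": 0.048,
  "rates_per_1000py": [
    { "stage": 1, "event": "stroke",             "mean": 2.9,  "ci_low": 2.6,  "ci_high": 3.2 },
    { "stage": 1, "event": "mi",                 "mean": 1.3,  "ci_low": 1.1,  "ci_high": 1.5 },
    { "stage": 1, "event": "death",              "mean": 4.1,  "ci_low": 3.7,  "ci_high": 4.5 },
    { "stage": 1, "event": "mi_after_stroke",    "mean": 0.03, "ci_low": 0.01, "ci_high": 0.1 },
    { "stage": 1, "event": "recurrent_stroke",   "mean": 31.1, "ci_low": 22.5, "ci_high": 42.9 },
    { "stage": 1, "event": "death_after_stroke", "mean": 0.3,  "ci_low": 0.2,  "ci_high": 0.5 },
    { "stage": 1, "event": "stroke_after_mi",    "mean": 0.02, "ci_low": 0.01, "ci_high": 0.08 },
    { "stage": 1, "event": "recurrent_mi",       "mean": 36.4, "ci_low": 23.7, "ci_high": 55.8 },
    { "stage": 1, "event": "death_after_mi",     "mean": 0.2,  "ci_low": 0.1,  "ci_high": 0.3 },
    { "stage": 2, "event": "stroke",             "mean": 8.1,  "ci_low": 7.7,  "ci_high": 8.5 },
    { "stage": 2, "event": "mi",                 "mean": 2.3,  "ci_low": 2.1,  "ci_high": 2.5 },
    { "stage": 2, "event": "death",              "mean": 8.9,  "ci_low": 8.2,  "ci_high": 9.1 },
    { "stage": 2, "event": "mi_after_stroke",    "mean": 0.13, "ci_low": 0.08, "ci_high": 0.20 },
    { "stage": 2, "event": "recurrent_stroke",   "mean": 55.1, "ci_low": 49.1, "ci_high": 61.9 },
    { "stage": 2, "event": "death_after_stroke", "mean": 1.4,  "ci_low": 1.2,  "ci_high": 1.6 },
    { "stage": 2, "event": "stroke_after_mi",    "mean": 0.09, "ci_low": 0.06, "ci_high": 0.2 },
    { "stage": 2, "event": "recurrent_mi",       "mean": 44.9, "ci_low": 36.2, "ci_high": 55.7 },
    { "stage": 2, "event": "death_after_mi",     "mean": 0.4,  "ci_low": 0.3,  "ci_high": 0.5 }
  ],
  "progression_annual_pct": { "mean": 24.08, "ci_low": 21.72, "ci_high": 25.52 },
  "relative_risks": [
    { "stage": 1, "endpoint": "stroke",           "mean": 0.85, "ci_low": 0.68, "ci_high": 1.06 },
    { "stage": 1, "endpoint": "recurrent_stroke", "mean": 0.68, "ci_low": 0.56, "ci_high": 0.84 },
    { "stage": 1, "endpoint": "mi",               "mean": 0.98, "ci_low": 0.88, "ci_high": 1.09 },
    { "stage": 1, "endpoint": "recurrent_mi",     "mean": 0.73, "ci_low": 0.64, "ci_high": 0.82 },
    { "stage": 1, "endpoint": "death",            "mean": 0.98, "ci_low": 0.90, "ci_high": 1.06 },
    { "stage": 1, "endpoint": "progression",      "mean": 0.61, "ci_low": 0.53, "ci_high": 0.70 },
    { "stage": 2, "endpoint": "stroke",           "mean": 0.86, "ci_low": 0.72, "ci_high": 1.01 },
    { "stage": 2, "endpoint": "recurrent_stroke", "mean": 0.74, "ci_low": 0.67, "ci_high": 0.81 },
    { "stage": 2, "endpoint": "mi",               "mean": 0.86, "ci_low": 0.76, "ci_high": 0.96 },
    { "stage": 2, "endpoint": "recurrent_mi",     "mean": 0.68, "ci_low": 0.58, "ci_high": 0.80 },
    { "stage": 2, "endpoint": "death",            "mean": 0.87, "ci_low": 0.75, "ci_high": 1.00 }
  ],
  "annual_costs_usd": [
    { "item": "screening",         "mean": 28.71,   "rel_range": 0.25 },
    { "item": "drug",              "mean": 88.92,   "rel_range": 0.25 },
    { "item": "productivity",      "mean": 275.38,  "rel_range": 0.25 },
    { "item": "stroke_first_year", "mean": 3249.55, "rel_range": 0.25 },
    { "item": "stroke_subsequent", "mean": 1525.64, "rel_range": 0.25 },
    { "item": "mi_first_year",     "mean": 4710.83, "rel_range": 0.25 },
    { "item": "mi_subsequent",     "mean": 428.26,  "rel_range": 0.25 }
  ],
  "utilities": [
    { "state": "hypertension", "mean": 0.90, "ci_low": 0.79, "ci_high": 0.95 },
    { "state": "stroke",       "mean": 0.63, "ci_low": 0.26, "ci_high": 0.88 },
    { "state": "post_stroke",  "mean": 0.65, "ci_low": 0.46, "ci_high": 0.82 },
    { "state": "mi",           "mean": 0.76, "ci_low": 0.50, "ci_high": 0.89 },
    { "state": "post_mi",      "mean": 0.88, "ci_low": 0.67, "ci_high": 0.94 },
    { "state": "death",        "mean": 0.0,  "ci_low": 0.0,  "ci_high": 0.0 }
  ]
}
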