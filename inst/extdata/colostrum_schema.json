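{
  "variables": {
    "collection_point": {
      "type": "categorical",
      "levels": ["Cows teat", "Colostrum collection bucket", "Feeding teat", "Esophageal tube"]
    },
    "calving_pen_days": {
      "type": "continuous",
      "unit": "days"
    },
    "premilk_disinfection": {
      "type": "categorical",
      "levels": ["No", "Yes"]
    },
    "teat_dry_wiped": {
      "type": "categorical",
      "levels": ["No", "Yes"]
    },
    "milking_system": {
      "type": "categorical",
      "levels": ["Not applicable", "Parlor", "Robot"]
    },
    "collection_clean_freq": {
      "type": "categorical",
      "levels": ["Each use", "Less than each use", "Not applicable"]
    },
    "collection_clean_method": {
      "type": "categorical",
      "levels": ["Water", "Hypochlorite", "Parlor wash", "Peracetic acid", "Soap", "Not applicable"]
    },
    "collection_hot_water": {
      "type": "categorical",
      "levels": ["No", "Yes", "Not applicable"]
    },
    "feeding_clean_freq": {
      "type": "categorical",
      "levels": ["Each calf", "Less than each calf", "Not applicable"]
    },
    "feeding_clean_method": {
      "type": "categorical",
      "levels": ["Water", "Hypochlorite", "Parlor wash", "Peracetic acid", "Soap", "Not applicable"]
    },
    "feeding_hot_water": {
      "type": "categorical",
      "levels": ["No", "Yes", "Not applicable"]
    },
    "colostrum_frozen": {
      "type": "categorical",
      "levels": ["No", "Yes", "Not applicable"]
    },
    "pasteuriser_used": {
      "type": "categorical",
      "levels": ["No", "Yes", "Not applicable"]
    }
  },
  "structural_rules": [
    {
      "when": "Cows teat",
      "set_not_applicable": ["milking_system", "collection_clean_freq", "collection_clean_method", "collection_hot_water", "feeding_clean_freq", "feeding_clean_method", "feeding_hot_water", "colostrum_frozen", "pasteuriser_used"]
    },
    {
      "when": "Colostrum collection bucket",
      "set_not_applicable": ["feeding_clean_freq", "feeding_clean_method", "feeding_hot_water"]
    }
  ],
  "outcomes": {
    "tbc": {
      "count": "tbc",
      "log": "log_tbc",
      "threshold": 100000
    },
    "cc": {
      "count": "cc",
      "log": "log_cc",
      "threshold": 10000
    }
  },
  "id_columns": ["farm_id", "cow_id"]
}
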