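{
  "name": "caide",
  "metadata": {
    "description": "Midlife dementia risk score (Kivipelto et al., Lancet Neurology 2006) used as a comparator index, with the dichotomous late-life cut-offs: age >47 years, female sex, <10 years education, total cholesterol >6.5 mmol/L, systolic blood pressure >140 mm Hg, physically inactive, BMI >= 30 kg/m^2.",
    "notes": "Weights follow the original derivation cohort publication and are overridable; this validation framing treats female sex as the risk category."
  },
  "factors": [
    {
      "name": "age",
      "display": "Age (>47 years)",
      "source": "age",
      "stratified_by_sex": false,
      "categories": [
        {"label": "<=47", "age_max": 47, "points": 0},
        {"label": ">47", "age_min": 48, "points": 4}
      ]
    },
    {
      "name": "sex",
      "display": "Sex (female)",
      "source": "sex",
      "stratified_by_sex": false,
      "categories": [
        {"label": "male", "points": 0},
        {"label": "female", "points": 1}
      ]
    },
    {
      "name": "low_education",
      "display": "Low education (<10 years)",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "no", "points": 0},
        {"label": "yes", "points": 3}
      ]
    },
    {
      "name": "hypercholesterolaemia",
      "display": "Hypercholesterolaemia (>6.5 mmol/L)",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "no", "points": 0},
        {"label": "yes", "points": 2}
      ]
    },
    {
      "name": "high_systolic_bp",
      "display": "High systolic blood pressure (>140 mm Hg)",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "no", "points": 0},
        {"label": "yes", "points": 2}
      ]
    },
    {
      "name": "physical_inactivity",
      "display": "Physical inactivity",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "no", "points": 0},
        {"label": "yes", "points": 1}
      ]
    },
    {
      "name": "obesity",
      "display": "Obesity (BMI >= 30 kg/m^2)",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "no", "points": 0},
        {"label": "yes", "points": 2}
      ]
    }
  ]
}
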