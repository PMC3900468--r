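{
  "name": "anu_adri",
  "metadata": {
    "description": "Additive self-report Alzheimer's disease risk index. Points are evidence-synthesis weights: per-factor log risk ratios pooled across cohort studies, scaled to integers. Protective categories carry negative points.",
    "notes": "The 'heavy' alcohol category has no published point value; it defaults to 0 (same as abstainers) and can be overridden."
  },
  "factors": [
    {
      "name": "age",
      "display": "Age and gender",
      "source": "age",
      "stratified_by_sex": true,
      "strata": {
        "male": [
          {"label": "<65", "age_max": 64, "points": 0},
          {"label": "65-69", "age_min": 65, "age_max": 69, "points": 1},
          {"label": "70-74", "age_min": 70, "age_max": 74, "points": 12},
          {"label": "75-79", "age_min": 75, "age_max": 79, "points": 18},
          {"label": "80-84", "age_min": 80, "age_max": 84, "points": 26},
          {"label": "85-89", "age_min": 85, "age_max": 89, "points": 33},
          {"label": ">=90", "age_min": 90, "points": 38}
        ],
        "female": [
          {"label": "<65", "age_max": 64, "points": 0},
          {"label": "65-69", "age_min": 65, "age_max": 69, "points": 5},
          {"label": "70-74", "age_min": 70, "age_max": 74, "points": 14},
          {"label": "75-79", "age_min": 75, "age_max": 79, "points": 21},
          {"label": "80-84", "age_min": 80, "age_max": 84, "points": 29},
          {"label": "85-89", "age_min": 85, "age_max": 89, "points": 35},
          {"label": ">=90", "age_min": 90, "points": 41}
        ]
      }
    },
    {
      "name": "education",
      "display": "Educational level (years)",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "<8", "points": 0},
        {"label": "8-11", "points": 3},
        {"label": ">11", "points": 6}
      ]
    },
    {
      "name": "diabetes",
      "display": "Diabetes",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "no", "points": 0},
        {"label": "yes", "points": 3}
      ]
    },
    {
      "name": "tbi",
      "display": "Traumatic brain injury",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "no", "points": 0},
        {"label": "yes", "points": 4}
      ]
    },
    {
      "name": "depression",
      "display": "Depressive symptoms",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "no", "points": 0},
        {"label": "yes", "points": 2}
      ]
    },
    {
      "name": "cognitive_activity",
      "display": "Cognitively stimulating activities",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "low", "points": 0},
        {"label": "moderate", "points": -6},
        {"label": "high", "points": -7}
      ]
    },
    {
      "name": "social_network",
      "display": "Social network and engagement",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "high", "points": 0},
        {"label": "medium_high", "points": 1},
        {"label": "medium_low", "points": 4},
        {"label": "low", "points": 6}
      ]
    },
    {
      "name": "smoking",
      "display": "Smoking",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "never", "points": 0},
        {"label": "former", "points": 1},
        {"label": "current", "points": 4}
      ]
    },
    {
      "name": "alcohol",
      "display": "Alcohol consumption",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "abstainer", "points": 0},
        {"label": "light_moderate", "points": -3},
        {"label": "heavy", "points": 0}
      ]
    },
    {
      "name": "physical_activity",
      "display": "Physical activity",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "low", "points": 0},
        {"label": "medium", "points": -2},
        {"label": "high", "points": -3}
      ]
    },
    {
      "name": "fish_intake",
      "display": "Fish intake (serves/week)",
      "source": "column",
      "stratified_by_sex": false,
      "categories": [
        {"label": "0-0.25", "points": 0},
        {"label": "0.26-2.0", "points": -3},
        {"label": "2.1-4.0", "points": -4},
        {"label": ">=4.1", "points": -5}
      ]
    }
  ]
}
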