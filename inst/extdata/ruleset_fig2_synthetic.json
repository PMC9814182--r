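{
  "provenance": "paper_fig2",
  "comment": "Synthetic reconstruction of the published decision tree excluding ideation-duration predictors. The variable vocabulary (burdensomeness, hopelessness, self-efficacy, study week) is transcribed from the running text, as is the existence of a risk pathway combining the cumulative hopelessness mean, cumulative burdensomeness mean and self-efficacy change score; thresholds reuse the figure-1 values where the text states them and all remaining structure/labels are plausible completions, not transcriptions.",
  "variables": ["burdensomeness_cm", "hopelessness_cm", "self_efficacy_cs", "study_week"],
  "paths": [
    {
      "conditions": [
        {"var": "burdensomeness_cm", "cmp": "<=", "thr": 1.95, "na_follows": true}
      ],
      "prediction": "no SI",
      "probability": null
    },
    {
      "conditions": [
        {"var": "burdensomeness_cm", "cmp": ">", "thr": 1.95, "na_follows": false},
        {"var": "hopelessness_cm", "cmp": "<=", "thr": 2.19, "na_follows": true},
        {"var": "self_efficacy_cs", "cmp": "<=", "thr": -1.59, "na_follows": true}
      ],
      "prediction": "SI",
      "probability": null
    },
    {
      "conditions": [
        {"var": "burdensomeness_cm", "cmp": ">", "thr": 1.95, "na_follows": false},
        {"var": "hopelessness_cm", "cmp": "<=", "thr": 2.19, "na_follows": true},
        {"var": "self_efficacy_cs", "cmp": ">", "thr": -1.59, "na_follows": false}
      ],
      "prediction": "no SI",
      "probability": null
    },
    {
      "conditions": [
        {"var": "burdensomeness_cm", "cmp": ">", "thr": 1.95, "na_follows": false},
        {"var": "hopelessness_cm", "cmp": ">", "thr": 2.19, "na_follows": false},
        {"var": "study_week", "cmp": "<=", "thr": 1, "na_follows": true}
      ],
      "prediction": "no SI",
      "probability": null
    },
    {
      "conditions": [
        {"var": "burdensomeness_cm", "cmp": ">", "thr": 1.95, "na_follows": false},
        {"var": "hopelessness_cm", "cmp": ">", "thr": 2.19, "na_follows": false},
        {"var": "study_week", "cmp": ">", "thr": 1, "na_follows": false}
      ],
      "prediction": "SI",
      "probability": null
    }
  ]
}
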