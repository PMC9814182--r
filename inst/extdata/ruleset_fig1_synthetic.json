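{
  "provenance": "paper_fig1",
  "comment": "Synthetic reconstruction of the published decision tree for next-day suicidal ideation (model with ideation duration). The pathway {ideation_duration_cm <= 0.95, hopelessness_cm <= 2.19, burdensomeness_cm > 1.95, self_efficacy_cs <= -1.59} -> SI and the variable vocabulary are transcribed from the running text; all other branches and labels are plausible completions, not transcriptions.",
  "variables": ["ideation_duration_cm", "hopelessness_cm", "burdensomeness_cm", "self_efficacy_cs"],
  "paths": [
    {
      "conditions": [
        {"var": "ideation_duration_cm", "cmp": "<=", "thr": 0.95, "na_follows": true},
        {"var": "hopelessness_cm", "cmp": "<=", "thr": 2.19, "na_follows": true},
        {"var": "burdensomeness_cm", "cmp": "<=", "thr": 1.95, "na_follows": true}
      ],
      "prediction": "no SI",
      "probability": null
    },
    {
      "conditions": [
        {"var": "ideation_duration_cm", "cmp": "<=", "thr": 0.95, "na_follows": true},
        {"var": "hopelessness_cm", "cmp": "<=", "thr": 2.19, "na_follows": true},
        {"var": "burdensomeness_cm", "cmp": ">", "thr": 1.95, "na_follows": false},
        {"var": "self_efficacy_cs", "cmp": "<=", "thr": -1.59, "na_follows": true}
      ],
      "prediction": "SI",
      "probability": null
    },
    {
      "conditions": [
        {"var": "ideation_duration_cm", "cmp": "<=", "thr": 0.95, "na_follows": true},
        {"var": "hopelessness_cm", "cmp": "<=", "thr": 2.19, "na_follows": true},
        {"var": "burdensomeness_cm", "cmp": ">", "thr": 1.95, "na_follows": false},
        {"var": "self_efficacy_cs", "cmp": ">", "thr": -1.59, "na_follows": false}
      ],
      "prediction": "no SI",
      "probability": null
    },
    {
      "conditions": [
        {"var": "ideation_duration_cm", "cmp": "<=", "thr": 0.95, "na_follows": true},
        {"var": "hopelessness_cm", "cmp": ">", "thr": 2.19, "na_follows": false}
      ],
      "prediction": "SI",
      "probability": null
    },
    {
      "conditions": [
        {"var": "ideation_duration_cm", "cmp": ">", "thr": 0.95, "na_follows": false}
      ],
      "prediction": "SI",
      "probability": null
    }
  ]
}
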