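{
  "disease": "A",
  "setting": "on_demand",
  "provenance": "Published round-2 consensus medians (haemophilia A, on-demand)",
  "domains": [
    {
      "id": "bleeding_episodes",
      "name": "bleeding_episodes",
      "weight_pct": 38,
      "items": [
        {
          "id": "abr",
          "text": "What is the annualized bleeding rate (ABR)?",
          "scale_size": 4,
          "weight_pct": 100,
          "options": [
            {
              "label": "Total ABR 0",
              "severity_rank": 0,
              "value": 0
            },
            {
              "label": "Total ABR 1-2",
              "severity_rank": 1,
              "value": 0.33
            },
            {
              "label": "Total ABR 3-4",
              "severity_rank": 2,
              "value": 0.67
            },
            {
              "label": "Total ABR >= 5",
              "severity_rank": 3,
              "value": 1
            }
          ],
          "bucketing_rule": "abr"
        }
      ]
    },
    {
      "id": "joint_health",
      "name": "joint_health",
      "weight_pct": 37,
      "items": [
        {
          "id": "pj_count",
          "text": "How many Problem Joints (PJs) does the patient currently present with?",
          "scale_size": 4,
          "weight_pct": 18,
          "options": [
            {
              "label": "None",
              "severity_rank": 0,
              "value": 0
            },
            {
              "label": "1",
              "severity_rank": 1,
              "value": 0.33
            },
            {
              "label": "2-3",
              "severity_rank": 2,
              "value": 0.67
            },
            {
              "label": ">= 4",
              "severity_rank": 3,
              "value": 1
            }
          ],
          "bucketing_rule": "pj_count"
        },
        {
          "id": "tj_count",
          "text": "How many Target Joints (TJs) does the patient currently present with?",
          "scale_size": 3,
          "weight_pct": 19,
          "options": [
            {
              "label": "None",
              "severity_rank": 0,
              "value": 0
            },
            {
              "label": "1",
              "severity_rank": 1,
              "value": 0.5
            },
            {
              "label": ">= 2",
              "severity_rank": 2,
              "value": 1
            }
          ],
          "bucketing_rule": "tj_count"
        },
        {
          "id": "hjhs_change",
          "text": "Since the last assessment, how has the clinical evaluation of the patient's joint status changed?",
          "scale_size": 3,
          "weight_pct": 23,
          "options": [
            {
              "label": "Improved or remained approximately unchanged (at most +1 point)",
              "severity_rank": 0,
              "value": 0
            },
            {
              "label": "Moderately worsened (+2/+3 points)",
              "severity_rank": 1,
              "value": 0.5
            },
            {
              "label": "Significantly worsened (+4 points)",
              "severity_rank": 2,
              "value": 1
            }
          ],
          "bucketing_rule": "hjhs_delta"
        },
        {
          "id": "headus_change",
          "text": "Since the last assessment, how has the ultrasound evaluation of the patient's joint status changed?",
          "scale_size": 3,
          "weight_pct": 22,
          "options": [
            {
              "label": "Improved or remained unchanged",
              "severity_rank": 0,
              "value": 0
            },
            {
              "label": "Moderately worsened (+1 point)",
              "severity_rank": 1,
              "value": 0.5
            },
            {
              "label": "Significantly worsened (+2 points or more)",
              "severity_rank": 2,
              "value": 1
            }
          ],
          "bucketing_rule": "headus_delta"
        },
        {
          "id": "ajbr",
          "text": "What is the annualized joint bleeding rate (AJBR)?",
          "scale_size": 4,
          "weight_pct": 18,
          "options": [
            {
              "label": "Total AJBR 0",
              "severity_rank": 0,
              "value": 0
            },
            {
              "label": "Total AJBR 1",
              "severity_rank": 1,
              "value": 0.33
            },
            {
              "label": "Total AJBR 2",
              "severity_rank": 2,
              "value": 0.67
            },
            {
              "label": "Total AJBR >= 3",
              "severity_rank": 3,
              "value": 1
            }
          ],
          "bucketing_rule": "ajbr"
        }
      ]
    },
    {
      "id": "adherence_qol",
      "name": "adherence_qol",
      "weight_pct": 25,
      "items": [
        {
          "id": "qol_current",
          "text": "How would you assess your patient's current Quality of Life (QoL)?",
          "scale_size": 4,
          "weight_pct": 100,
          "options": [
            {
              "label": "Very satisfactory (5-6 points)",
              "severity_rank": 0,
              "value": 0
            },
            {
              "label": "Moderately satisfactory (7-11 points)",
              "severity_rank": 1,
              "value": 0.33
            },
            {
              "label": "Poorly satisfactory (12-18 points)",
              "severity_rank": 2,
              "value": 0.67
            },
            {
              "label": "Not at all satisfactory (19-25 points)",
              "severity_rank": 3,
              "value": 1
            }
          ],
          "bucketing_rule": "lss_current"
        }
      ]
    }
  ]
}
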