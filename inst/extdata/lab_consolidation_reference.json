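[
  {
    "analyzer": "Alinity c1",
    "general_plan": 3,
    "individualized": {
      "4": [
        "Chloride"
      ]
    },
    "uncovered": [
      "LD",
      "Magnesium",
      "Sodium"
    ]
  },
  {
    "analyzer": "Alinity c2",
    "general_plan": 2,
    "individualized": {
      "5": [
        "Creatinine"
      ],
      "6": [
        "GGT",
        "Total Protein"
      ]
    },
    "uncovered": [
      "Chloride",
      "Sodium"
    ]
  },
  {
    "analyzer": "Alinity c3",
    "general_plan": 3,
    "individualized": {
      "4": [
        "AST",
        "Magnesium"
      ],
      "7": [
        "Chloride",
        "Uric Acid"
      ]
    },
    "uncovered": [
      "LD",
      "Sodium",
      "Total Protein"
    ]
  },
  {
    "analyzer": "Alinity c4",
    "general_plan": 2,
    "individualized": {
      "4": [
        "HDL",
        "Triglyceride"
      ],
      "7": [
        "Magnesium"
      ]
    },
    "uncovered": []
  },
  {
    "analyzer": "Cobas 1",
    "general_plan": 3,
    "individualized": {},
    "uncovered": []
  },
  {
    "analyzer": "Cobas 2",
    "general_plan": 3,
    "individualized": {
      "4": [
        "NT-proBNP"
      ]
    },
    "uncovered": []
  }
]
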