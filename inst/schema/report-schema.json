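{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "chemPercept pipeline report",
  "type": "object",
  "required": ["task", "provenance"],
  "properties": {
    "task": {"enum": ["color", "odor", "crossmodal"]},
    "model": {"enum": ["forest", "dbn", "both"]},
    "featureSet": {"enum": ["all", "rf_selected", "ga_selected", "union"]},
    "nMolecules": {"type": "integer", "minimum": 0},
    "nDescriptors": {"type": "integer", "minimum": 0},
    "nFeaturesUsed": {"type": "integer", "minimum": 0},
    "selectedFeatures": {"type": ["array", "null"], "items": {"type": "string"}},
    "results": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["foldAccuracy", "accuracyMean", "accuracySd",
                     "foldKappa", "kappaMean", "kappaSd", "confusion"],
        "properties": {
          "foldAccuracy": {"type": "array",
                           "items": {"type": "number", "minimum": 0, "maximum": 1}},
          "accuracyMean": {"type": "number", "minimum": 0, "maximum": 1},
          "accuracySd": {"type": "number", "minimum": 0},
          "foldKappa": {"type": "array",
                        "items": {"type": "number", "minimum": -1, "maximum": 1}},
          "kappaMean": {"type": "number", "minimum": -1, "maximum": 1},
          "kappaSd": {"type": "number", "minimum": 0},
          "confusion": {"type": "array"},
          "vocabulary": {"type": "array", "items": {"type": "string"}},
          "skippedFolds": {"type": "array", "items": {"type": "integer"}}
        }
      }
    },
    "chiSquare": {
      "type": "object",
      "properties": {
        "statistic": {"type": "number", "minimum": 0},
        "dof": {"const": 1},
        "pValue": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "nEdges": {"type": "integer", "minimum": 0},
    "sharedDescriptors": {"type": "array", "items": {"type": "string"}},
    "provenance": {
      "type": "object",
      "required": ["configHash", "seed", "packageVersion"],
      "properties": {
        "configHash": {"type": "string"},
        "seed": {"type": "integer"},
        "packageVersion": {"type": "string"}
      }
    }
  }
}
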