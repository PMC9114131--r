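{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "chembias experiment report",
  "type": "object",
  "required": ["target", "scenario", "n_trials", "per_trial_mae",
               "summary", "tests", "binned_mae", "densities"],
  "properties": {
    "target": {"type": "string"},
    "scenario": {"type": "integer", "minimum": 1, "maximum": 4},
    "n_trials": {"type": "integer", "minimum": 1},
    "per_trial_mae": {
      "type": "array",
      "items": {"type": "object",
                "additionalProperties": {"type": "number"}}
    },
    "summary": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["method", "mean_mae", "sd_mae"],
        "properties": {
          "method": {"enum": ["baseline", "ips", "cfr"]},
          "mean_mae": {"type": "number"},
          "sd_mae": {"type": "number"}
        }
      }
    },
    "tests": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["p", "stars"],
        "properties": {
          "t": {"type": ["number", "null"]},
          "p": {"type": "number", "minimum": 0, "maximum": 1},
          "stars": {"enum": ["", "*", "**"]}
        }
      }
    },
    "binned_mae": {
      "type": "object",
      "additionalProperties": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["bin_low", "bin_high", "mid", "n"],
          "properties": {
            "bin_low": {"type": "number"},
            "bin_high": {"type": "number"},
            "mid": {"type": "number"},
            "n": {"type": "integer"},
            "mae": {"type": ["number", "null"]}
          }
        }
      }
    },
    "densities": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["bin_low", "bin_high", "mid",
                     "train_density", "test_density"]
      }
    },
    "failures": {"type": "array", "items": {"type": "string"}}
  }
}
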