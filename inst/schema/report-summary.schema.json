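{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "defscreen report summary",
  "type": "object",
  "required": [
    "seed", "alpha", "min_total", "n_deficiencies", "n_crosses",
    "hi_counts", "minimal_counts", "component_counts", "comparisons",
    "paired_tests", "anova", "interaction_cells"
  ],
  "properties": {
    "seed": {"type": "integer"},
    "alpha": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "min_total": {"type": "integer", "minimum": 1},
    "n_deficiencies": {"type": "integer", "minimum": 0},
    "n_crosses": {"type": "integer", "minimum": 0},
    "hi_counts": {"type": "object"},
    "minimal_counts": {"type": "object"},
    "component_counts": {"type": "object"},
    "comparisons": {"type": ["object", "array"]},
    "paired_tests": {"type": ["object", "array", "null"]},
    "anova": {"type": ["object", "null"]},
    "interaction_cells": {"type": ["object", "null"]}
  }
}
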