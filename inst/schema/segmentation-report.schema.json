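{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "foadpc-segmentation-report-v1",
  "title": "foadpc segmentation report",
  "type": "object",
  "required": ["schema", "method", "k", "effective_k", "entropy_bits",
               "sec", "evaluations", "cluster_mean_gray", "trace"],
  "properties": {
    "schema": {"const": "foadpc-segmentation-report-v1"},
    "method": {"enum": ["foa", "ga", "grid", "kmeans"]},
    "seed": {"type": ["integer", "null"]},
    "d_c": {"type": ["number", "null"], "minimum": 1, "maximum": 10},
    "k": {"type": "integer", "minimum": 2},
    "effective_k": {"type": "integer", "minimum": 1},
    "entropy_bits": {"type": "number", "minimum": 0},
    "sec": {"type": "number", "minimum": 0},
    "evaluations": {"type": "integer", "minimum": 0},
    "centers": {"type": "array", "items": {"type": "integer", "minimum": 0, "maximum": 255}},
    "cluster_mean_gray": {"type": "array", "items": {"type": "number", "minimum": 0, "maximum": 255}},
    "trace": {"type": "array", "items": {"type": "number"}}
  },
  "additionalProperties": false
}
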