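{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "isoneo pipeline report",
  "description": "Shape of report.json written by run_pipeline()/write_report().",
  "type": "object",
  "required": [
    "tool", "version", "seed", "config", "model_config", "feature_config",
    "scoring_mode", "lstv_table", "class_counts", "stage_counts",
    "binder_counts", "candidates", "binders", "timestamp"
  ],
  "properties": {
    "tool": { "type": "string", "const": "isoneo" },
    "version": { "type": "string" },
    "seed": { "type": "integer" },
    "config": { "type": "object" },
    "model_config": { "type": "object" },
    "feature_config": { "type": "object" },
    "scoring_mode": { "enum": ["model", "rank_baseline"] },
    "lstv_table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "chrom", "strand", "start", "end",
                     "primary_class", "support"]
      }
    },
    "class_counts": {
      "type": "object",
      "required": ["intergenic", "alt5", "alt3", "intron_retention",
                   "exon_skipping", "mutually_exclusive_exons",
                   "other_novel"]
    },
    "stage_counts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["stage", "provenance", "count"]
      }
    },
    "binder_counts": {
      "type": "object",
      "required": ["I", "II"]
    },
    "candidates": { "type": "array" },
    "binders": { "type": "array" },
    "dropped": { "type": ["array", "null"] },
    "timestamp": { "type": "string" }
  }
}
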