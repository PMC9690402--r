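{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ctscreen structured report",
  "type": "object",
  "required": ["meta", "sections", "provenance"],
  "properties": {
    "meta": {"type": "object"},
    "sections": {
      "type": "object",
      "minProperties": 1,
      "additionalProperties": {
        "type": "object",
        "required": ["title", "results", "conclusion"],
        "properties": {
          "title": {"type": "string"},
          "conclusion": {"type": "string"},
          "results": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["name", "units", "status"],
              "properties": {
                "name": {"type": "string"},
                "value": {"type": ["number", "null"]},
                "units": {"type": "string"},
                "status": {
                  "enum": ["green", "yellow", "red", "not_evaluated"]
                },
                "category_label": {"type": "string"},
                "recommendation": {"type": "string"},
                "provenance": {"type": "object"}
              }
            }
          }
        }
      }
    },
    "thumbnails": {"type": "array", "items": {"type": "string"}},
    "provenance": {"type": "object"}
  }
}
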