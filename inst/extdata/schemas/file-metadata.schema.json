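{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/msgroupr/file-metadata.schema.json",
  "title": "msgroupr per-file acquisition metadata",
  "description": "One acquisition file's metadata: file-specific header fields plus a list of per-instrument parameter trees. Parameter trees are nested objects whose leaves are strings, numbers, booleans or null; sibling keys must be unique (duplicate keys are rejected by the reader).",
  "type": "object",
  "required": ["FileName", "Instruments"],
  "properties": {
    "FileName": {"type": "string", "minLength": 1},
    "AcquiredDate": {
      "type": ["string", "null"],
      "description": "ISO-8601 timestamp or null"
    },
    "SampleInfo": {
      "type": "object",
      "additionalProperties": {"type": "string"}
    },
    "Instruments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["Model", "ModuleType"],
        "properties": {
          "Model": {"type": "string", "minLength": 1},
          "ModuleType": {"enum": ["MS", "LC", "OTHER"]},
          "MethodText": {"type": ["string", "null"]},
          "Parameters": {"$ref": "#/definitions/parameterTree"}
        }
      }
    }
  },
  "definitions": {
    "parameterTree": {
      "type": "object",
      "additionalProperties": {
        "oneOf": [
          {"type": ["string", "number", "boolean", "null"]},
          {"$ref": "#/definitions/parameterTree"}
        ]
      }
    }
  }
}
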