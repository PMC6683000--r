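{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/msgroupr/grouped-collection.schema.json",
  "title": "msgroupr grouped parameter collection",
  "description": "The reduced representation of a collection: the minimal set of parameter groups, each linking one shared parameter tree to the member file names. Group ids run 1..G in order; file-name lists are sorted and disjoint across groups. Files that failed to read are listed under Failed, never silently dropped.",
  "type": "object",
  "required": ["Version", "Groups"],
  "properties": {
    "Version": {"type": "string"},
    "Groups": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["GroupId", "FileNames", "SharedParameters"],
        "properties": {
          "GroupId": {"type": "integer", "minimum": 1},
          "FileNames": {
            "type": "array",
            "minItems": 1,
            "items": {"type": "string"}
          },
          "SharedParameters": {"$ref": "file-metadata.schema.json#/definitions/parameterTree"}
        }
      }
    },
    "Failed": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["FileName", "Error"],
        "properties": {
          "FileName": {"type": "string"},
          "Error": {"type": "string"}
        }
      }
    }
  }
}
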