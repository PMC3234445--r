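{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "morphokey-kb-1.schema.json",
  "title": "morphokey knowledge base interchange format, version morphokey-kb/1",
  "type": "object",
  "required": ["format", "descriptors", "taxa", "descriptions"],
  "properties": {
    "format": { "const": "morphokey-kb/1" },
    "metadata": {
      "type": "object",
      "properties": {
        "name": { "type": "string" },
        "version": { "type": "string" },
        "license": { "type": "string" }
      }
    },
    "groups": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "label": { "type": "string" }
        }
      }
    },
    "descriptors": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "label": { "type": "string" },
          "kind": { "enum": ["categorical", "numeric"] },
          "group": { "type": "string" },
          "unit": { "type": "string" },
          "taxonomic_value": { "type": "boolean" },
          "states": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["id"],
              "properties": {
                "id": { "type": "string", "minLength": 1 },
                "label": { "type": "string" },
                "definition": { "type": "string" }
              }
            }
          }
        }
      }
    },
    "dependencies": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["child", "parent", "enabling_states"],
        "properties": {
          "child": { "type": "string" },
          "parent": { "type": "string" },
          "enabling_states": {
            "type": "array",
            "items": { "type": "string" },
            "minItems": 1
          }
        }
      }
    },
    "taxa": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": { "type": "string", "minLength": 1 },
          "name": { "type": "string" },
          "notes": { "type": "string" },
          "classification": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["rank", "name"],
              "properties": {
                "rank": { "type": "string" },
                "name": { "type": "string" }
              }
            }
          }
        }
      }
    },
    "descriptions": {
      "type": "object",
      "description": "taxon id -> descriptor id -> cell; unknown cells are omitted",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {
          "oneOf": [
            { "const": "?" },
            { "const": "-" },
            {
              "type": "object",
              "required": ["states"],
              "properties": {
                "states": {
                  "type": "array",
                  "items": { "type": "string" },
                  "minItems": 1
                }
              }
            },
            {
              "type": "object",
              "required": ["interval"],
              "properties": {
                "interval": {
                  "type": "array",
                  "items": { "type": "number" },
                  "minItems": 2,
                  "maxItems": 2
                }
              }
            }
          ]
        }
      }
    }
  }
}
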