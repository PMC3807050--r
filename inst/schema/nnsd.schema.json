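{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/nnsd.schema.json",
  "title": "NNSD: Neural Network Structure Description",
  "description": "JSON-dialect serialization of a Neural Schematic model: populations and projections annotated with cortical layers, areas, non-cortical regions, and functional units.",
  "type": "object",
  "required": ["format_version"],
  "properties": {
    "format_version": { "type": "string" },
    "metadata": { "type": "object" },
    "regions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "properties": {
          "id": { "$ref": "#/definitions/identifier" },
          "kind": { "enum": ["area", "ncr"] },
          "name": { "type": "string" },
          "display_order": { "type": "integer" }
        }
      }
    },
    "layers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "area"],
        "properties": {
          "id": { "$ref": "#/definitions/identifier" },
          "name": { "enum": ["I", "II", "III", "IV", "V", "VI"] },
          "area": { "$ref": "#/definitions/identifier" }
        }
      }
    },
    "populations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "label"],
        "properties": {
          "id": { "$ref": "#/definitions/identifier" },
          "label": {
            "type": "object",
            "minProperties": 1,
            "properties": {
              "ephys": { "$ref": "#/definitions/class_token" },
              "morph": { "$ref": "#/definitions/class_token" }
            }
          },
          "layer": { "$ref": "#/definitions/identifier" },
          "region": { "$ref": "#/definitions/identifier" },
          "extra": { "type": "object" }
        }
      }
    },
    "projections": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "source", "target", "excitation"],
        "properties": {
          "id": { "$ref": "#/definitions/identifier" },
          "source": { "$ref": "#/definitions/endpoint" },
          "target": { "$ref": "#/definitions/endpoint" },
          "excitation": { "enum": ["excitatory", "inhibitory"] },
          "density": { "type": "number", "minimum": 0, "maximum": 1 },
          "density_percent": { "type": "number", "minimum": 0, "maximum": 100 },
          "extra": { "type": "object" }
        }
      }
    },
    "units": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "members"],
        "properties": {
          "id": { "$ref": "#/definitions/identifier" },
          "name": { "type": "string" },
          "members": {
            "type": "array",
            "items": { "$ref": "#/definitions/identifier" },
            "uniqueItems": true
          }
        }
      }
    }
  },
  "definitions": {
    "identifier": { "type": "string", "minLength": 1, "not": { "const": "EXTERNAL" } },
    "endpoint": { "type": "string", "minLength": 1 },
    "class_token": { "type": "string", "pattern": "^[A-Z0-9]+$" }
  }
}
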