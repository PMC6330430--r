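{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "hcscreen-pedigree-v1",
  "title": "Pedigree interchange document",
  "type": "object",
  "required": ["proband"],
  "additionalProperties": false,
  "properties": {
    "id": {"type": "string"},
    "proband": {"$ref": "#/$defs/member"},
    "members": {"type": "array", "items": {"$ref": "#/$defs/member"}},
    "ethnicities": {
      "type": "array",
      "items": {"enum": ["African American", "Ashkenazi Jewish", "Asian",
                         "Caucasian", "Hispanic", "Native American",
                         "Unknown"]}
    },
    "mutations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene_group"],
        "additionalProperties": false,
        "properties": {
          "gene_group": {"enum": ["BRCA1_BRCA2", "LYNCH", "APC_MUTYH"]},
          "carrier": {"type": "string"}
        }
      }
    },
    "family_sizes": {"type": "object"}
  },
  "$defs": {
    "age": {
      "type": "object",
      "required": ["kind"],
      "additionalProperties": false,
      "properties": {
        "kind": {"enum": ["EXACT", "EARLY_DECADE", "LATE_DECADE", "DECADE",
                          "UNKNOWN"]},
        "value": {"type": "integer", "minimum": 0, "maximum": 120}
      }
    },
    "diagnosis": {
      "type": "object",
      "required": ["cancer_type"],
      "additionalProperties": false,
      "properties": {
        "cancer_type": {"type": "string"},
        "age": {"$ref": "#/$defs/age"},
        "qualifiers": {
          "type": "array",
          "items": {"enum": ["DCIS", "TRIPLE_NEGATIVE", "GLEASON_GT7",
                             "SYNCHRONOUS", "METACHRONOUS"]}
        },
        "primary_index": {"type": "integer", "minimum": 1}
      }
    },
    "member": {
      "type": "object",
      "required": ["relationship"],
      "additionalProperties": false,
      "properties": {
        "relationship": {"type": "string"},
        "sex": {"enum": ["female", "male", "unknown"]},
        "diagnoses": {"type": "array", "items": {"$ref": "#/$defs/diagnosis"}},
        "polyp_count": {"type": "integer", "minimum": 0},
        "deceased": {"type": "boolean"}
      }
    }
  }
}
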