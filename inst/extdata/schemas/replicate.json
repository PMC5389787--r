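{
    "title": "Replicate",
    "collection": "replicates",
    "schema_version": 1,
    "identifyingProperties": ["uuid"],
    "required": [],
    "properties": {
        "experiment": {"linkTo": "experiment"},
        "library": {"linkTo": "library"},
        "biological_replicate_number": {"type": "integer"},
        "technical_replicate_number": {"type": "integer", "default": 1},
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    }
}
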