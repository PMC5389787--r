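{
    "title": "Award",
    "collection": "awards",
    "schema_version": 1,
    "identifyingProperties": ["uuid", "name"],
    "required": ["name"],
    "properties": {
        "name": {
            "type": "string",
            "pattern": "^[A-Za-z0-9_-]+$",
            "uniqueKey": "award:name",
            "comment": "the key from which the canonical path is minted"
        },
        "project": {
            "type": "string",
            "enum": ["ENCODE", "GGR"],
            "default": "ENCODE"
        },
        "title": {"type": "string"},
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    },
    "facets": {
        "project": {"title": "Project"},
        "status": {"title": "Status"}
    }
}
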