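{
    "title": "Lab",
    "collection": "labs",
    "schema_version": 1,
    "identifyingProperties": ["uuid", "name"],
    "required": ["name"],
    "properties": {
        "name": {
            "type": "string",
            "pattern": "^[A-Za-z0-9_-]+$",
            "uniqueKey": "lab:name"
        },
        "title": {"type": "string"},
        "institute": {"type": "string"},
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    },
    "facets": {
        "status": {"title": "Status"}
    }
}
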