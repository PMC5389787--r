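{
    "title": "User",
    "collection": "users",
    "schema_version": 1,
    "identifyingProperties": ["uuid", "email"],
    "required": ["email"],
    "properties": {
        "email": {
            "type": "string",
            "pattern": "^[^@\\s]+@[^@\\s]+$",
            "uniqueKey": "user:email"
        },
        "first_name": {"type": "string"},
        "last_name": {"type": "string"},
        "lab": {"linkTo": "lab"},
        "submits_for": {
            "type": "array",
            "items": {"linkTo": "lab"}
        },
        "groups": {
            "type": "array",
            "items": {"type": "string", "enum": ["admin", "consortium"]}
        },
        "project": {
            "type": "string",
            "enum": ["ENCODE", "GGR"],
            "default": "ENCODE"
        },
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    }
}
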