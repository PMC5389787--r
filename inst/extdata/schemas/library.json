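{
    "title": "Library",
    "collection": "libraries",
    "schema_version": 1,
    "identifyingProperties": ["uuid", "accession"],
    "required": [],
    "properties": {
        "accession": {
            "type": "string",
            "pattern": "^TSTLB[0-9]{3}[A-Z]{3}$",
            "uniqueKey": "accession",
            "accessionType": "LB"
        },
        "biosample": {"linkTo": "biosample"},
        "nucleic_acid_term_name": {
            "type": "string",
            "enum": ["DNA", "RNA"]
        },
        "lab": {"linkTo": "lab"},
        "award": {"linkTo": "award"},
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    }
}
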