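{
    "title": "Donor",
    "collection": "donors",
    "schema_version": 1,
    "identifyingProperties": ["uuid", "accession"],
    "required": [],
    "properties": {
        "accession": {
            "type": "string",
            "pattern": "^TSTDO[0-9]{3}[A-Z]{3}$",
            "uniqueKey": "accession",
            "accessionType": "DO"
        },
        "organism": {
            "type": "string",
            "enum": ["human", "mouse"]
        },
        "sex": {
            "type": "string",
            "enum": ["male", "female", "unknown"]
        },
        "age": {"type": "string"},
        "lab": {"linkTo": "lab"},
        "award": {"linkTo": "award"},
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    },
    "facets": {
        "organism": {"title": "Organism"},
        "status": {"title": "Status"}
    }
}
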