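{
    "title": "AntibodyLot",
    "collection": "antibody-lots",
    "schema_version": 1,
    "identifyingProperties": ["uuid", "accession"],
    "required": [],
    "properties": {
        "accession": {
            "type": "string",
            "pattern": "^TSTAB[0-9]{3}[A-Z]{3}$",
            "uniqueKey": "accession",
            "accessionType": "AB"
        },
        "target": {"type": "string"},
        "host_organism": {
            "type": "string",
            "enum": ["rabbit", "mouse", "goat"]
        },
        "lot_id": {"type": "string"},
        "lab": {"linkTo": "lab"},
        "award": {"linkTo": "award"},
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    },
    "facets": {
        "host_organism": {"title": "Host organism"},
        "status": {"title": "Status"}
    }
}
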