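{
    "title": "Biosample",
    "collection": "biosamples",
    "schema_version": 2,
    "identifyingProperties": ["uuid", "accession", "aliases"],
    "required": [],
    "properties": {
        "accession": {
            "type": "string",
            "pattern": "^TSTBS[0-9]{3}[A-Z]{3}$",
            "uniqueKey": "accession",
            "accessionType": "BS"
        },
        "aliases": {
            "type": "array",
            "items": {
                "type": "string",
                "pattern": "^[A-Za-z0-9_-]+:[A-Za-z0-9_.-]+$",
                "uniqueKey": "alias"
            }
        },
        "biosample_term_name": {"type": "string"},
        "biosample_term_id": {
            "type": "string",
            "pattern": "^(CL|EFO|UBERON):[0-9]{7}$"
        },
        "organism": {
            "type": "string",
            "enum": ["human", "mouse"]
        },
        "donor": {"linkTo": "donor"},
        "starting_amount": {
            "type": "number",
            "comment": "schema v1 stored this as a string; the 1->2 upgrade coerces it"
        },
        "date_obtained": {"type": "string", "format": "date"},
        "description": {"type": "string"},
        "lab": {"linkTo": "lab"},
        "award": {"linkTo": "award"},
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    },
    "calculatedProperties": ["summary"],
    "facets": {
        "organism": {"title": "Organism"},
        "biosample_term_name": {"title": "Biosample term"},
        "status": {"title": "Status"}
    }
}
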