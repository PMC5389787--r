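{
    "title": "Experiment",
    "collection": "experiments",
    "schema_version": 2,
    "identifyingProperties": ["uuid", "accession", "aliases"],
    "required": [],
    "properties": {
        "accession": {
            "type": "string",
            "pattern": "^TSTSR[0-9]{3}[A-Z]{3}$",
            "uniqueKey": "accession",
            "accessionType": "SR"
        },
        "aliases": {
            "type": "array",
            "items": {
                "type": "string",
                "pattern": "^[A-Za-z0-9_-]+:[A-Za-z0-9_.-]+$",
                "uniqueKey": "alias"
            }
        },
        "assay_term_name": {
            "type": "string",
            "enum": ["ChIP-seq", "RNA-seq", "DNase-seq"]
        },
        "assay_term_id": {
            "type": "string",
            "pattern": "^OBI:[0-9]{7}$"
        },
        "target": {"type": "string"},
        "antibody": {"linkTo": "antibody_lot"},
        "description": {"type": "string"},
        "date_released": {"type": "string", "format": "date"},
        "lab": {"linkTo": "lab"},
        "award": {"linkTo": "award"},
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    },
    "rev": {
        "files": ["file", "dataset"],
        "replicates": ["replicate", "experiment"]
    },
    "facets": {
        "assay_term_name": {"title": "Assay"},
        "status": {"title": "Status"}
    }
}
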