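{
    "title": "File",
    "collection": "files",
    "schema_version": 1,
    "identifyingProperties": ["uuid", "accession"],
    "required": [],
    "properties": {
        "accession": {
            "type": "string",
            "pattern": "^TSTFF[0-9]{3}[A-Z]{3}$",
            "uniqueKey": "accession",
            "accessionType": "FF"
        },
        "dataset": {"linkTo": "experiment"},
        "replicate": {"linkTo": "replicate"},
        "file_format": {
            "type": "string",
            "enum": ["fastq", "bam", "bigWig"]
        },
        "output_type": {
            "type": "string",
            "enum": ["reads", "alignments", "signal"]
        },
        "mapped_read_count": {"type": "integer"},
        "lab": {"linkTo": "lab"},
        "award": {"linkTo": "award"},
        "status": {
            "type": "string",
            "enum": ["in progress", "released", "deleted"],
            "default": "in progress"
        }
    },
    "facets": {
        "file_format": {"title": "File format"},
        "output_type": {"title": "Output type"},
        "status": {"title": "Status"}
    }
}
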