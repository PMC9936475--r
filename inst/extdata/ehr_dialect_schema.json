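{
  "dialect": "ehrcurate OMOP-lite",
  "version": "0.1",
  "conventions": {
    "csv": "RFC-4180, UTF-8, ISO-8601 dates, missing values as empty fields",
    "parquet": "identical schema, one file per table",
    "dates": "day resolution; timestamps truncated on load",
    "intervals": "closed on both ends; a one-day interval has start == end",
    "missing": "encoded by absence (empty field / null), never sentinels"
  },
  "tables": {
    "person": {
      "person_id": "string", "site_id": "string", "birth_year": "integer",
      "sex": "enum(female,male) or missing", "race": "string or missing",
      "ethnicity": "string or missing"
    },
    "visit_occurrence": {
      "visit_id": "string", "person_id": "string", "site_id": "string",
      "visit_kind": "enum(inpatient,emergency,outpatient,other)",
      "start_date": "date", "end_date": "date or missing",
      "discharge_disposition": "string or missing"
    },
    "drug_exposure": {
      "person_id": "string", "site_id": "string", "concept_id": "integer",
      "start_date": "date", "end_date": "date or missing",
      "drug_type_label": "string or missing"
    },
    "measurement": {
      "person_id": "string", "site_id": "string",
      "variable": "enum over the dialect's measurement variables",
      "value": "number (fixed per-variable units)", "date": "date"
    },
    "condition_occurrence": {
      "person_id": "string", "site_id": "string", "concept_id": "integer",
      "date": "date"
    },
    "death": {
      "person_id": "string", "site_id": "string", "death_date": "date"
    },
    "concept": {
      "concept_id": "integer", "concept_name": "string",
      "level": "enum(ingredient,clinical_drug,branded_drug,other)"
    },
    "concept_ancestor": {
      "ancestor_id": "integer", "descendant_id": "integer"
    },
    "site": {
      "site_id": "string",
      "source_cdm": "enum(OMOP,PCORnet,ACT,TriNetX)",
      "max_date_shift_days": "integer >= 0"
    }
  }
}
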