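"source_code","source_description","source_context","target_concept_id","mapping_status"
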