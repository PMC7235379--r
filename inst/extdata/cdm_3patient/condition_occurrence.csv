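person_id,condition_concept_id,condition_start_date
1,374915,2010-01-01
2,4055361,2010-06-01
3,4179936,2010-02-01
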