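person_id,sex,birth_date
1,male,2000-05-10
2,female,1990-01-01
3,male,2005-03-15
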