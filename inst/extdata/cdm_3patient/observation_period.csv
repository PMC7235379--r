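person_id,start_date,end_date
1,2009-06-01,2012-06-01
2,2009-01-01,2013-01-01
3,2009-06-01,2012-12-31
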