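person_id,drug_concept_id,exposure_date
1,7001,2010-01-01
1,7001,2010-03-02
1,7001,2010-05-31
1,7001,2010-09-28
1,7001,2011-01-26
1,7001,2011-05-26
1,7001,2011-09-03
1,7002,2010-07-20
1,7002,2011-03-07
1,7002,2011-10-13
2,7001,2010-06-01
2,7001,2010-10-29
2,7001,2011-02-26
2,7001,2011-06-26
2,7001,2011-10-24
2,7001,2012-02-01
3,7004,2010-02-01
3,7004,2010-07-01
3,7004,2011-03-08
3,7004,2011-08-05
3,7004,2012-01-02
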