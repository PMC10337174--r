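patient_id,death_date,cause_rank,icd10
p01,2015-02-10,0,J841
p01,2015-02-10,1,I509
p02,2016-08-21,0,J189
p02,2016-08-21,1,J849
p03,2014-12-01,0,C349
p05,2017-03-30,0,I219
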