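patient_id,admission_date,discharge_date,episode_index,position,icd10
p01,2012-06-01,2012-06-09,1,1,J841
p01,2012-06-01,2012-06-09,1,2,I509
p02,2014-03-11,2014-03-20,1,1,J189
p02,2014-03-11,2014-03-20,1,2,I509
p02,2014-03-11,2014-03-20,1,3,J841
p05,2011-11-02,2011-11-05,1,1,J848
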