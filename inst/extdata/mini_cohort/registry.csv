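patient_id,birth_date,sex,registration_start,last_collection_date,transfer_out_date,death_date
p01,1942-03-15,male,2001-05-01,2019-06-30,,2015-02-10
p02,1950-11-02,female,1999-01-01,2019-06-30,,2016-08-21
p03,1938-07-29,male,2005-09-12,2019-06-30,,2014-12-01
p04,1947-01-20,female,2003-02-28,2019-06-30,,
p05,1944-06-05,male,2000-10-15,2019-06-30,,2017-03-30
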