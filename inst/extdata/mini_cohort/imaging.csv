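patient_id,event_date,modality,body_region
p01,2011-12-15,CT,thorax
p02,2013-01-20,XRAY,thorax
p03,2013-04-01,CT,thorax
p05,2011-10-01,CT,other
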