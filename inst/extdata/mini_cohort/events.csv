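patient_id,event_date,code,term
p01,2010-04-12,PF-PULMFIB,pulmonary fibrosis
p01,2011-01-05,IPF-IPF,idiopathic pulmonary fibrosis
p01,2009-06-01,SMOK-EX,ex smoker
p02,2012-09-30,PF-DIFFUSE,diffuse pulmonary fibrosis
p02,2010-02-14,SMOK-CURRENT,current smoker
p02,2011-07-07,COM-COPD,chronic obstructive pulmonary disease
p03,2013-05-22,IPF-CFA,cryptogenic fibrosing alveolitis
p03,2012-01-10,ILD-SARC,pulmonary sarcoidosis
p05,2009-03-03,SMOK-NEVER,never smoked
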