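code	term	system	rating
IPF-IPF	idiopathic pulmonary fibrosis	SNOMED_LIKE	yes
IPF-IFA	idiopathic fibrosing alveolitis	SNOMED_LIKE	yes
IPF-CFA	cryptogenic fibrosing alveolitis	SNOMED_LIKE	yes
PF-PULMFIB	pulmonary fibrosis	SNOMED_LIKE	maybe
PF-DIFFUSE	diffuse pulmonary fibrosis	SNOMED_LIKE	maybe
PF-FIBALV	fibrosing alveolitis	SNOMED_LIKE	maybe
PF-HONEY	honeycomb lung	SNOMED_LIKE	maybe
PF-RADIATION	radiation fibrosis of lung	SNOMED_LIKE	no
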