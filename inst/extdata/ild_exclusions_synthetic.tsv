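code	term	system	rating
ILD-CTD	connective tissue disease associated ILD	SNOMED_LIKE	yes
ILD-SARC	pulmonary sarcoidosis	SNOMED_LIKE	yes
ILD-EAA	extrinsic allergic alveolitis	SNOMED_LIKE	yes
ILD-DRUG	drug-induced interstitial lung disease	SNOMED_LIKE	yes
ILD-ASB	asbestosis	SNOMED_LIKE	yes
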