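token	class
antioxidant	AOX
anti-oxidant	AOX
aox	AOX
antiinflammatory	AINF
anti-inflammatory	AINF
ainf	AINF
antiaging	AAG
anti-aging	AAG
antiageing	AAG
aag	AAG
antisenescence	ASEN
anti-senescence	ASEN
asen	ASEN
senolytic	ASEN
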