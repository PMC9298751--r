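condition	icd10_prefix
hypertension	I10
diabetes	E10
diabetes	E11
diabetes	E14
dyslipidemia	E78.0
dyslipidemia	E78.1
dyslipidemia	E78.2
dyslipidemia	E78.3
dyslipidemia	E78.4
dyslipidemia	E78.5
heart_failure	I50.0
heart_failure	I50.1
heart_failure	I50.9
sepsis	A40
sepsis	A41
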