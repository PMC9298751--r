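icd10_prefix	disease_group
B15	infectious hepatitis
B16	infectious hepatitis
B17	infectious hepatitis
B18	infectious hepatitis
B19	infectious hepatitis
K70	alcoholic liver disease
K71	toxic liver disease
K72	hepatic failure
K73	chronic hepatitis
K74	fibrosis and cirrhosis
K75	other inflammatory liver disease
K76	other liver disease incl. NAFLD
K77	liver disorders in diseases classified elsewhere
C22	malignant neoplasm of liver
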