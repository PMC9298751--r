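atc5	substance
A05BA08	glycyrrhizic acid
V03AB32	glutathione
A06AD11	lactulose
A05BA01	L-arginine glutamate
G04BX16	tiopronin
A06AD12	lactitol
A07AA11	rifaximin
A05AA02	ursodeoxycholic acid
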