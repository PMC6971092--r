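# pKa sets used for net charge / isoelectric point
set	group	pka
lehninger	nterm	9.69
lehninger	cterm	2.34
lehninger	D	3.65
lehninger	E	4.25
lehninger	C	8.33
lehninger	Y	10.07
lehninger	H	6.00
lehninger	K	10.53
lehninger	R	12.48
emboss	nterm	8.6
emboss	cterm	3.6
emboss	D	3.9
emboss	E	4.1
emboss	C	8.5
emboss	Y	10.1
emboss	H	6.5
emboss	K	10.8
emboss	R	12.5
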