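sample_id	origin	variety	m1	m2	m3	m4	m5	m6	m7	m8	m9	m10	m11	judgment_value
Daewon	domestic	Daewon	1	1	1	0	1	0	0	1	0	1	1	1687
Taekwang	domestic	Taekwang	1	0	0	0	1	0	0	0	1	1	0	785
Pungsannamul	domestic	Pungsannamul	1	1	1	1	1	1	0	1	0	0	1	1215
Seonyu	domestic	Seonyu	1	0	0	1	1	0	0	1	0	1	0	665
Daepung	domestic	Daepung	1	1	1	1	0	1	1	0	0	1	0	623
Sinhwa	domestic	Sinhwa	1	0	1	1	1	1	0	1	0	0	0	189
Hwangkeum	domestic	Hwangkeum	1	1	1	0	1	1	0	1	0	1	1	1719
Nampung	domestic	Nampung	1	1	0	1	1	1	0	0	1	1	0	827
Cheonsang	domestic	Cheonsang	1	1	0	0	1	1	0	0	1	1	0	819
Uram	domestic	Uram	1	1	0	1	1	0	0	0	0	1	1	1563
Hwangkeumol	domestic	Hwangkeumol	1	0	0	1	1	0	0	1	0	1	0	665
Saedanbaek	domestic	Saedanbaek	1	0	1	1	0	0	0	1	0	1	1	1677
Pungwon	domestic	Pungwon	1	0	1	0	1	1	1	0	1	1	1	1909
Cheongja1	domestic	Cheongja1	1	1	0	0	1	1	0	1	0	0	1	1203
Cheongja3	domestic	Cheongja3	1	1	0	0	1	0	0	0	1	1	0	787
Williams82	imported	Williams82	1	1	1	1	1	1	1	1	1	1	1	2047
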