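# Meeker & Escobar running times of 30 devices (published benchmark table).
275
13
147
23
181
30
65
10
300
173
106
300
300
212
300
300
300
2
261
293
88
247
28
143
300
23
300
80
245
266
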