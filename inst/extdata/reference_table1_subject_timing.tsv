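subject	positive_peak_s	negative_peak_s	voxels_analyzed
1	3.78	11.61	5215
2	3.63	12.79	7460
3	5.63	16.41	7282
4	3.91	14.09	8425
5	3.08	9.18	9301
6	4.88	15.13	6864
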