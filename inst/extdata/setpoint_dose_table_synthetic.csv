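"ca_mM","n_total","n_maximal"
0.5,687,0
0.75,654,2
1,712,5
1.25,698,13
2,675,71
3,641,223
5,722,495
10,660,523
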