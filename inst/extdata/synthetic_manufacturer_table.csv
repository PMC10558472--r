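power_W,duration_min,length_mm,diameter_mm
80,3,38,28.8
80,5,42,34
80,8,46,38.9
80,10,50,41.6
90,3,38,30
90,5,42,34.2
90,8,46,38.9
90,10,50,42
100,3,38,30.3
100,5,42,34.2
100,8,46,39.7
100,10,50,42.2
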