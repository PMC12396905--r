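polar_deg,azimuth_deg,thickness_mm
15,0,1.4
15,120,1.4
15,240,1.4
45,0,1.7
45,90,1.6
45,180,1.5
45,270,1.5
95,0,2.6
95,45,2.5
95,90,2.3
95,180,1.8
95,270,1.9
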