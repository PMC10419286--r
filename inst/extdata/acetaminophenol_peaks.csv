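position,name
390.9,ring_def
465.1,ring_def
504.0,ring_def
651.6,ring_breath
710.8,CH_oop
797.2,CH_oop
834.5,ring
857.9,ring
968.7,CH3_rock
1105.5,ring_CH
1168.5,CH_bend
1236.8,C_N
1278.5,amide_III
1323.9,CH_bend
1371.5,CH3_def
1561.6,ring_stretch
1648.4,amide_I
2931.1,CH3_stretch
3064.6,ring_CH_stretch
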