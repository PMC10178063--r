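model,location,region_kind,wss_low_pa,wss_high_pa,velocity_low_ms,velocity_high_ms
1C,Junction 1,junction,0.420,1.260,0.055,0.11
1C,Junction 2,junction,0.840,2.520,0.055,0.22
1C,Wall 1,wall,0.840,1.680,0.11,0.165
1C,Wall 2,wall,0.0000055,0.420,0.00,0.055
1C,Wall 3,wall,0.840,2.10,0.055,0.22
1D,Junction 1,junction,0.420,1.260,0.055,0.165
1D,Junction 2,junction,0.840,1.680,0.055,0.11
1D,Junction 3,junction,0.840,2.10,0.11,0.165
1D,Wall 1,wall,0.420,1.680,0.11,0.165
1D,Wall 2,wall,0.420,0.840,0.00,0.055
1D,Wall 3,wall,0.0000055,1.680,0.055,0.165
1D,Wall 4,wall,0.420,1.260,0.055,0.11
1E,Junction 1,junction,0.420,1.260,0.055,0.165
1E,Junction 2,junction,0.840,1.680,0.00,0.055
1E,Junction 3,junction,0.840,2.10,0.055,0.11
1E,Junction 4,junction,0.420,1.680,0.055,0.11
1E,Wall 1,wall,0.840,1.260,0.11,0.165
1E,Wall 2,wall,0.0000055,0.420,0.00,0.055
1E,Wall 3,wall,0.840,2.10,0.11,0.22
1E,Wall 4,wall,0.0000055,0.420,0.00,0.055
1E,Wall 5,wall,0.840,1.680,0.11,0.165
1F,Junction 1,junction,0.420,1.260,0.00,0.055
1F,Junction 2,junction,0.840,2.10,0.11,0.165
1F,Junction 3,junction,1.260,4.20,0.11,0.165
1F,Wall 1,wall,0.840,1.260,0.11,0.165
1F,Wall 2,wall,0.0000055,0.420,0.00,0.055
1F,Wall 3,wall,0.840,2.950,0.11,0.22
1F,Wall 4,wall,0.840,1.680,0.11,0.165
1G,Junction 1,junction,0.420,1.680,0.00,0.055
1G,Junction 2,junction,0.840,4.20,0.055,0.11
1G,Junction 3,junction,0.840,4.20,0.165,0.22
1G,Junction 4,junction,1.260,4.20,0.11,0.22
1G,Wall 1,wall,0.840,1.680,0.11,0.22
1G,Wall 2,wall,0.0000055,0.420,0.00,0.055
1G,Wall 3,wall,0.840,4.20,0.11,0.22
1G,Wall 4,wall,1.680,2.940,0.165,0.22
1G,Wall 5,wall,0.840,1.680,0.11,0.165
2A,Junction 1,junction,0.420,1.260,0.055,0.11
2A,Junction 2,junction,0.840,2.10,0.055,0.11
2A,Junction 3,junction,0.420,1.260,0.055,0.11
2A,Junction 4,junction,0.840,2.520,0.055,0.11
2A,Junction 5,junction,0.420,1.260,0.00,0.11
2A,Junction 6,junction,0.840,2.10,0.00,0.11
2A,Wall 1,wall,0.840,1.260,0.11,0.165
2A,Wall 2,wall,0.0000055,0.420,0.00,0.055
2A,Wall 3,wall,0.420,1.680,0.11,0.165
2A,Wall 4,wall,0.0000055,0.420,0.00,0.055
2A,Wall 5,wall,0.0000055,0.420,0.00,0.055
2A,Wall 6,wall,0.840,2.520,0.11,0.22
2B,Junction 1,junction,0.420,1.260,0.055,0.11
2B,Junction 2,junction,0.420,2.10,0.055,0.11
2B,Junction 3,junction,0.420,1.680,0.055,0.11
2B,Junction 4,junction,0.840,2.520,0.055,0.11
2B,Junction 5,junction,0.840,1.260,0.00,0.11
2B,Junction 6,junction,0.840,2.10,0.00,0.11
2B,Wall 1,wall,0.840,1.680,0.11,0.165
2B,Wall 2,wall,0.0000055,0.420,0.00,0.055
2B,Wall 3,wall,0.840,1.680,0.11,0.165
2B,Wall 4,wall,0.0000055,0.420,0.00,0.055
2B,Wall 5,wall,0.0000055,0.420,0.00,0.055
2B,Wall 6,wall,0.840,2.10,0.11,0.22
2C,Junction 1,junction,0.420,1.680,0.055,0.11
2C,Junction 2,junction,0.840,2.520,0.055,0.11
2C,Junction 3,junction,0.840,4.20,0.165,0.22
2C,Junction 4,junction,1.680,3.780,0.165,0.22
2C,Junction 5,junction,2.10,4.20,0.11,0.165
2C,Junction 6,junction,0.840,2.940,0.11,0.165
2C,Wall 1,wall,0.840,1.680,0.11,0.165
2C,Wall 2,wall,0.0000055,0.420,0.00,0.055
2C,Wall 3,wall,0.840,4.20,0.11,0.22
2C,Wall 4,wall,1.680,2.10,0.165,0.22
2C,Wall 5,wall,0.420,0.840,0.055,0.11
2C,Wall 6,wall,0.0000055,1.680,0.055,0.165
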