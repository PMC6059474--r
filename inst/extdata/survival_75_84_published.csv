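group,rs_a,rs_b,css
NH Whites,48.5,48.7,44.8
NH Blacks,39.5,38.2,37.9
NH AI/AN,21.8,35.2,32.2
NH API,42.6,43.1,43.7
Hispanics,51.3,41.4,43.0
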