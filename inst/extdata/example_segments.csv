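segment,name,t2_ms
1,basal anterior,50.1
2,basal anteroseptal,51.6
3,basal inferoseptal,47.6
4,basal inferior,47.7
5,basal inferolateral,45.0
6,basal anterolateral,52.9
7,mid anterior,55.5
8,mid anteroseptal,57.1
9,mid inferoseptal,50.2
10,mid inferior,50.2
11,mid inferolateral,54.6
12,mid anterolateral,49.2
13,apical anterior,54.7
14,apical septal,54.8
15,apical inferior,49.4
16,apical lateral,54.9
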