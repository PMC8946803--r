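patient,sample,organ
1,A,ovarian
1,B,ovarian
1,C,ovarian
1,D,omentum
2,A,mesenterium
3,A,omentum
3,B,ovarian
4,A,omentum
4,B,omentum
4,C,intestines
6,A,ovarian
6,B,ovarian
6,C,intestines
6,D,omentum
6,E,omentum
7,A,omentum
7,B,ovarian
7,C,ovarian
8,A,omentum
8,B,ovarian
9,A,ovarian
9,B,ovarian
10,A,ovarian
10,B,omentum
10,C,ovarian
11,A,omentum
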