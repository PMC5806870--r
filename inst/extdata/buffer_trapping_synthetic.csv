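width,te,source
3,0.55,synthetic-filter-strip-A
5,0.62,synthetic-filter-strip-A
6,0.70,synthetic-filter-strip-B
9,0.80,synthetic-filter-strip-B
10,0.85,synthetic-filter-strip-C
15,0.90,synthetic-filter-strip-A
20,0.95,synthetic-filter-strip-C
25,0.93,synthetic-filter-strip-B
30,0.97,synthetic-filter-strip-C
45,0.99,synthetic-filter-strip-A
60,0.995,synthetic-filter-strip-B
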