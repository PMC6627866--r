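step,added_n,free_n
1,194,194
2,381,356
3,146,177
4,565,569
5,20,20
6,58,58
7,2,2
8,34,28
9,74,70
10,9,9
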