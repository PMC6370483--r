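replicate	seed	recall
1	20001	1
2	20002	1
3	20003	1
4	20004	1
5	20005	1
6	20006	1
7	20007	1
8	20008	1
9	20009	1
10	20010	1
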