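archetype	class	D-2	D0	D3	D9
1	stable_low	1	1	1	1
2	stable_low	4	4	4	4
3	stable_high	30	30	30	30
4	stable_high	120	120	120	120
5	induced_D0	0	20	20	20
6	induced_D3	0	0	20	20
7	induced_D9	0	0	0	20
8	expressed_up	10	20	45	90
9	repressed_D0	20	0	0	0
10	repressed_D3	20	20	0	0
11	repressed_D9	20	20	20	0
12	transient_up_D0	2	25	2	2
13	transient_up_D3	2	2	25	2
14	transient_down_mid	25	2	2	25
15	transient_down_D3	25	25	2	25
16	transient_down_D0	25	2	25	25
17	transient_up_mid	2	25	25	2
18	oscillating_down	25	2	25	2
19	oscillating_up	2	25	2	25
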