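fragment_id	primer_combo	size_bp	female__r1	female__r2	male__r1	male__r2	hybrid__r1	hybrid__r2
frag_00001	E4+M8	156	0	0	0	1	0	0
frag_00002	E6+M7	199	0	0	0	0	0	0
frag_00003	E2+M6	397	1	1	1	1	1	1
frag_00004	E2+M6	190	0	0	1	1	0	0
frag_00005	E8+M3	368	1	1	0	0	0	0
frag_00006	E2+M5	280	1	1	0	0	1	1
frag_00007	E2+M6	153	0	0	1	1	1	1
frag_00008	E4+M8	438	1	0	1	1	1	1
frag_00009	E8+M3	387	1	1	0	0	0	0
frag_00010	E7+M3	307	0	0	1	1	1	0
frag_00011	E8+M3	345	1	1	0	0	0	0
frag_00012	E4+M8	159	0	0	1	1	0	0
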