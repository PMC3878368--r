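fragment_id	female__H	female__M	male__H	male__M	hybrid__H	hybrid__M
site_00001	1	0	1	0	1	0
site_00002	1	0	1	1	1	0
site_00003	1	1	0	0	1	1
site_00004	1	0	1	0	1	0
site_00005	0	1	1	1	0	1
site_00006	0	1	0	1	0	1
site_00007	0	1	1	1	1	1
site_00008	1	1	1	0	1	0
site_00009	0	1	1	1	1	1
site_00010	0	1	1	0	1	0
site_00011	0	1	0	1	1	1
site_00012	0	1	1	0	0	1
site_00013	1	0	1	1	1	0
site_00014	1	1	0	1	0	1
site_00015	0	1	1	1	0	1
site_00016	1	0	1	0	1	0
site_00017	0	0	1	1	1	1
site_00018	1	1	1	1	1	1
site_00019	0	1	1	0	0	1
site_00020	0	1	0	1	1	1
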