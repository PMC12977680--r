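gene_id	wing_disc	fat_body	muscle
g00001	1900	796	547
g00002	492	1740	577
g00003	640	214	1892
g00004	1828	772	729
g00005	766	1035	406
g00006	342	434	1461
g00007	3471	546	475
g00008	250	1604	299
g00009	423	431	2547
g00010	1844	426	998
g00011	279	1603	434
g00012	365	510	2553
g00013	1951	465	283
g00014	317	2846	591
g00015	659	360	1189
g00016	2185	507	192
g00017	392	2314	402
g00018	364	714	2253
g00019	1695	312	416
g00020	339	2348	270
g00021	475	231	3872
g00022	1842	435	600
g00023	947	3154	384
g00024	430	517	3025
g00025	1845	696	349
g00026	298	1557	240
g00027	299	252	1089
g00028	2299	468	336
g00029	477	1359	500
g00030	1010	398	1543
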