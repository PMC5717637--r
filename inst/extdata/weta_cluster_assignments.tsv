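sample	sex	age	haplogroup	cluster_pc12	cluster_pc15
Hc-Ran-618	female	juvenile	2	2	1
Hc-Ran-624	female	adult	2	2	1
Hc-Ran-619	male	adult	2	1	1
Hc-Ran-620	female	adult	2	2	1
Hc-Ran-1308	female	adult	2	1	2
Hc-Ran-1310	male	juvenile	2	1	1
Hc-Ran-1311	female	juvenile	2	1	1
Hc-Ran-1312	female	juvenile	2	1	1
Hc-Ran-1328	female	adult	2	1	1
Hc-Ran-1315	female	adult	2	2	1
Hc-Ran-622	female	adult	2	2	1
Hc-Ran-1316	male	juvenile	2	3	2
Hc-Ran-1317	male	juvenile	2	1	1
Hc-Ran-1318	male	juvenile	2	1	1
Hc-Ran-1319	male	juvenile	2	1	1
Hc-Ran-1320	female	juvenile	2	1	1
Hc-Ran-1321	female	juvenile	2	1	1
Hc-Ran-1322	female	juvenile	2	1	2
Hc-Ran-1323	male	juvenile	2	1	2
Hc-Ran-1324	female	juvenile	2	1	1
Hc-Ran-1325	female	juvenile	2	1	2
Hc-Ran-1326	male	juvenile	2	1	1
Hc-Ran-1327	male	juvenile	2	1	1
Hc-Ran-NN	female	juvenile	3	1	2
Hc-Ran-621	female	adult	3	1	1
Hc-Ran-1309	male	adult	3	1	1
Hc-Ran-1313	female	juvenile	3	1	1
Hc-Ran-1314	female	adult	3	1	1
Hc-Ran-623	male	adult	3	2	1
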