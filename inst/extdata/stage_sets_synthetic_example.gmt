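G1.S	synthetic example stage geneset (simulator-derived, not curated biology)	G00053	G00294	G00276	G00024	G00120	G00188	G00101	G00131	G00062
S	synthetic example stage geneset (simulator-derived, not curated biology)	G00016	G00213	G00279	G00146	G00267	G00169	G00089	G00109	G00082
G2	synthetic example stage geneset (simulator-derived, not curated biology)	G00025	G00069	G00035	G00184	G00273	G00004	G00284	G00070	G00242
G2.M	synthetic example stage geneset (simulator-derived, not curated biology)	G00290	G00003	G00011	G00165	G00299	G00221	G00252	G00272	G00277
M.G1	synthetic example stage geneset (simulator-derived, not curated biology)	G00040	G00247	G00160	G00286	G00043	G00020	G00172	G00258	G00163
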