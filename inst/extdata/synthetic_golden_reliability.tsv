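probe_id	n_pairs	icc	sigma_b2	sigma_w2	sd_diff	hola	micc	class_icc	class_micc	mean_beta	sd_beta
cgTEST001	6	-0.0789223	0	0.0183754	0.191705	0.375741	-0.454664	Poor	Poor	0.841054	0.131059
cgTEST002	6	0.827749	0.00888688	0.00173075	0.0588345	0.115316	0.712434	Excellent	Good	0.393116	0.0907268
cgTEST003	6	0.622971	0.00489192	0.00345777	0.0831598	0.162993	0.459978	Good	Fair	0.349983	0.0754252
cgTEST004	6	0.948375	0.0595383	0.00378377	0.0869917	0.170504	0.777871	Excellent	Excellent	0.558453	0.235206
cgTEST005	6	0.534707	0.0175922	0.0162919	0.18051	0.353799	0.180908	Fair	Poor	0.64923	0.184355
cgTEST006	6	0.422409	0.00880804	0.0144492	0.169995	0.333191	0.0892183	Fair	Poor	0.848329	0.149873
cgTEST007	6	0.850782	0.048488	0.00929645	0.136356	0.267257	0.583525	Excellent	Fair	0.698757	0.221028
cgTEST008	6	0.423351	0.00398687	0.00620755	0.111423	0.218389	0.204962	Fair	Poor	0.117953	0.115325
cgTEST009	6	0.575221	0.020812	0.0181302	0.190421	0.373226	0.201995	Fair	Poor	0.731511	0.159608
cgTEST010	6	0.940779	0.041999	0.00268692	0.0733065	0.143681	0.797098	Excellent	Excellent	0.737091	0.206567
cgTEST011	6	0.370215	0.0116944	0.023	0.214476	0.420374	-0.0501586	Poor	Poor	0.220208	0.167642
cgTEST012	6	0.458217	0.0206712	0.0291969	0.241648	0.47363	-0.0154127	Fair	Poor	0.563015	0.185155
cgTEST013	6	0.979324	0.0791385	0.00197564	0.0628592	0.123204	0.85612	Excellent	Excellent	0.334213	0.275269
cgTEST014	6	0.730841	0.0347069	0.0128518	0.160323	0.314234	0.416607	Good	Fair	0.751987	0.241259
cgTEST015	6	-0.361308	0	0.0255391	0.226005	0.442969	-0.804277	Poor	Poor	0.7806	0.125369
cgTEST016	6	-0.112455	0	0.0103834	0.144107	0.28245	-0.394905	Poor	Poor	0.881143	0.0758017
cgTEST017	6	0.919941	0.0106408	0.000900114	0.0424291	0.083161	0.83678	Excellent	Excellent	0.364005	0.10841
cgTEST018	6	0.34126	0.00238128	0.00362037	0.0850926	0.166781	0.174479	Poor	Poor	0.749266	0.0523813
cgTEST019	6	NA	0	5.31334e-32	0	0	NA	Undefined	Undefined	0.5	0
cgTEST020	5	0.596115	0.00961426	0.00796499	0.126214	0.24738	0.348735	Fair	Poor	0.143446	0.131043
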